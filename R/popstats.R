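#' @keywords internal
#' Per-population, per-locus building blocks shared by both estimators:
#' typed counts, observed heterozygosity, unbiased within-population gene
#' diversity and allele frequencies. Populations contribute to a locus only
#' with >= 2 typed individuals (the unbiased Hs correction needs n >= 2);
#' with fewer they are excluded at that locus.
locus_building_blocks <- function(gm) {
  pops <- populations(gm)
  K <- length(pops)
  L <- n_loci(gm)
  typed <- !is.na(gm$a1)
  max_code <- suppressWarnings(max(c(gm$a1, gm$a2), na.rm = TRUE))
  if (!is.finite(max_code)) max_code <- 0L
  A <- max_code + 1L                      # allele codes 0..max_code
  n_k <- matrix(0L, K, L)                 # typed individuals
  ho_k <- matrix(NA_real_, K, L)          # observed heterozygosity
  hs_k <- matrix(NA_real_, K, L)          # unbiased gene diversity
  p <- array(NA_real_, c(K, A, L))        # allele frequencies
  h_a <- array(NA_real_, c(K, A, L))      # het-for-allele frequencies (WC)
  het <- gm$a1 != gm$a2
  for (k in seq_len(K)) {
    idx <- which(gm$pop == pops[k])
    tk <- typed[idx, , drop = FALSE]
    nk <- colSums(tk)
    n_k[k, ] <- nk
    ho <- colSums(het[idx, , drop = FALSE], na.rm = TRUE) / nk
    ho_k[k, ] <- ifelse(nk > 0, ho, NA_real_)
    sum_p2 <- 0
    for (a in seq_len(A) - 1L) {
      is_a1 <- gm$a1[idx, , drop = FALSE] == a
      is_a2 <- gm$a2[idx, , drop = FALSE] == a
      cnt <- colSums(is_a1, na.rm = TRUE) + colSums(is_a2, na.rm = TRUE)
      pa <- ifelse(nk > 0, cnt / (2 * nk), NA_real_)
      p[k, a + 1L, ] <- pa
      sum_p2 <- sum_p2 + ifelse(is.na(pa), 0, pa^2)
      h_a[k, a + 1L, ] <- ifelse(
        nk > 0, colSums(is_a1 != is_a2, na.rm = TRUE) / nk, NA_real_
      )
    }
    hs_k[k, ] <- ifelse(
      nk >= 2,
      nk / (nk - 1) * (1 - sum_p2 - ho_k[k, ] / (2 * nk)),
      NA_real_
    )
  }
  list(pops = pops, K = K, L = L, A = A,
       n_k = n_k, ho_k = ho_k, hs_k = hs_k, p = p, h_a = h_a,
       include = n_k >= 2L)
}

#' Per-locus gene diversities and F-statistics
#'
#' For each locus, computes Nei's sample-size-corrected gene diversity
#' statistics across populations under missing data. Per population `k` with
#' `n_k` typed individuals, observed heterozygosity `Ho_k` is the heterozygote
#' fraction and the unbiased within-population gene diversity is
#' `Hs_k = n_k/(n_k - 1) * (1 - sum_i p_ki^2 - Ho_k/(2 n_k))` (requires
#' `n_k >= 2`; populations below that are excluded at the locus — the count
#' of exclusions is reported). Across the `np` included populations, with
#' `n~` their harmonic mean sample size and `pbar_i` the unweighted mean
#' allele frequencies: `ho` and `hs` are the means of `Ho_k` and `Hs_k`, and
#' the total gene diversity is
#' `ht = 1 - sum_i pbar_i^2 + hs/(n~ np) - ho/(2 n~ np)`.
#' Then `fst = (ht - hs)/ht` (defined when `np >= 2` and `ht > 0`) and
#' `fis = 1 - ho/hs` (defined when `hs > 0`). Undefined statistics are `NA`
#' with their `*_defined` flag `FALSE` — never a silent zero. Multiallelic
#' loci (microsatellites) are handled natively by the same formulas.
#'
#' @param gm A [geno_mat()].
#' @return A tibble with one row per locus: `locus`, `n_typed` (total typed
#'   individuals), `np_used` (populations included), `n_excluded_pops`
#'   (populations with 1 typed individual, excluded), `ho`, `hs`, `ht`,
#'   `fst`, `fis`, `fst_defined`, `fis_defined`.
#' @examples
#' a1 <- matrix(0L, 4, 1, dimnames = list(paste0("i", 1:4), "L1"))
#' a2 <- matrix(c(0L, 1L, 1L, 1L), 4, 1, dimnames = dimnames(a1))
#' a1[3:4, 1] <- 1L
#' per_locus_stats(geno_mat(a1, a2, pop = c("A", "A", "B", "B")))
#' @export
per_locus_stats <- function(gm) {
  bb <- locus_building_blocks(gm)
  inc <- bb$include
  np <- colSums(inc)
  n_excluded <- colSums(bb$n_k == 1L)
  incn <- ifelse(inc, 1, NA_real_)     # mask: NA where excluded
  ho <- colMeans(bb$ho_k * incn, na.rm = TRUE)
  hs <- colMeans(bb$hs_k * incn, na.rm = TRUE)
  nharm <- np / colSums(ifelse(inc, 1 / bb$n_k, 0))
  # mean allele frequencies over included populations
  sum_pbar2 <- numeric(bb$L)
  for (a in seq_len(bb$A)) {
    pa <- bb$p[, a, , drop = FALSE]
    dim(pa) <- c(bb$K, bb$L)
    pbar <- colMeans(pa * incn, na.rm = TRUE)
    sum_pbar2 <- sum_pbar2 + ifelse(is.na(pbar), 0, pbar^2)
  }
  ht <- ifelse(np >= 2,
               1 - sum_pbar2 + hs / (nharm * np) - ho / (2 * nharm * np),
               NA_real_)
  ho[np == 0] <- NA_real_
  hs[np == 0] <- NA_real_
  fst_defined <- !is.na(ht) & ht > 0
  fis_defined <- !is.na(hs) & hs > 0
  tibble::tibble(
    locus = loci(gm),
    n_typed = as.integer(colSums(bb$n_k)),
    np_used = as.integer(np),
    n_excluded_pops = as.integer(n_excluded),
    ho = ho, hs = hs, ht = ht,
    fst = ifelse(fst_defined, (ht - hs) / ht, NA_real_),
    fis = ifelse(fis_defined, 1 - ho / hs, NA_real_),
    fst_defined = fst_defined,
    fis_defined = fis_defined
  )
}

#' Multilocus statistics by ratio-of-averages aggregation
#'
#' Aggregates a per-locus table into multilocus statistics the standard way:
#' average the diversity components over loci first, then form the ratios —
#' `fst = (ht_bar - hs_bar)/ht_bar` over loci with a defined `ht`, and
#' `fis = 1 - ho_bar/hs_bar` over loci with a defined `hs` — never the
#' average of per-locus ratios. Loci with undefined components are excluded
#' from the corresponding mean, and the number used is reported per
#' component.
#'
#' @param locus_stats A per-locus tibble from [per_locus_stats()] (columns
#'   `ho`, `hs`, `ht` at minimum).
#' @return A one-row tibble: `ho`, `hs`, `ht`, `fst`, `fis`, `n_loci_ho`,
#'   `n_loci_fst`, `n_loci_fis`.
#' @export
multilocus_stats <- function(locus_stats) {
  ok_ho <- !is.na(locus_stats$ho)
  ok_ht <- !is.na(locus_stats$ht)
  ok_hs <- !is.na(locus_stats$hs)
  if (!any(ok_ho | ok_hs | ok_ht)) {
    stop("no locus with defined statistics", call. = FALSE)
  }
  ho_bar <- if (any(ok_ho)) mean(locus_stats$ho[ok_ho]) else NA_real_
  hs_bar <- if (any(ok_hs)) mean(locus_stats$hs[ok_hs]) else NA_real_
  ht_bar <- if (any(ok_ht)) mean(locus_stats$ht[ok_ht]) else NA_real_
  fst <- if (!is.na(ht_bar) && !is.na(hs_bar) && ht_bar > 0) {
    (ht_bar - hs_bar) / ht_bar
  } else NA_real_
  fis <- if (!is.na(hs_bar) && !is.na(ho_bar) && hs_bar > 0) {
    1 - ho_bar / hs_bar
  } else NA_real_
  tibble::tibble(
    ho = ho_bar, hs = hs_bar, ht = ht_bar, fst = fst, fis = fis,
    n_loci_ho = sum(ok_ho), n_loci_fst = sum(ok_ht), n_loci_fis = sum(ok_hs)
  )
}

#' Weir-Cockerham theta
#'
#' The variance-components F_ST estimator of Weir & Cockerham (1984),
#' provided as an alternative to the gene-diversity estimator so that
#' estimator-choice sensitivity can be examined. Per locus and allele the
#' among-population (`a`), between-individual (`b`) and within-individual
#' (`c`) components are computed from sample sizes, allele frequencies and
#' heterozygote-for-allele frequencies; components are summed over alleles,
#' giving per-locus `theta = sum(a) / sum(a + b + c)`, and pooled over loci
#' for the overall estimate. The same missing-data rule as
#' [per_locus_stats()] applies: populations with fewer than 2 typed
#' individuals are excluded at that locus.
#'
#' @param gm A [geno_mat()].
#' @return A list with `per_locus` (tibble: `locus`, `a`, `abc`, `theta`,
#'   `defined`) and `overall` (pooled theta over loci).
#' @export
wc_theta <- function(gm) {
  bb <- locus_building_blocks(gm)
  inc <- bb$include
  r <- colSums(inc)
  incn <- ifelse(inc, 1, NA_real_)
  n_use <- bb$n_k * incn
  nbar <- colMeans(n_use, na.rm = TRUE)
  sum_n <- colSums(n_use, na.rm = TRUE)
  sum_n2 <- colSums(n_use^2, na.rm = TRUE)
  nc <- ifelse(r >= 2, (sum_n - sum_n2 / sum_n) / (r - 1), NA_real_)
  a_sum <- numeric(bb$L)
  abc_sum <- numeric(bb$L)
  for (al in seq_len(bb$A)) {
    pk <- matrix(bb$p[, al, ], bb$K, bb$L) * incn
    hk <- matrix(bb$h_a[, al, ], bb$K, bb$L) * incn
    pbar <- colSums(n_use * pk, na.rm = TRUE) / sum_n
    s2 <- ifelse(r >= 2,
                 colSums(n_use * sweep(pk, 2, pbar)^2, na.rm = TRUE) /
                   ((r - 1) * nbar),
                 NA_real_)
    hbar <- colSums(n_use * hk, na.rm = TRUE) / sum_n
    a_c <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_c <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    contrib_ok <- !is.na(a_c)
    a_sum <- a_sum + ifelse(contrib_ok, a_c, 0)
    abc_sum <- abc_sum + ifelse(contrib_ok, a_c + b_c + c_c, 0)
  }
  defined <- r >= 2 & abc_sum > 0
  per_locus <- tibble::tibble(
    locus = loci(gm),
    a = ifelse(r >= 2, a_sum, NA_real_),
    abc = ifelse(r >= 2, abc_sum, NA_real_),
    theta = ifelse(defined, a_sum / abc_sum, NA_real_),
    defined = defined
  )
  overall <- if (any(defined)) {
    sum(per_locus$a[defined]) / sum(per_locus$abc[defined])
  } else NA_real_
  list(per_locus = per_locus, overall = overall)
}

#' One-versus-rest pairwise F_ST
#'
#' Pools all non-focal individuals into a single group and returns the
#' two-group multilocus F_ST — the "one sampling location versus all others
#' combined" contrast.
#'
#' @param gm A [geno_mat()] with at least two populations.
#' @param focal A population label of `gm`.
#' @param estimator `"nei"` (gene-diversity, the default) or `"wc"`
#'   (Weir-Cockerham theta).
#' @return A single F_ST value.
#' @seealso [pairwise_fst_table()] for all locations at once.
#' @export
pairwise_one_vs_rest <- function(gm, focal, estimator = c("nei", "wc")) {
  estimator <- match.arg(estimator)
  if (!focal %in% populations(gm)) {
    stop("unknown focal population: ", focal, call. = FALSE)
  }
  if (length(populations(gm)) < 2) {
    stop("need at least one non-focal population", call. = FALSE)
  }
  two <- set_populations(gm, ifelse(gm$pop == focal, focal, "rest"))
  if (estimator == "nei") {
    multilocus_stats(per_locus_stats(two))$fst
  } else {
    wc_theta(two)$overall
  }
}

#' @rdname pairwise_one_vs_rest
#' @return `pairwise_fst_table()` returns a tibble with columns `population`
#'   and `fst` (one-vs-rest), one row per population.
#' @export
pairwise_fst_table <- function(gm, estimator = c("nei", "wc")) {
  estimator <- match.arg(estimator)
  tibble::tibble(
    population = populations(gm),
    fst = vapply(populations(gm),
                 function(p) pairwise_one_vs_rest(gm, p, estimator), numeric(1),
                 USE.NAMES = FALSE)
  )
}

#' Inbreeding coefficient from heterozygosities
#'
#' `F_IS = (H_E - H_O) / H_E`: positive for a heterozygote deficit, negative
#' for an excess. Undefined (NA) when `H_E` is zero.
#'
#' @param ho Observed heterozygosity (vectorised).
#' @param he Expected heterozygosity (within-population gene diversity).
#' @return `(he - ho) / he`, `NA_real_` where `he == 0`.
#' @examples
#' fis_from_het(0.4, 0.5)   #  0.25
#' fis_from_het(0.5, 0.4)   # -0.25
#' @export
fis_from_het <- function(ho, he) {
  ifelse(he == 0, NA_real_, (he - ho) / he)
}

#' Per-location heterozygosity and inbreeding
#'
#' Within each sampling location: `ho`, the mean over loci of the location's
#' observed heterozygosity (loci with at least one typed member), and `fis`,
#' computed as `1 - mean(Ho)/mean(Hs)` over the loci where the location's
#' unbiased gene diversity `Hs` is defined (>= 2 typed members). The
#' `ho_for_fis`/`hs` columns expose the two means entering `fis`, so
#' `fis == fis_from_het(ho_for_fis, hs)` holds exactly.
#'
#' @param gm A [geno_mat()].
#' @return A tibble with one row per population: `population`, `n_loci_ho`,
#'   `ho`, `n_loci_fis`, `ho_for_fis`, `hs`, `fis` (`NA` with zero usable
#'   loci).
#' @export
per_location_stats <- function(gm) {
  bb <- locus_building_blocks(gm)
  purrr::map_dfr(seq_len(bb$K), function(k) {
    ho_k <- bb$ho_k[k, ]
    hs_k <- bb$hs_k[k, ]
    ok_ho <- !is.na(ho_k)
    ok_hs <- !is.na(hs_k)
    hs_bar <- if (any(ok_hs)) mean(hs_k[ok_hs]) else NA_real_
    ho_for_fis <- if (any(ok_hs)) mean(ho_k[ok_hs]) else NA_real_
    tibble::tibble(
      population = bb$pops[k],
      n_loci_ho = sum(ok_ho),
      ho = if (any(ok_ho)) mean(ho_k[ok_ho]) else NA_real_,
      n_loci_fis = sum(ok_hs),
      ho_for_fis = ho_for_fis,
      hs = hs_bar,
      fis = if (!is.na(hs_bar) && hs_bar > 0) 1 - ho_for_fis / hs_bar else NA_real_
    )
  })
}

#' Histogram of a per-locus statistic with an extreme-value tally
#'
#' Bins per-locus values into half-open bins `[lo, lo + w)` and counts the
#' loci strictly above an extreme threshold — the summary used to expose
#' pile-ups of near-fixed loci (e.g. F_ST or H_O above 0.975) that appear
#' when low-completeness loci are retained. Undefined (`NA`) values are
#' excluded from the bins and tallied separately.
#'
#' @param values Numeric vector of per-locus statistic values (`NA` allowed).
#' @param bin_width Bin width (> 0); default 0.05.
#' @param extreme_threshold Count values strictly above this; default 0.975.
#' @return A list: `bins` (tibble `bin_lo`, `bin_hi`, `count`), `n_extreme`,
#'   `n_undefined`.
#' @export
stat_histogram <- function(values, bin_width = 0.05, extreme_threshold = 0.975) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  n_undefined <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    return(list(
      bins = tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                            count = integer()),
      n_extreme = 0L, n_undefined = n_undefined
    ))
  }
  first <- floor(min(v) / bin_width + 1e-9)
  idx <- floor(v / bin_width + 1e-9)      # guard fp edges like 1.0/0.5
  counts <- table(factor(idx, levels = first:max(idx)))
  bins <- tibble::tibble(
    bin_lo = as.integer(names(counts)) * bin_width,
    bin_hi = (as.integer(names(counts)) + 1) * bin_width,
    count = as.integer(counts)
  )
  list(bins = bins, n_extreme = sum(v > extreme_threshold),
       n_undefined = n_undefined)
}
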