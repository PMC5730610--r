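#' Keep one SNP per RAD tag
#'
#' RAD assemblies call several SNPs on the same short tag; retaining more
#' than one per tag duplicates tightly linked information. This keeps, for
#' each tag, the first locus in input order — the same convention as the
#' "write single SNP" export of RAD genotyping pipelines.
#'
#' @param gm A [geno_mat()] with tag labels.
#' @return A [geno_mat()] with exactly one locus per tag, in input order.
#' @export
select_single_snp <- function(gm) {
  if (is.null(gm$tags)) {
    stop("no RAD-tag labels on this matrix; skip the single-SNP stage or supply `tags`",
         call. = FALSE)
  }
  keep <- !duplicated(unname(gm$tags))
  subset_loci(gm, which(keep))
}

#' Pooled minor-allele frequencies
#'
#' @param gm A [geno_mat()].
#' @return A tibble with columns `locus`, `maf` (minor-allele frequency over
#'   all typed individuals pooled across populations; `NA` for a fully
#'   missing locus) and `n_alleles` (distinct allele codes observed).
#' @export
pooled_maf <- function(gm) {
  maf <- numeric(n_loci(gm))
  n_all <- integer(n_loci(gm))
  for (j in seq_len(n_loci(gm))) {
    al <- c(gm$a1[, j], gm$a2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0) {
      maf[j] <- NA_real_
      n_all[j] <- 0L
      next
    }
    freq <- table(al) / length(al)
    n_all[j] <- length(freq)
    maf[j] <- if (length(freq) < 2) 0 else 1 - max(freq)
  }
  tibble::tibble(locus = loci(gm), maf = maf, n_alleles = n_all)
}

#' Minor-allele-frequency filter
#'
#' Retains loci whose minor-allele frequency — computed on all typed alleles
#' pooled across populations, the frequency a genotyping pipeline sees before
#' any population analysis — is strictly greater than `maf_min`. Monomorphic
#' and fully missing loci are always removed.
#'
#' @param gm A [geno_mat()].
#' @param maf_min Threshold in `[0, 0.5)`; default 0.05.
#' @return A filtered [geno_mat()].
#' @export
filter_maf <- function(gm, maf_min = 0.05) {
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must be in [0, 0.5)", call. = FALSE)
  maf <- pooled_maf(gm)$maf
  subset_loci(gm, which(!is.na(maf) & maf > maf_min))
}

#' Locus-completeness filter
#'
#' Retains exactly the loci genotyped in at least `k` individuals.
#' Individuals are never removed.
#'
#' @param gm A [geno_mat()].
#' @param k Minimum number of typed individuals, in `[1, n_ind(gm)]`.
#' @return A filtered [geno_mat()].
#' @export
filter_min_individuals <- function(gm, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > n_ind(gm)) {
    stop(sprintf("`k` must be a single integer in [1, %d]", n_ind(gm)), call. = FALSE)
  }
  subset_loci(gm, which(typed_per_locus(gm) >= k))
}

#' Build a completeness-filtered dataset family
#'
#' Applies [filter_min_individuals()] at each cutoff, producing the nested
#' family of datasets a completeness gradient generates: stricter cutoffs
#' keep fewer, more complete loci. The summary mirrors the standard reporting
#' columns: cutoff in individuals, locus count, the cutoff as a percentage of
#' individuals (rounded half-up to one decimal), and the percentage of
#' missing calls in the retained matrix.
#'
#' @param gm A [geno_mat()].
#' @param cutoffs Integer vector of distinct completeness cutoffs, each in
#'   `[1, n_ind(gm)]`. Members are ordered by increasing cutoff.
#' @return An object of class `dataset_family`: a list with `members` (named
#'   list of [geno_mat()], names `"cutoff_<k>"`) and `summary` (a tibble with
#'   columns `cutoff`, `n_loci`, `pct_individuals_required`,
#'   `pct_missing_cells`).
#' @examples
#' gm <- simulate_snp_panel(sim_config(n_loci = 300, seed = 4))$matrix
#' gm <- apply_mcar(gm, rate = 0.3, seed = 5)
#' fam <- build_dataset_family(gm, cutoffs = c(1, 48, 77))
#' fam$summary
#' @export
build_dataset_family <- function(gm, cutoffs) {
  if (length(cutoffs) == 0) stop("`cutoffs` must be non-empty", call. = FALSE)
  if (anyDuplicated(cutoffs)) stop("duplicate cutoffs", call. = FALSE)
  cutoffs <- sort(as.integer(cutoffs))
  members <- lapply(cutoffs, function(k) filter_min_individuals(gm, k))
  names(members) <- paste0("cutoff_", cutoffs)
  summary <- tibble::tibble(
    cutoff = cutoffs,
    n_loci = vapply(members, n_loci, integer(1)),
    pct_individuals_required = round_half_up(100 * cutoffs / n_ind(gm), 1),
    pct_missing_cells = vapply(members, function(m) {
      if (n_loci(m) == 0) 0 else 100 * mean(is.na(m$a1))
    }, numeric(1))
  )
  structure(list(members = members, summary = summary), class = "dataset_family")
}

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @export
print.dataset_family <- function(x, ...) {
  cat(sprintf("<dataset_family> %d members\n", length(x$members)))
  print(x$summary)
  invisible(x)
}
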