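#' Simulation configuration for island-model genotype panels
#'
#' The defaults mirror a study-shaped RAD design: 12 sampling locations of 8
#' diploid individuals each (96 total), biallelic SNPs with ancestral minor
#' allele frequency drawn uniformly on `[0.05, 0.5]` so generated panels pass
#' a MAF > 0.05 filter by construction, and differentiation controlled by a
#' Balding-Nichols target F_ST.
#'
#' @param n_pops Number of demes (sampling locations).
#' @param n_per_pop Diploid individuals per deme.
#' @param n_loci Number of loci.
#' @param target_fst Expected F_ST among demes, in `[0, 1)`; 0 gives
#'   identical deme frequencies.
#' @param maf_min,maf_max Support of the uniform ancestral
#'   minor-allele-frequency law (SNP panels).
#' @param marker_type `"snp"` (biallelic) or `"ssr"` (multiallelic
#'   microsatellite-like).
#' @param n_alleles Allele count per SSR locus.
#' @param dirichlet_conc Symmetric Dirichlet concentration for ancestral SSR
#'   allele frequencies.
#' @param seed Integer seed; the panel is fully determined by the
#'   configuration (seed included).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 12, n_per_pop = 8, n_loci = 1000,
                       target_fst = 0.1, maf_min = 0.05, maf_max = 0.5,
                       marker_type = c("snp", "ssr"), n_alleles = 10,
                       dirichlet_conc = 1, seed = 1) {
  marker_type <- match.arg(marker_type)
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_loci >= 1, n_alleles >= 2,
            maf_min >= 0, maf_max <= 0.5, maf_min <= maf_max)
  if (target_fst < 0 || target_fst >= 1) {
    stop("`target_fst` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 target_fst = target_fst, maf_min = maf_min, maf_max = maf_max,
                 marker_type = marker_type, n_alleles = n_alleles,
                 dirichlet_conc = dirichlet_conc, seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a given seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Balding-Nichols deme frequencies around ancestral p with parameter F
bn_deme_freq <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

sim_labels <- function(cfg) {
  pops <- sprintf("P%02d", seq_len(cfg$n_pops))
  inds <- as.vector(vapply(pops, function(p) {
    sprintf("%s_i%d", p, seq_len(cfg$n_per_pop))
  }, character(cfg$n_per_pop)))
  locs <- sprintf("L%05d", seq_len(cfg$n_loci))
  list(pops = pops, inds = inds,
       pop_of = rep(pops, each = cfg$n_per_pop), loci = locs)
}

#' Simulate an island-model SNP panel
#'
#' Per locus: an ancestral frequency for allele 1 is drawn from the
#' configured uniform MAF law; deme frequencies follow the Balding-Nichols
#' model, `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose expected F_ST equals
#' the target `F` (with `p_k = p` exactly at `F = 0`); genotypes are drawn
#' under Hardy-Weinberg equilibrium within demes. Loci receive singleton RAD
#' tags so the single-SNP stage is a no-op on simulated panels. No calls are
#' missing; layer missingness with [apply_mcar()],
#' [apply_individual_missingness()] or [apply_allelic_dropout()].
#'
#' @param cfg A [sim_config()] with `marker_type = "snp"`.
#' @return A list with `matrix` (a [geno_mat()]) and `truth` (a `sim_truth`
#'   list recording the seed, target F_ST, ancestral frequencies and the
#'   demes-by-loci frequency matrix).
#' @examples
#' panel <- simulate_snp_panel(sim_config(n_loci = 200, target_fst = 0.1, seed = 7))
#' multilocus_stats(per_locus_stats(panel$matrix))
#' @export
simulate_snp_panel <- function(cfg) {
  if (cfg$marker_type != "snp") stop("`cfg` must have marker_type = 'snp'", call. = FALSE)
  lab <- sim_labels(cfg)
  with_seed(cfg$seed, {
    p_anc <- stats::runif(cfg$n_loci, cfg$maf_min, cfg$maf_max)
    deme_p <- matrix(NA_real_, cfg$n_pops, cfg$n_loci,
                     dimnames = list(lab$pops, lab$loci))
    for (k in seq_len(cfg$n_pops)) deme_p[k, ] <- bn_deme_freq(p_anc, cfg$target_fst)
    n <- cfg$n_pops * cfg$n_per_pop
    # two allele draws per individual per locus, HWE within deme
    prob <- deme_p[rep(seq_len(cfg$n_pops), each = cfg$n_per_pop), ]
    a1 <- matrix(stats::rbinom(n * cfg$n_loci, 1L, prob), n, cfg$n_loci)
    a2 <- matrix(stats::rbinom(n * cfg$n_loci, 1L, prob), n, cfg$n_loci)
    dimnames(a1) <- dimnames(a2) <- list(lab$inds, lab$loci)
    gm <- geno_mat(a1, a2, pop = lab$pop_of,
                   tags = paste0("tag_", lab$loci))
    truth <- structure(list(
      marker_type = "snp", seed = cfg$seed, target_fst = cfg$target_fst,
      ancestral = tibble::tibble(locus = lab$loci, p = p_anc),
      deme_freq = deme_p, dropout = NULL
    ), class = "sim_truth")
    list(matrix = gm, truth = truth)
  })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate an island-model microsatellite (SSR) panel
#'
#' Ancestral allele frequencies per locus are symmetric-Dirichlet; deme
#' frequencies follow `Dirichlet(ancestral * (1-F)/F)`, the multiallelic
#' analogue of the Balding-Nichols model (expected F_ST approximately `F`;
#' deme equals ancestral exactly at `F = 0`). Genotypes are Hardy-Weinberg
#' within demes. Allele codes run 1..`n_alleles` (0 is the genepop missing
#' code).
#'
#' @param cfg A [sim_config()] with `marker_type = "ssr"`.
#' @return As [simulate_snp_panel()]; `truth$ancestral` is a loci-by-alleles
#'   frequency matrix and `truth$deme_freq` a demes x alleles x loci array.
#' @export
simulate_ssr_panel <- function(cfg) {
  if (cfg$marker_type != "ssr") stop("`cfg` must have marker_type = 'ssr'", call. = FALSE)
  lab <- sim_labels(cfg)
  A <- cfg$n_alleles
  with_seed(cfg$seed, {
    anc <- t(vapply(seq_len(cfg$n_loci),
                    function(j) rdirichlet1(rep(cfg$dirichlet_conc, A)),
                    numeric(A)))
    dimnames(anc) <- list(lab$loci, paste0("allele", seq_len(A)))
    deme_p <- array(NA_real_, c(cfg$n_pops, A, cfg$n_loci),
                    dimnames = list(lab$pops, paste0("allele", seq_len(A)), lab$loci))
    for (j in seq_len(cfg$n_loci)) {
      for (k in seq_len(cfg$n_pops)) {
        deme_p[k, , j] <- if (cfg$target_fst == 0) anc[j, ] else {
          rdirichlet1(anc[j, ] * (1 - cfg$target_fst) / cfg$target_fst)
        }
      }
    }
    n <- cfg$n_pops * cfg$n_per_pop
    a1 <- matrix(NA_integer_, n, cfg$n_loci, dimnames = list(lab$inds, lab$loci))
    a2 <- a1
    for (j in seq_len(cfg$n_loci)) {
      for (k in seq_len(cfg$n_pops)) {
        rows <- which(lab$pop_of == lab$pops[k])
        a1[rows, j] <- sample.int(A, length(rows), replace = TRUE,
                                  prob = deme_p[k, , j])
        a2[rows, j] <- sample.int(A, length(rows), replace = TRUE,
                                  prob = deme_p[k, , j])
      }
    }
    gm <- geno_mat(a1, a2, pop = lab$pop_of)
    truth <- structure(list(
      marker_type = "ssr", seed = cfg$seed, target_fst = cfg$target_fst,
      ancestral = anc, deme_freq = deme_p, dropout = NULL
    ), class = "sim_truth")
    list(matrix = gm, truth = truth)
  })
}

#' Missing-completely-at-random masking
#'
#' Sets each call missing independently with probability `rate` — the
#' baseline missingness mechanism against which allelic-dropout bias is
#' contrasted: MCAR missingness is independent of genotype, so completeness
#' filtering under MCAR leaves estimates unbiased.
#'
#' @param gm A [geno_mat()].
#' @param rate Per-call missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [geno_mat()] with calls masked.
#' @export
apply_mcar <- function(gm, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    mask <- matrix(stats::runif(n_ind(gm) * n_loci(gm)) < rate,
                   n_ind(gm), n_loci(gm))
    a1 <- gm$a1; a2 <- gm$a2
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
    geno_mat(a1, a2, pop = gm$pop, tags = gm$tags)
  })
}

#' Per-individual missingness
#'
#' Masks each individual's calls independently at that individual's own
#' rate, emulating library-quality differences between samples and the
#' location-to-location spread of missingness seen in RAD panels.
#'
#' @param gm A [geno_mat()].
#' @param rate_per_individual Numeric vector of per-call missingness rates,
#'   one per individual (in matrix order, or named by individual ID).
#' @param seed Integer seed.
#' @return A [geno_mat()].
#' @export
apply_individual_missingness <- function(gm, rate_per_individual, seed = 1) {
  r <- rate_per_individual
  if (!is.null(names(r))) r <- r[individuals(gm)]
  if (length(r) != n_ind(gm) || anyNA(r) || any(r < 0 | r > 1)) {
    stop("`rate_per_individual` must give a rate in [0,1] for every individual",
         call. = FALSE)
  }
  with_seed(seed, {
    mask <- matrix(stats::runif(n_ind(gm) * n_loci(gm)), n_ind(gm), n_loci(gm)) <
      matrix(r, n_ind(gm), n_loci(gm))
    a1 <- gm$a1; a2 <- gm$a2
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
    geno_mat(a1, a2, pop = gm$pop, tags = gm$tags)
  })
}

#' Restriction-site allelic dropout
#'
#' Models a null allele segregating at each RAD locus: a restriction-site
#' mutation that prevents the tag from being sequenced on the haplotype
#' carrying it. Because the mutation arises on a haplotype, the null is
#' linked to the SNP allele on that background, and the linked fraction
#' drifts among demes like any allele. Concretely, per locus an ancestral
#' null fraction `q` is drawn from `q_law`, and for each allele background
#' and deme the within-background null fraction follows the Balding-Nichols
#' model with the panel's own F. Each allele copy an individual carries is
#' then null with its background's deme-specific rate: two null copies
#' silence the locus for that individual (missing call); one silences one
#' haplotype, so the surviving allele is called as a homozygote (a
#' heterozygote miscall when the call was heterozygous). Because null rates
#' differ between allele backgrounds deme by deme, apparent allele
#' frequencies among called genotypes are distorted deme-specifically —
#' the mechanism that inflates F_ST, increasingly so at high-`q`
#' (high-missingness) loci, which is why relaxing a completeness cutoff
#' lets the bias in. A null drawn independently of the allele carried
#' would leave apparent frequencies unbiased and produce no such
#' inflation.
#'
#' @param gm A [geno_mat()] from [simulate_snp_panel()] (no prior missing
#'   calls required, but allowed).
#' @param truth The panel's `sim_truth` (supplies the F used to spread null
#'   alleles among demes).
#' @param q_law Function `n -> n` draws of the ancestral null fraction,
#'   with support in `[0, 1)`. The default `Uniform(0, 0.9)` spans per-locus
#'   missingness from none to near-complete, the spectrum seen in RAD panels
#'   before completeness filtering.
#' @param seed Integer seed.
#' @return A list: `matrix` (the corrupted [geno_mat()]) and `truth` with a
#'   `dropout` element recording per-locus ancestral `q`, the
#'   demes x backgrounds x loci null rates, and the miscalled (het-to-hom)
#'   and silenced cells.
#' @export
apply_allelic_dropout <- function(gm, truth,
                                  q_law = function(n) stats::runif(n, 0, 0.9),
                                  seed = 1) {
  if (!inherits(truth, "sim_truth")) stop("`truth` must be a sim_truth", call. = FALSE)
  pops <- populations(gm)
  K <- length(pops)
  L <- n_loci(gm)
  n <- n_ind(gm)
  max_code <- suppressWarnings(max(c(gm$a1, gm$a2), na.rm = TRUE))
  if (!is.finite(max_code)) max_code <- 0L
  A <- max_code + 1L
  with_seed(seed, {
    q_anc <- q_law(L)
    if (any(q_anc < 0 | q_anc >= 1)) {
      stop("`q_law` must have support in [0, 1)", call. = FALSE)
    }
    f <- truth$target_fst
    # null rate per (deme, allele background, locus), BN drift around q_anc
    u <- array(NA_real_, c(K, A, L),
               dimnames = list(pops, paste0("bg", seq_len(A) - 1L), loci(gm)))
    for (k in seq_len(K)) {
      for (a in seq_len(A)) {
        u[k, a, ] <- pmin(bn_deme_freq(q_anc, f), 1 - 1e-12)
      }
    }
    ki <- match(gm$pop, pops)
    rate_for <- function(al) {
      # per-cell null rate given the allele carried on that haplotype
      r <- matrix(0, n, L)
      for (a in seq_len(A) - 1L) {
        hit <- !is.na(al) & al == a
        if (any(hit)) {
          ua <- matrix(u[, a + 1L, ], K, L)[ki, , drop = FALSE]
          r[hit] <- ua[hit]
        }
      }
      r
    }
    null1 <- matrix(stats::runif(n * L), n, L) < rate_for(gm$a1)
    null2 <- matrix(stats::runif(n * L), n, L) < rate_for(gm$a2)
    typed <- !is.na(gm$a1)
    a1 <- gm$a1; a2 <- gm$a2
    was_het <- typed & a1 != a2
    silenced <- typed & null1 & null2
    one_null <- typed & xor(null1, null2)
    surv <- ifelse(null1, a2, a1)          # the haplotype that still amplifies
    a1[one_null] <- surv[one_null]
    a2[one_null] <- surv[one_null]
    a1[silenced] <- NA_integer_
    a2[silenced] <- NA_integer_
    miscalled <- one_null & was_het
    truth$dropout <- list(
      q_anc = stats::setNames(q_anc, loci(gm)),
      null_rate = u,
      miscalled = miscalled,
      silenced = silenced,
      n_miscalled = sum(miscalled),
      n_silenced = sum(silenced)
    )
    list(matrix = geno_mat(a1, a2, pop = gm$pop, tags = gm$tags), truth = truth)
  })
}
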