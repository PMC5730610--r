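test_that("panels are fully determined by configuration and seed", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 4, n_loci = 50, target_fst = 0.1,
                    seed = 17)
  p1 <- simulate_snp_panel(cfg)
  p2 <- simulate_snp_panel(cfg)
  expect_true(isTRUE(all.equal(p1$matrix, p2$matrix)))
  expect_equal(p1$truth$deme_freq, p2$truth$deme_freq)
  p3 <- simulate_snp_panel(sim_config(n_pops = 3, n_per_pop = 4, n_loci = 50,
                                      target_fst = 0.1, seed = 18))
  expect_false(isTRUE(all.equal(p1$matrix, p3$matrix)))
  # the simulator restores the caller's RNG state
  set.seed(5); before <- .Random.seed
  invisible(simulate_snp_panel(cfg))
  expect_identical(.Random.seed, before)
})

test_that("undifferentiated panels give near-zero F_ST and truth matches frequencies", {
  p0 <- simulate_snp_panel(sim_config(n_loci = 5000, target_fst = 0, seed = 23))
  expect_lt(abs(multilocus_stats(per_locus_stats(p0$matrix))$fst), 0.01)
  # at F = 0 every deme carries the ancestral frequencies exactly
  expect_true(all(p0$truth$deme_freq[1, ] == p0$truth$ancestral$p))

  # genotype frequencies reproduce truth frequencies within binomial error:
  # chi-square over the three genotype classes at n = 500
  p <- simulate_snp_panel(sim_config(n_pops = 1, n_per_pop = 500, n_loci = 20,
                                     target_fst = 0, seed = 31))
  pvals <- sapply(seq_len(20), function(j) {
    pj <- p$truth$deme_freq[1, j]
    dos <- p$matrix$a1[, j] + p$matrix$a2[, j]
    obs <- tabulate(dos + 1L, 3)
    expct <- 500 * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    stats::pchisq(sum((obs - expct)^2 / expct), df = 2, lower.tail = FALSE)
  })
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("SSR panels reduce to SNP-like behaviour and gain diversity with alleles", {
  # n_alleles = 2 behaves like a biallelic panel
  cfg2 <- sim_config(n_loci = 400, target_fst = 0.1, marker_type = "ssr",
                     n_alleles = 2, seed = 41)
  ssr2 <- simulate_ssr_panel(cfg2)
  fst2 <- multilocus_stats(per_locus_stats(ssr2$matrix))$fst
  expect_gt(fst2, 0.05); expect_lt(fst2, 0.2)

  # 8 loci, 10 alleles, study shape: wide envelope around the target
  fsts <- sapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 8, target_fst = 0.12, marker_type = "ssr",
                      n_alleles = 10, seed = 100 + s)
    multilocus_stats(per_locus_stats(simulate_ssr_panel(cfg)$matrix))$fst
  })
  expect_gt(mean(fsts >= 0.03 & fsts <= 0.25), 0.7)

  # expected heterozygosity grows with allele count
  hs_at <- function(A) {
    mean(sapply(1:4, function(s) {
      cfg <- sim_config(n_loci = 30, target_fst = 0.05, marker_type = "ssr",
                        n_alleles = A, seed = 200 + s)
      multilocus_stats(per_locus_stats(simulate_ssr_panel(cfg)$matrix))$hs
    }))
  }
  expect_lt(hs_at(2), hs_at(5))
  expect_lt(hs_at(5), hs_at(12))
})

test_that("MCAR and per-individual missingness hit their configured rates", {
  gm <- simulate_snp_panel(sim_config(n_pops = 4, n_per_pop = 25,
                                      n_loci = 100, seed = 3))$matrix
  expect_true(isTRUE(all.equal(apply_mcar(gm, 0, seed = 1), gm)))
  allm <- apply_mcar(gm, 1, seed = 1)
  expect_true(all(is.na(allm$a1)))

  # realized rate within 3 binomial sd of the target at 10,000 cells
  m <- apply_mcar(gm, 0.3, seed = 9)
  expect_lt(abs(mean(is.na(m$a1)) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  # per-individual rates: fully missing row, and ordering preserved
  rates <- rep(c(0.05, 0.6), length.out = n_ind(gm))
  rates[1] <- 1
  im <- apply_individual_missingness(gm, rates, seed = 5)
  expect_true(all(is.na(im$a1[1, ])))
  realized <- rowMeans(is.na(im$a1))
  expect_true(mean(realized[rates == 0.6]) > mean(realized[rates == 0.05]))
})

test_that("allelic dropout: identity at q=0, silence at q->1, bookkeeping", {
  p <- simulate_snp_panel(sim_config(n_loci = 60, target_fst = 0.1, seed = 8))
  d0 <- apply_allelic_dropout(p$matrix, p$truth, q_law = function(n) rep(0, n),
                              seed = 2)
  expect_true(isTRUE(all.equal(d0$matrix, p$matrix)))
  expect_equal(d0$truth$dropout$n_miscalled, 0)

  d1 <- apply_allelic_dropout(p$matrix, p$truth,
                              q_law = function(n) rep(1 - 1e-12, n), seed = 2)
  expect_true(all(is.na(d1$matrix$a1)))

  expect_error(apply_allelic_dropout(p$matrix, p$truth,
                                     q_law = function(n) rep(1.2, n)),
               "support")

  d <- apply_allelic_dropout(p$matrix, p$truth, seed = 4)
  # silenced cells are exactly the new missing ones; miscalls are homozygous
  newly_missing <- is.na(d$matrix$a1) & !is.na(p$matrix$a1)
  expect_equal(which(newly_missing), which(d$truth$dropout$silenced))
  mc <- d$truth$dropout$miscalled
  expect_true(all(d$matrix$a1[mc] == d$matrix$a2[mc]))
  # a miscall keeps one of the original two alleles
  expect_true(all(d$matrix$a1[mc] == p$matrix$a1[mc] |
                  d$matrix$a1[mc] == p$matrix$a2[mc]))
})

test_that("dropout with MCAR contrast: only dropout biases filtered estimates", {
  # MCAR missingness: completeness-filtered estimates stay near the target
  p <- simulate_snp_panel(sim_config(n_loci = 2000, target_fst = 0.1, seed = 55))
  m <- apply_mcar(p$matrix, 0.3, seed = 56)
  lo <- filter_min_individuals(m, 10)
  hi <- filter_min_individuals(m, 77)
  fst_lo <- multilocus_stats(per_locus_stats(lo))$fst
  fst_hi <- multilocus_stats(per_locus_stats(hi))$fst
  expect_lt(abs(fst_lo - fst_hi), 0.02)
  expect_lt(abs(fst_lo - 0.1), 0.025)

  # allelic dropout: the loose-cutoff estimate is inflated
  d <- apply_allelic_dropout(p$matrix, p$truth, seed = 57)
  dlo <- multilocus_stats(per_locus_stats(filter_min_individuals(d$matrix, 10)))$fst
  dhi <- multilocus_stats(per_locus_stats(filter_min_individuals(d$matrix, 77)))$fst
  expect_gt(dlo, dhi)
})
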