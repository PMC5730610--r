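test_that("hand-worked two-population example matches the formulas exactly", {
  st <- per_locus_stats(hand_example_gm())
  expect_equal(st$ho, 0.25)
  expect_equal(st$hs, 0.25)
  expect_equal(st$ht, 0.5)
  expect_equal(st$fst, 0.5)
  expect_equal(st$fis, 0)
  expect_true(st$fst_defined && st$fis_defined)
})

test_that("per-locus and multilocus statistics agree with the brute-force oracle", {
  for (s in 1:4) {
    gm <- random_gm(n_ind = 18, n_loci = 25, n_pops = 3, miss = 0.35,
                    seed = s, max_allele = if (s %% 2) 1 else 3)
    pls <- per_locus_stats(gm)
    for (j in seq_len(n_loci(gm))) {
      o <- oracle_locus_stats(gm, j)
      expect_equal(pls$np_used[j], o$np)
      if (o$np > 0) {
        expect_equal(pls$ho[j], o$ho, tolerance = 1e-12)
        expect_equal(pls$hs[j], o$hs, tolerance = 1e-12)
      }
      if (!is.na(o$ht)) expect_equal(pls$ht[j], o$ht, tolerance = 1e-12)
      if (!is.na(o$fst)) expect_equal(pls$fst[j], o$fst, tolerance = 1e-12)
    }
    ml <- multilocus_stats(pls)
    om <- oracle_multilocus(gm)
    expect_equal(ml$fst, om$fst, tolerance = 1e-12)
    expect_equal(ml$fis, om$fis, tolerance = 1e-12)
  }
})

test_that("degenerate loci are flagged undefined, never silently zero", {
  # polymorphic between pops but all homozygous: ho = 0, fis = 1
  gm <- gm_from_strings(matrix(c("0/0", "0/0", "1/1", "0/0"), 4, 1),
                        pop = c("A", "A", "B", "B"))
  st <- per_locus_stats(gm)
  expect_equal(st$ho, 0)
  expect_equal(st$fis, 1)

  # typed in a single population: fst undefined, not an exception
  one <- gm_from_strings(matrix(c("0/1", "0/0", ".", "."), 4, 1),
                         pop = c("A", "A", "B", "B"))
  st1 <- per_locus_stats(one)
  expect_false(st1$fst_defined)
  expect_true(is.na(st1$fst))
  expect_equal(st1$np_used, 1)

  # identical populations: fst within the small-sample correction of zero
  calls <- matrix(rep(c("0/0", "0/1", "1/1", "0/1"), 2), 8, 1)
  same <- gm_from_strings(calls, pop = rep(c("A", "B"), each = 4))
  expect_lt(abs(per_locus_stats(same)$fst), 0.15)
})

test_that("multilocus aggregation is ratio-of-averages", {
  tbl <- tibble::tibble(ho = c(0.1, 0.3), hs = c(0.2, 0.4), ht = c(0.4, 0.4))
  ml <- multilocus_stats(tbl)
  expect_equal(ml$fst, (0.4 - 0.3) / 0.4)      # 0.25, not mean of ratios
  expect_equal(ml$fis, 1 - 0.2 / 0.3)
  # single locus: identity
  one <- per_locus_stats(hand_example_gm())
  expect_equal(multilocus_stats(one)$fst, one$fst)
  expect_error(multilocus_stats(tibble::tibble(ho = NA_real_, hs = NA_real_,
                                               ht = NA_real_)), "no locus")
})

test_that("Weir-Cockerham theta: fixation, identity and oracle agreement", {
  # fixed difference, n = 10 per pop: theta = 1
  fixed <- gm_from_strings(matrix(rep(c("0/0", "1/1"), each = 10), 20, 1),
                           pop = rep(c("A", "B"), each = 10))
  expect_equal(wc_theta(fixed)$overall, 1)

  # identical populations at n = 50: |theta| near 0
  set.seed(31)
  g <- sample(c("0/0", "0/1", "1/1"), 50, TRUE, prob = c(.25, .5, .25))
  same <- gm_from_strings(matrix(rep(g, 2), 100, 1),
                          pop = rep(c("A", "B"), each = 50))
  expect_lt(abs(wc_theta(same)$overall), 0.05)

  # randomized panels against the loop oracle
  for (s in 1:3) {
    gm <- random_gm(n_ind = 15, n_loci = 20, n_pops = 3, miss = 0.3, seed = s,
                    max_allele = 2)
    wc <- wc_theta(gm)
    for (j in seq_len(n_loci(gm))) {
      o <- oracle_wc_locus(gm, j)
      if (!is.na(o$a)) {
        expect_equal(wc$per_locus$a[j], o$a, tolerance = 1e-12)
        expect_equal(wc$per_locus$abc[j], o$abc, tolerance = 1e-12)
      }
    }
  }
})

test_that("one-vs-rest pairwise F_ST pools the non-focal populations", {
  # two populations: pooling is the identity
  gm2 <- random_gm(n_ind = 12, n_loci = 15, n_pops = 2, miss = 0.2, seed = 5)
  expect_equal(pairwise_one_vs_rest(gm2, "pop1"),
               multilocus_stats(per_locus_stats(gm2))$fst)

  # three populations: equals brute force on an explicitly relabeled matrix
  gm3 <- random_gm(n_ind = 18, n_loci = 15, n_pops = 3, miss = 0.2, seed = 6)
  manual <- set_populations(gm3, ifelse(pop_of(gm3) == "pop2", "pop2", "other"))
  expect_equal(pairwise_one_vs_rest(gm3, "pop2"),
               oracle_multilocus(manual)$fst, tolerance = 1e-12)
  expect_error(pairwise_one_vs_rest(gm3, "nope"), "unknown focal")

  tab <- pairwise_fst_table(gm3)
  expect_equal(tab$population, populations(gm3))
  expect_equal(tab$fst[2], pairwise_one_vs_rest(gm3, "pop2"))
})

test_that("F_IS from heterozygosities follows (He - Ho)/He", {
  expect_equal(fis_from_het(0.4, 0.5), 0.2)
  expect_equal(fis_from_het(0.5, 0.4), -0.25)
  expect_equal(fis_from_het(0.3, 0.3), 0)
  expect_true(is.na(fis_from_het(0.2, 0)))
})

test_that("per-location statistics: symmetry, identity and HWE calibration", {
  gm <- random_gm(n_ind = 12, n_loci = 20, n_pops = 2, miss = 0.2, seed = 4)
  loc <- per_location_stats(gm)
  # fis identity holds exactly
  expect_equal(loc$fis, fis_from_het(loc$ho_for_fis, loc$hs))

  # all-heterozygote population has ho = 1
  het <- gm_from_strings(matrix("0/1", 4, 2), pop = rep("A", 4))
  expect_equal(per_location_stats(het)$ho, 1)

  # swapped genotype tables give swapped per-location values
  sw <- subset_individuals(gm, c(7:12, 1:6))
  sw <- set_populations(sw, rep(c("pop1", "pop2"), each = 6))
  locs <- per_location_stats(sw)
  expect_equal(locs$ho, loc$ho[c(2, 1)], tolerance = 1e-12)
  expect_equal(locs$fis, loc$fis[c(2, 1)], tolerance = 1e-12)

  # single population simulated under HWE at p = 0.5, n = 500: fis near 0
  set.seed(99)
  g <- paste0(rbinom(500, 1, 0.5), "/", rbinom(500, 1, 0.5))
  hwe <- gm_from_strings(matrix(g, 500, 1), pop = rep("A", 500))
  expect_lt(abs(per_location_stats(hwe)$fis), 0.05)
})

test_that("statistic histograms bin half-open intervals and tally extremes", {
  h <- stat_histogram(c(0, 0.5, 1), bin_width = 0.5)
  expect_equal(h$bins$bin_lo, c(0, 0.5, 1))
  expect_equal(h$bins$count, c(1, 1, 1))
  expect_equal(h$n_extreme, 1)

  h2 <- stat_histogram(c(NA, NA, NA))
  expect_equal(nrow(h2$bins), 0)
  expect_equal(h2$n_undefined, 3)

  h3 <- stat_histogram(c(-0.12, 0.02, 0.98, 0.99), bin_width = 0.05,
                       extreme_threshold = 0.975)
  expect_equal(h3$n_extreme, 2)
  expect_equal(sum(h3$bins$count), 4)
  expect_equal(h3$bins$bin_lo[1], -0.15)
})

test_that("statistics are invariant to shuffling and to dropping untyped rows", {
  gm <- random_gm(n_ind = 16, n_loci = 12, n_pops = 4, miss = 0.3, seed = 10)
  ml <- multilocus_stats(per_locus_stats(gm))

  set.seed(1)
  # shuffle individuals within populations, reorder loci
  ord <- unlist(lapply(populations(gm), function(p) {
    sample(which(unname(pop_of(gm)) == p))
  }))
  perm <- subset_loci(subset_individuals(gm, ord), sample(loci(gm)))
  mlp <- multilocus_stats(per_locus_stats(perm))
  expect_equal(mlp$fst, ml$fst, tolerance = 1e-12)
  expect_equal(mlp$fis, ml$fis, tolerance = 1e-12)
  expect_equal(wc_theta(perm)$overall, wc_theta(gm)$overall, tolerance = 1e-12)

  # deleting a fully untyped individual changes nothing
  gm2 <- gm
  gm2$a1[3, ] <- NA_integer_; gm2$a2[3, ] <- NA_integer_
  gm2 <- geno_mat(gm2$a1, gm2$a2, pop = gm2$pop)
  dropped <- subset_individuals(gm2, setdiff(individuals(gm2),
                                             individuals(gm2)[3]))
  expect_equal(multilocus_stats(per_locus_stats(dropped)),
               multilocus_stats(per_locus_stats(gm2)))
  expect_equal(wc_theta(dropped)$overall, wc_theta(gm2)$overall)
})
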