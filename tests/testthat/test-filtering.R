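test_that("single-SNP selection keeps the first locus of each tag", {
  gm <- random_gm(n_ind = 4, n_loci = 6, seed = 2)
  gm <- geno_mat(gm$a1, gm$a2, pop = gm$pop,
                 tags = c("t1", "t1", "t2", "t3", "t2", "t3"))
  one <- select_single_snp(gm)
  expect_equal(loci(one), c("loc1", "loc3", "loc4"))
  expect_setequal(unname(one$tags), unname(unique(gm$tags)))

  # singleton tags: identity
  single <- geno_mat(gm$a1, gm$a2, pop = gm$pop, tags = paste0("u", 1:6))
  expect_equal(loci(select_single_snp(single)), loci(single))

  # randomized tag assignment: output tag set equals input tag set
  for (s in 1:3) {
    rgm <- random_gm(n_ind = 4, n_loci = 20, seed = s, tags = TRUE)
    out <- select_single_snp(rgm)
    expect_setequal(unname(out$tags), unname(unique(rgm$tags)))
    expect_false(anyDuplicated(out$tags) > 0)
  }

  expect_error(select_single_snp(random_gm(seed = 1)), "tag")
})

test_that("MAF filter uses pooled typed alleles with a strict threshold", {
  # 3 minor copies among 40 alleles = 0.075 > 0.05: retained
  calls <- matrix("0/0", 20, 1)
  calls[1:3, 1] <- "0/1"
  gm <- gm_from_strings(calls, pop = rep(c("A", "B"), each = 10))
  expect_equal(n_loci(filter_maf(gm, 0.05)), 1)
  expect_equal(pooled_maf(gm)$maf, 0.075)

  # monomorphic locus removed even at maf_min = 0
  mono <- gm_from_strings(matrix("1/1", 4, 1), pop = rep("A", 4))
  expect_equal(n_loci(filter_maf(mono, 0)), 0)

  # exact boundary is excluded (strict >)
  calls <- matrix("0/0", 10, 1); calls[1, 1] <- "1/1"   # maf exactly 0.1
  gmb <- gm_from_strings(calls, pop = rep("A", 10))
  expect_equal(n_loci(filter_maf(gmb, 0.1)), 0)
  expect_equal(n_loci(filter_maf(gmb, 0.099)), 1)

  # random panels: every retained locus beats the threshold by direct recount
  for (s in 1:3) {
    rgm <- random_gm(n_ind = 10, n_loci = 30, miss = 0.3, seed = s)
    kept <- filter_maf(rgm, 0.2)
    for (l in loci(kept)) {
      al <- c(kept$a1[, l], kept$a2[, l])
      al <- al[!is.na(al)]
      expect_gt(1 - max(table(al)) / length(al), 0.2)
    }
    dropped <- setdiff(loci(rgm), loci(kept))
    for (l in dropped) {
      al <- c(rgm$a1[, l], rgm$a2[, l])
      al <- al[!is.na(al)]
      maf <- if (length(al) == 0 || length(unique(al)) < 2) 0 else
        1 - max(table(al)) / length(al)
      expect_lte(maf, 0.2)
    }
  }
})

test_that("completeness filter retains exactly the loci typed in >= k individuals", {
  gm <- random_gm(n_ind = 96, n_loci = 3, miss = 0, seed = 1, n_pops = 12)
  # force typed counts 96, 75, 10
  gm$a1[1:21, 2] <- NA_integer_; gm$a2[1:21, 2] <- NA_integer_
  gm$a1[1:86, 3] <- NA_integer_; gm$a2[1:86, 3] <- NA_integer_
  gm <- geno_mat(gm$a1, gm$a2, pop = gm$pop)
  expect_equal(n_loci(filter_min_individuals(gm, 75)), 2)
  expect_equal(n_loci(filter_min_individuals(gm, 1)), 3)
  expect_equal(n_loci(filter_min_individuals(gm, 96)), 1)
  expect_error(filter_min_individuals(gm, 0), "k")
  expect_error(filter_min_individuals(gm, 97), "k")

  # random missingness: retained set equals a brute-force scan
  for (s in 1:3) {
    rgm <- random_gm(n_ind = 12, n_loci = 40, miss = 0.5, seed = s)
    k <- 6
    kept <- loci(filter_min_individuals(rgm, k))
    brute <- loci(rgm)[sapply(loci(rgm), function(l) {
      sum(!is.na(rgm$a1[, l])) >= k
    })]
    expect_equal(kept, brute)
  }
})

test_that("dataset family reproduces the percent-required arithmetic and summaries", {
  gm <- random_gm(n_ind = 96, n_loci = 50, n_pops = 12, miss = 0.4, seed = 8)
  fam <- build_dataset_family(gm, cutoffs = c(83, 75, 65, 50, 30, 1))
  expect_equal(fam$summary$pct_individuals_required,
               c(1.0, 31.3, 52.1, 67.7, 78.1, 86.5))
  # n_loci non-increasing with cutoff; missingness non-increasing too
  expect_true(all(diff(fam$summary$n_loci) <= 0))
  expect_true(all(diff(fam$summary$pct_missing_cells) <= 0))
  expect_error(build_dataset_family(gm, c(10, 10)), "duplicate")

  # fully typed matrix: all members identical, no missing cells
  full <- random_gm(n_ind = 10, n_loci = 6, miss = 0, seed = 2)
  fam2 <- build_dataset_family(full, c(1, 5, 10))
  expect_true(all(fam2$summary$n_loci == 6))
  expect_true(all(fam2$summary$pct_missing_cells == 0))
})

test_that("family members are nested and filters are idempotent", {
  for (s in 1:3) {
    gm <- random_gm(n_ind = 24, n_loci = 60, miss = 0.5, seed = s, n_pops = 4)
    fam <- build_dataset_family(gm, c(4, 12, 20))
    l1 <- loci(fam$members[[1]]); l2 <- loci(fam$members[[2]])
    l3 <- loci(fam$members[[3]])
    expect_true(all(l3 %in% l2))
    expect_true(all(l2 %in% l1))
    # idempotence
    m <- fam$members[[2]]
    expect_equal(loci(filter_min_individuals(m, 12)), loci(m))
    fm <- filter_maf(gm, 0.1)
    expect_equal(loci(filter_maf(fm, 0.1)), loci(fm))
  }
})
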