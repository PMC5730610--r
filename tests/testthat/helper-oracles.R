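# Brute-force reference implementations, written as plain loops straight
# from the formulas and kept independent of the package's vectorised code
# paths. Used as oracles for the estimator tests.

# per-locus gene-diversity statistics for locus j of a geno_mat
oracle_locus_stats <- function(gm, j) {
  pops <- unique(unname(gm$pop))
  per_pop <- list()
  for (p in pops) {
    rows <- which(unname(gm$pop) == p)
    g1 <- gm$a1[rows, j]
    g2 <- gm$a2[rows, j]
    keep <- !is.na(g1)
    g1 <- g1[keep]; g2 <- g2[keep]
    n <- length(g1)
    if (n < 2) next                       # excluded: unbiased Hs needs n >= 2
    ho <- mean(g1 != g2)
    alleles <- c(g1, g2)
    freqs <- sapply(sort(unique(c(gm$a1[, j], gm$a2[, j]))), function(a) {
      mean(alleles == a)
    })
    hs <- n / (n - 1) * (1 - sum(freqs^2) - ho / (2 * n))
    per_pop[[p]] <- list(n = n, ho = ho, hs = hs, freqs = freqs)
  }
  np <- length(per_pop)
  if (np == 0) {
    return(list(np = 0, ho = NA, hs = NA, ht = NA, fst = NA, fis = NA))
  }
  ho <- mean(sapply(per_pop, `[[`, "ho"))
  hs <- mean(sapply(per_pop, `[[`, "hs"))
  if (np < 2) {
    return(list(np = np, ho = ho, hs = hs, ht = NA, fst = NA,
                fis = if (hs > 0) 1 - ho / hs else NA))
  }
  nharm <- np / sum(1 / sapply(per_pop, `[[`, "n"))
  pbar <- rowMeans(sapply(per_pop, `[[`, "freqs"))
  ht <- 1 - sum(pbar^2) + hs / (nharm * np) - ho / (2 * nharm * np)
  list(np = np, ho = ho, hs = hs, ht = ht,
       fst = if (ht > 0) (ht - hs) / ht else NA,
       fis = if (hs > 0) 1 - ho / hs else NA)
}

# multilocus ratio-of-averages from the per-locus oracle
oracle_multilocus <- function(gm) {
  per <- lapply(seq_len(ncol(gm$a1)), function(j) oracle_locus_stats(gm, j))
  ho <- sapply(per, `[[`, "ho"); hs <- sapply(per, `[[`, "hs")
  ht <- sapply(per, `[[`, "ht")
  ho_bar <- mean(ho[!is.na(ho)])
  hs_bar <- mean(hs[!is.na(hs)])
  ht_bar <- mean(ht[!is.na(ht)])
  list(ho = ho_bar, hs = hs_bar, ht = ht_bar,
       fst = (ht_bar - hs_bar) / ht_bar, fis = 1 - ho_bar / hs_bar)
}

# Weir-Cockerham variance components for locus j, plain loops
oracle_wc_locus <- function(gm, j) {
  pops <- unique(unname(gm$pop))
  dat <- list()
  for (p in pops) {
    rows <- which(unname(gm$pop) == p)
    g1 <- gm$a1[rows, j]; g2 <- gm$a2[rows, j]
    keep <- !is.na(g1)
    if (sum(keep) < 2) next
    dat[[p]] <- cbind(g1[keep], g2[keep])
  }
  r <- length(dat)
  if (r < 2) return(list(a = NA, abc = NA))
  ns <- sapply(dat, nrow)
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  alleles <- sort(unique(unlist(dat)))
  a_sum <- 0; abc_sum <- 0
  for (al in alleles) {
    pk <- sapply(dat, function(m) mean(m == al))
    hk <- sapply(dat, function(m) mean((m[, 1] == al) != (m[, 2] == al)))
    pbar <- sum(ns * pk) / sum(ns)
    s2 <- sum(ns * (pk - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hk) / sum(ns)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  list(a = a_sum, abc = abc_sum)
}
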