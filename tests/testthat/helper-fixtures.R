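# Small fixture builders used across the suite. Everything is generated in
# code; no binary fixtures.

# geno_mat from a compact spec: calls is a character matrix/vector with
# entries like "0/1" or "." (missing), individuals in rows.
gm_from_strings <- function(calls, pop, ids = NULL, loci = NULL, tags = NULL) {
  calls <- as.matrix(calls)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(calls)))
  a1 <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = list(ids, loci))
  a2 <- a1
  typed <- calls != "."
  if (any(typed)) {
    parts <- do.call(rbind, strsplit(calls[typed], "/", fixed = TRUE))
    a1[typed] <- as.integer(parts[, 1])
    a2[typed] <- as.integer(parts[, 2])
  }
  geno_mat(a1, a2, pop = pop, tags = tags)
}

# randomized small panel, independent of the package's simulator: biallelic
# calls with uniform allele frequency per locus and MCAR-style missing cells
random_gm <- function(n_ind = 8, n_loci = 12, n_pops = 2, miss = 0.2,
                      seed = 1, tags = FALSE, max_allele = 1) {
  set.seed(seed)
  ids <- paste0("s", seq_len(n_ind))
  locs <- paste0("loc", seq_len(n_loci))
  a1 <- matrix(sample(0:max_allele, n_ind * n_loci, TRUE), n_ind, n_loci,
               dimnames = list(ids, locs))
  a2 <- matrix(sample(0:max_allele, n_ind * n_loci, TRUE), n_ind, n_loci,
               dimnames = list(ids, locs))
  drop <- matrix(runif(n_ind * n_loci) < miss, n_ind, n_loci)
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  pop <- rep(paste0("pop", seq_len(n_pops)), length.out = n_ind)
  tg <- if (tags) paste0("tag", sample(ceiling(n_loci / 2), n_loci, TRUE)) else NULL
  geno_mat(a1, a2, pop = sort(pop), tags = tg)
}

# two-population hand example used for the estimator worked example:
# pop1 = {A/A, A/a}, pop2 = {a/a, a/a}  (A = 0, a = 1)
hand_example_gm <- function() {
  gm_from_strings(matrix(c("0/0", "0/1", "1/1", "1/1"), 4, 1),
                  pop = c("p1", "p1", "p2", "p2"))
}
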