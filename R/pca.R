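#' Genotype principal component analysis
#'
#' Standard SNP PCA on the alternate-allele dosage matrix (0/1/2 copies of
#' allele 1 at biallelic loci). Missing dosages are imputed to the locus
#' mean, each locus is centered by twice its mean allele frequency, and —
#' with `scaling = "unit"` (the default, the usual SNP-PCA normalisation) —
#' scaled by `sqrt(p(1 - p))`. Scores come from the eigen-decomposition of
#' the individual-by-individual covariance of the standardized dosages.
#' Because missing cells are imputed to the mean, an individual typed at no
#' locus lands at the origin. Loci with more than two observed alleles are
#' either dropped with a warning (`multiallelic = "drop"`, default) or
#' one-hot expanded into per-allele dosages (`"expand"`, for microsatellite
#' panels).
#'
#' @param gm A [geno_mat()] with at least 2 individuals.
#' @param n_components Number of components to return (default 4; capped at
#'   `min(n_ind, loci used)`).
#' @param scaling `"unit"` or `"none"`.
#' @param multiallelic `"drop"` or `"expand"`.
#' @return An object of class `pca_result`: `scores` (tibble `individual`,
#'   `population`, `PC1`, ...), `explained_variance` (per returned
#'   component), `eigenvalues` (all), `total_variance` (trace of the
#'   centered covariance), `loci_used`, `scaling`, `imputation` (`"mean"`).
#'   See [tidy.pca_result()], [glance.pca_result()], [autoplot.pca_result()].
#' @examples
#' gm <- simulate_snp_panel(sim_config(n_pops = 2, n_per_pop = 10,
#'                                     n_loci = 500, target_fst = 0.2,
#'                                     seed = 3))$matrix
#' pca_genotypes(gm, n_components = 2)
#' @export
pca_genotypes <- function(gm, n_components = 4, scaling = c("unit", "none"),
                          multiallelic = c("drop", "expand")) {
  scaling <- match.arg(scaling)
  multiallelic <- match.arg(multiallelic)
  if (n_ind(gm) < 2) stop("need at least 2 individuals", call. = FALSE)
  n_obs_alleles <- pooled_maf(gm)$n_alleles
  bi <- n_obs_alleles <= 2
  X <- NULL
  col_locus <- character()
  if (multiallelic == "drop") {
    if (any(!bi)) {
      warning(sprintf("%d multiallelic locus/loci dropped from PCA", sum(!bi)))
    }
    keep <- which(bi & n_obs_alleles > 0)
    if (length(keep) > 0) {
      sub <- subset_loci(gm, keep)
      # dosage = copies of the larger observed allele code
      alt <- apply(rbind(sub$a1, sub$a2), 2, function(x) {
        max(x[!is.na(x)])
      })
      X <- (sub$a1 == matrix(alt, n_ind(sub), n_loci(sub), byrow = TRUE)) +
        (sub$a2 == matrix(alt, n_ind(sub), n_loci(sub), byrow = TRUE))
      col_locus <- loci(sub)
    }
  } else {
    # one-hot expansion: one dosage column per (locus, allele)
    cols <- list()
    for (j in seq_len(n_loci(gm))) {
      al <- sort(unique(c(gm$a1[, j], gm$a2[, j])))
      al <- al[!is.na(al)]
      if (length(al) < 2) next
      for (a in al) {
        cols[[length(cols) + 1L]] <- (gm$a1[, j] == a) + (gm$a2[, j] == a)
        col_locus <- c(col_locus, loci(gm)[j])
      }
    }
    if (length(cols) > 0) X <- do.call(cbind, cols)
  }
  if (is.null(X) || ncol(X) == 0) stop("no usable locus for PCA", call. = FALSE)
  storage.mode(X) <- "double"
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1
  if (!any(poly)) stop("no polymorphic locus for PCA (no variance)", call. = FALSE)
  X <- X[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  used <- unique(col_locus[poly])
  # mean imputation, then center by 2p; imputed cells land exactly at 0
  mu <- matrix(2 * p_hat, nrow(X), ncol(X), byrow = TRUE)
  X[is.na(X)] <- mu[is.na(X)]
  X <- X - mu
  if (scaling == "unit") {
    X <- sweep(X, 2, sqrt(p_hat * (1 - p_hat)), "/")
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  total <- sum(eig)
  k <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(individual = individuals(gm), population = unname(gm$pop)),
    scores
  )
  structure(list(
    scores = scores,
    explained_variance = eig[seq_len(k)] / total,
    eigenvalues = eig,
    total_variance = total,
    loci_used = used,
    n_loci_used = length(used),
    scaling = scaling,
    imputation = "mean"
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d individuals, %d loci, scaling '%s', mean imputation\n",
    nrow(x$scores), x$n_loci_used, x$scaling
  ))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Tidy and glance methods for genotype PCA
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return `tidy()` returns the score table (one row per individual);
#'   `glance()` a one-row summary (`n_individuals`, `n_loci_used`,
#'   `n_components`, `pve_pc1`, `pve_pc2`, `total_variance`, `scaling`).
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @rdname tidy.pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$scores),
    n_loci_used = x$n_loci_used,
    n_components = length(x$explained_variance),
    pve_pc1 = x$explained_variance[1],
    pve_pc2 = if (length(x$explained_variance) >= 2) x$explained_variance[2] else NA_real_,
    total_variance = x$total_variance,
    scaling = x$scaling
  )
}
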