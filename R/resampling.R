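#' @keywords internal
#' Per-locus component table for a multilocus statistic. Every multilocus
#' statistic here is a ratio of per-locus sums/means, so resampling loci and
#' recomputing the statistic only needs this table, not the genotypes.
locus_component_table <- function(gm, statistic) {
  if (statistic == "theta") {
    wc_theta(gm)$per_locus
  } else {
    per_locus_stats(gm)
  }
}

#' @keywords internal
#' Ratio-of-averages aggregation of a component table (or a row subset of
#' one) into a single multilocus value. Returns NA when undefined.
aggregate_components <- function(tbl, statistic) {
  if (statistic == "theta") {
    ok <- tbl$defined
    if (!any(ok)) return(NA_real_)
    return(sum(tbl$a[ok]) / sum(tbl$abc[ok]))
  }
  ms <- multilocus_stats(tbl)
  ms[[statistic]]
}

new_resampling_result <- function(statistic, values, point, alpha, seed,
                                  n_redrawn = 0L, kind = "bootstrap") {
  qs <- stats::quantile(values, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  structure(list(
    statistic = statistic, kind = kind,
    replicate_values = values,
    point_estimate = point,
    ci_low = qs[1], ci_high = qs[2],
    n_replicates = length(values), alpha = alpha, seed = seed,
    n_redrawn = n_redrawn
  ), class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "<resampling_result> %s of %s: point %.4f, %d%% CI [%.4f, %.4f] (%d replicates, seed %d)\n",
    x$kind, x$statistic, x$point_estimate, round(100 * (1 - x$alpha)),
    x$ci_low, x$ci_high, x$n_replicates, x$seed
  ))
  invisible(x)
}

#' Percentile bootstrap CI for a multilocus statistic
#'
#' Resamples loci with replacement (same locus count), recomputes the
#' multilocus statistic on each replicate, and returns the percentile
#' confidence interval — loci are treated as exchangeable, the standard
#' bootstrap unit for genome-wide F-statistics. Replicate `b` draws its loci
#' under seed `seed + b` (redraw attempt `t` of a replicate whose statistic
#' is undefined uses `seed + b + t * B`), so any replicate can be reproduced
#' in isolation. Undefined replicates are redrawn rather than dropped, with
#' a hard cap of `10 * B` total redraws.
#'
#' @param gm A [geno_mat()].
#' @param statistic One of `"fst"`, `"fis"`, `"ho"`, `"hs"`, `"ht"`
#'   (gene-diversity estimators) or `"theta"` (Weir-Cockerham).
#' @param B Number of bootstrap replicates (default 1000).
#' @param alpha Two-sided miscoverage; default 0.05 for a 95% CI.
#' @param seed Integer seed.
#' @return A `resampling_result`: replicate values, point estimate (on the
#'   full locus set), closed percentile interval `[ci_low, ci_high]`,
#'   replicate count and seed. See [tidy.resampling_result()] /
#'   [glance.resampling_result()].
#' @examples
#' gm <- simulate_snp_panel(sim_config(n_loci = 300, seed = 2))$matrix
#' bootstrap_ci(gm, "fst", B = 200, seed = 9)
#' @export
bootstrap_ci <- function(gm, statistic = "fst", B = 1000, alpha = 0.05,
                         seed = 1) {
  statistic <- match.arg(statistic, c("fst", "fis", "ho", "hs", "ht", "theta"))
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  tbl <- locus_component_table(gm, statistic)
  point <- aggregate_components(tbl, statistic)
  L <- nrow(tbl)
  values <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    t <- 0L
    repeat {
      v <- with_seed(seed + b + t * B, {
        idx <- sample.int(L, L, replace = TRUE)
        aggregate_components(tbl[idx, , drop = FALSE], statistic)
      })
      if (!is.na(v)) break
      t <- t + 1L
      redraws <- redraws + 1L
      if (redraws > 10L * B) {
        stop("statistic undefined on too many bootstrap replicates", call. = FALSE)
      }
    }
    values[b] <- v
  }
  if (redraws > 0) {
    warning(sprintf("%d bootstrap replicate(s) redrawn (undefined statistic)",
                    redraws))
  }
  new_resampling_result(statistic, values, point, alpha, seed, redraws)
}

#' Locus-subsampling experiment
#'
#' The experiment that separates the effect of locus count from the effect
#' of missingness: for each requested size, loci are drawn from the full
#' panel without replacement `reps` times (default 100) and the multilocus
#' statistic recomputed per draw. The replicate distribution for each size
#' is compared against the full panel's estimate and bootstrap CI, and
#' optionally against a supplied reference (e.g. the estimate and CI of the
#' completeness-filtered dataset of the same size). Draw `r` for the `s`-th
#' size uses seed `seed + (s - 1) * reps + r`.
#'
#' @param gm_full A [geno_mat()] — the full (least-filtered) panel.
#' @param sizes Integer vector of subsample sizes, each `<= n_loci(gm_full)`.
#' @param reps Draws per size (default 100).
#' @param statistic As in [bootstrap_ci()].
#' @param seed Integer seed.
#' @param B,alpha Bootstrap settings for the full panel's reference CI.
#' @param reference Optional named list of `resampling_result`s (or lists
#'   with `point_estimate`, `ci_low`, `ci_high`), one per size (names
#'   `"size_<n>"`), to compare each size's distribution against.
#' @return An object of class `subsample_experiment`: `full` (the full
#'   panel's `resampling_result`), `by_size` (named list of
#'   `resampling_result`s of kind `"subsample"`, point estimate = replicate
#'   mean), and `summary`, a tibble with one row per size: `size`, `mean`,
#'   `ci_low`, `ci_high` (percentile interval of the replicate
#'   distribution), `frac_in_full_ci`, `overlaps_full_ci`, and — when a
#'   reference is given — `ref_estimate`, `ref_ci_low`, `ref_ci_high`,
#'   `frac_in_ref_ci`, `overlaps_ref_ci`.
#' @export
subsample_experiment <- function(gm_full, sizes, reps = 100,
                                 statistic = "fst", seed = 1,
                                 B = 1000, alpha = 0.05, reference = NULL) {
  statistic <- match.arg(statistic, c("fst", "fis", "ho", "hs", "ht", "theta"))
  stopifnot(reps >= 1)
  tbl <- locus_component_table(gm_full, statistic)
  L <- nrow(tbl)
  if (any(sizes > L)) {
    stop(sprintf("subsample size exceeds available loci (%d)", L), call. = FALSE)
  }
  full <- bootstrap_ci(gm_full, statistic, B = B, alpha = alpha, seed = seed)
  by_size <- list()
  rows <- list()
  for (s in seq_along(sizes)) {
    size <- sizes[s]
    values <- vapply(seq_len(reps), function(r) {
      with_seed(seed + (s - 1L) * reps + r, {
        idx <- sample.int(L, size, replace = FALSE)
        aggregate_components(tbl[idx, , drop = FALSE], statistic)
      })
    }, numeric(1))
    res <- new_resampling_result(statistic, values, mean(values, na.rm = TRUE),
                                 alpha, seed, kind = "subsample")
    by_size[[paste0("size_", size)]] <- res
    inside_full <- mean(values >= full$ci_low & values <= full$ci_high,
                        na.rm = TRUE)
    row <- tibble::tibble(
      size = size, mean = res$point_estimate,
      ci_low = res$ci_low, ci_high = res$ci_high,
      frac_in_full_ci = inside_full,
      overlaps_full_ci = ci_overlap(res, full)$overlap
    )
    ref <- reference[[paste0("size_", size)]]
    if (!is.null(ref)) {
      ov <- ci_overlap(res, ref)
      row$ref_estimate <- ref$point_estimate
      row$ref_ci_low <- ref$ci_low
      row$ref_ci_high <- ref$ci_high
      row$frac_in_ref_ci <- ov$frac_a_in_b
      row$overlaps_ref_ci <- ov$overlap
    }
    rows[[s]] <- row
  }
  structure(list(full = full, by_size = by_size,
                 summary = dplyr::bind_rows(rows), statistic = statistic,
                 seed = seed),
            class = "subsample_experiment")
}

#' @export
print.subsample_experiment <- function(x, ...) {
  cat(sprintf("<subsample_experiment> statistic %s, full-panel point %.4f, CI [%.4f, %.4f]\n",
              x$statistic, x$full$point_estimate, x$full$ci_low, x$full$ci_high))
  print(x$summary)
  invisible(x)
}

#' Do two confidence intervals overlap?
#'
#' Intervals are closed: a shared endpoint counts as overlap, and a
#' replicate equal to a bound counts as inside.
#'
#' @param a,b `resampling_result`s (or lists with `ci_low`, `ci_high`, and
#'   for `a` optionally `replicate_values`).
#' @return A list: `overlap` (logical) and `frac_a_in_b`, the fraction of
#'   `a`'s replicate values inside `b`'s interval (`NA` if `a` carries no
#'   replicates).
#' @export
ci_overlap <- function(a, b) {
  if (is.na(a$ci_low) || is.na(b$ci_low)) {
    stop("both intervals must be defined", call. = FALSE)
  }
  overlap <- a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
  frac <- if (!is.null(a$replicate_values)) {
    mean(a$replicate_values >= b$ci_low & a$replicate_values <= b$ci_high,
         na.rm = TRUE)
  } else NA_real_
  list(overlap = overlap, frac_a_in_b = frac)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for resampling results
#'
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @return `tidy()` returns one row per replicate (`replicate`, `value`);
#'   `glance()` a one-row summary (`statistic`, `kind`, `point_estimate`,
#'   `ci_low`, `ci_high`, `n_replicates`, `alpha`, `seed`).
#' @export
tidy.resampling_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicate_values),
                 value = x$replicate_values)
}

#' @rdname tidy.resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, kind = x$kind,
                 point_estimate = x$point_estimate,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_replicates = x$n_replicates, alpha = x$alpha, seed = x$seed)
}

#' @rdname tidy.resampling_result
#' @export
tidy.subsample_experiment <- function(x, ...) {
  purrr::imap_dfr(x$by_size, function(res, nm) {
    tibble::tibble(size = as.integer(sub("size_", "", nm)),
                   replicate = seq_along(res$replicate_values),
                   value = res$replicate_values)
  })
}

#' @rdname tidy.resampling_result
#' @export
glance.subsample_experiment <- function(x, ...) x$summary
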