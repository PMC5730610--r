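#' Configuration for the end-to-end experiment
#'
#' Bundles every knob of [run_full_experiment()]: the input (a TSV genotype
#' matrix or a [sim_config()] to simulate one), the filter settings, the
#' estimator, resampling and PCA options, the seed, and the output
#' directory. The configuration is validated here, before any computation,
#' and serialized into the output directory for provenance.
#'
#' @param input Path to a TSV genotype matrix (the dialect of
#'   [write_matrix_tsv()]), or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param dropout Apply [apply_allelic_dropout()] to the simulated panel
#'   (ignored when reading from file).
#' @param cutoffs Completeness cutoffs for [build_dataset_family()];
#'   `NULL` defaults to `c(1, 0.3N, 0.5N, 0.8N)`.
#' @param maf Minor-allele-frequency threshold ([filter_maf()]).
#' @param single_snp Run [select_single_snp()] first (skipped with a note
#'   when the matrix carries no tags).
#' @param estimator `"nei"` or `"wc"`.
#' @param subsample_reps Draws per size in the locus-subsampling stage.
#' @param bootstrap_B,alpha Bootstrap settings.
#' @param pca_components,pca_scaling PCA settings.
#' @param seed Master seed; stage seeds are derived as documented offsets.
#' @param out_dir Output directory (created if absent).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = sim_config(), dropout = FALSE,
                       cutoffs = NULL, maf = 0.05, single_snp = TRUE,
                       estimator = c("nei", "wc"), subsample_reps = 100,
                       bootstrap_B = 1000, alpha = 0.05,
                       pca_components = 4, pca_scaling = "unit",
                       seed = 1, out_dir = tempfile("radfst_run_")) {
  estimator <- match.arg(estimator)
  if (is.null(input) && !inherits(sim, "sim_config")) {
    stop("either `input` or a `sim_config` is required", call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  stopifnot(maf >= 0, maf < 0.5, subsample_reps >= 1, bootstrap_B >= 1,
            alpha > 0, alpha < 1, pca_components >= 1)
  structure(list(
    input = input, sim = sim, dropout = dropout, cutoffs = cutoffs,
    maf = maf, single_snp = single_snp, estimator = estimator,
    subsample_reps = subsample_reps, bootstrap_B = bootstrap_B,
    alpha = alpha, pca_components = pca_components,
    pca_scaling = pca_scaling, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

write_report_tsv <- function(df, path, hash) {
  writeLines(paste0("#config_hash=", hash), path)
  suppressMessages(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

stage_log <- function(name, in_shape, out_shape, t0) {
  message(sprintf("[radfst] stage=%s in=%s out=%s elapsed=%.2fs",
                  name, in_shape, out_shape,
                  as.numeric(Sys.time()) - as.numeric(t0)))
}

#' Run the full filtering / statistics / resampling / PCA experiment
#'
#' Wires the pipeline stages end to end: obtain a panel (simulated, with
#' optional allelic dropout, or read from file), apply the filter regime
#' (single SNP per tag, MAF, completeness-cutoff family), then emit, per
#' family member: multilocus statistics with bootstrap CIs, one-vs-rest
#' pairwise F_ST per location, per-location heterozygosity and F_IS,
#' per-locus statistic histograms, and PCA coordinates; plus a
#' locus-subsampling experiment drawing from the least-filtered member at
#' each of the other members' locus counts, compared against those members'
#' own estimates and CIs. All reports are plain TSV carrying the
#' configuration hash; a JSON manifest records the config, seeds and
#' package version. A failing stage aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `out_dir`, `family` (the summary tibble),
#'   `multilocus` (per-member multilocus stats + CI), `subsampling` (the
#'   summary tibble), `manifest_path`.
#' @export
run_full_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  stage <- "input"
  result <- tryCatch({
    t0 <- Sys.time()
    if (is.null(cfg$input)) {
      panel <- simulate_snp_panel(cfg$sim)
      if (cfg$dropout) {
        panel <- apply_allelic_dropout(panel$matrix, panel$truth,
                                       seed = cfg$seed + 1L)
      }
      gm <- panel$matrix
    } else {
      gm <- read_matrix_tsv(cfg$input)
    }
    stage_log("input", "-", sprintf("%dx%d", n_ind(gm), n_loci(gm)), t0)

    stage <- "filter"
    t0 <- Sys.time()
    if (cfg$single_snp && !is.null(gm$tags)) gm <- select_single_snp(gm)
    gm <- filter_maf(gm, cfg$maf)
    cutoffs <- cfg$cutoffs
    if (is.null(cutoffs)) {
      cutoffs <- unique(pmax(1L, as.integer(round(c(1, 0.3, 0.5, 0.8) * n_ind(gm)))))
    }
    fam <- build_dataset_family(gm, cutoffs)
    write_report_tsv(fam$summary, file.path(cfg$out_dir, "dataset_family.tsv"), hash)
    for (nm in names(fam$members)) {
      write_matrix_tsv(fam$members[[nm]],
                       file.path(cfg$out_dir, paste0("matrix_", nm, ".tsv")))
    }
    stage_log("filter", sprintf("%dx%d", n_ind(gm), n_loci(gm)),
              paste(fam$summary$n_loci, collapse = ","), t0)

    stage <- "stats"
    t0 <- Sys.time()
    multi_rows <- list()
    pair_rows <- list()
    loc_rows <- list()
    boots <- list()
    for (i in seq_along(fam$members)) {
      nm <- names(fam$members)[i]
      m <- fam$members[[i]]
      if (n_loci(m) == 0) next
      pls <- per_locus_stats(m)
      write_report_tsv(pls, file.path(cfg$out_dir, paste0("per_locus_", nm, ".tsv")), hash)
      stat_for <- if (cfg$estimator == "nei") "fst" else "theta"
      bt <- bootstrap_ci(m, stat_for, B = cfg$bootstrap_B, alpha = cfg$alpha,
                         seed = cfg$seed + 100L * i)
      boots[[paste0("size_", n_loci(m))]] <- bt
      multi_rows[[nm]] <- dplyr::bind_cols(
        tibble::tibble(dataset = nm, n_loci = n_loci(m),
                       pct_missing = 100 * mean(is.na(m$a1))),
        multilocus_stats(pls),
        tibble::tibble(fst_ci_low = bt$ci_low, fst_ci_high = bt$ci_high,
                       theta = wc_theta(m)$overall)
      )
      pair_rows[[nm]] <- dplyr::mutate(pairwise_fst_table(m, cfg$estimator),
                                       dataset = nm, .before = 1)
      loc_rows[[nm]] <- dplyr::mutate(per_location_stats(m),
                                      dataset = nm, .before = 1)
      for (st in c("fst", "fis", "ho")) {
        h <- stat_histogram(pls[[st]])
        write_report_tsv(
          dplyr::mutate(h$bins, statistic = st, n_extreme = h$n_extreme,
                        n_undefined = h$n_undefined),
          file.path(cfg$out_dir, paste0("hist_", st, "_", nm, ".tsv")), hash)
      }
    }
    multi <- dplyr::bind_rows(multi_rows)
    write_report_tsv(multi, file.path(cfg$out_dir, "multilocus_stats.tsv"), hash)
    write_report_tsv(dplyr::bind_rows(pair_rows),
                     file.path(cfg$out_dir, "pairwise_fst.tsv"), hash)
    write_report_tsv(dplyr::bind_rows(loc_rows),
                     file.path(cfg$out_dir, "per_location_stats.tsv"), hash)
    stage_log("stats", paste(names(fam$members), collapse = ","),
              sprintf("%d datasets", nrow(multi)), t0)

    stage <- "subsample"
    t0 <- Sys.time()
    full <- fam$members[[1]]              # least-filtered member
    sizes <- setdiff(fam$summary$n_loci[-1], 0)
    sub_summary <- NULL
    if (length(sizes) > 0 && n_loci(full) > 0) {
      sub <- subsample_experiment(full, sizes, reps = cfg$subsample_reps,
                                  statistic = if (cfg$estimator == "nei") "fst" else "theta",
                                  seed = cfg$seed + 10000L,
                                  B = cfg$bootstrap_B, alpha = cfg$alpha,
                                  reference = boots)
      sub_summary <- sub$summary
      write_report_tsv(tidy(sub), file.path(cfg$out_dir, "subsample_replicates.tsv"), hash)
      write_report_tsv(sub$summary, file.path(cfg$out_dir, "subsample_summary.tsv"), hash)
    }
    stage_log("subsample", paste(sizes, collapse = ","),
              sprintf("%d sizes", length(sizes)), t0)

    stage <- "pca"
    t0 <- Sys.time()
    for (nm in names(fam$members)) {
      m <- fam$members[[nm]]
      pc <- tryCatch(
        pca_genotypes(m, cfg$pca_components, scaling = cfg$pca_scaling),
        error = function(e) NULL
      )
      if (is.null(pc)) next
      coords <- dplyr::mutate(tidy(pc), dataset = nm, scaling = pc$scaling,
                              .before = 1)
      write_report_tsv(coords, file.path(cfg$out_dir, paste0("pca_", nm, ".tsv")), hash)
      write_report_tsv(
        tibble::tibble(component = seq_along(pc$explained_variance),
                       explained_variance = pc$explained_variance),
        file.path(cfg$out_dir, paste0("pca_variance_", nm, ".tsv")), hash)
    }
    stage_log("pca", sprintf("%d datasets", length(fam$members)), "coords", t0)

    manifest <- list(
      package = "radfst",
      version = as.character(utils::packageVersion("radfst")),
      config_hash = hash,
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), c("sim", "out_dir"))],
      sim = if (is.null(cfg$input)) unclass(cfg$sim) else NULL,
      defaults = list(
        estimator = cfg$estimator,
        hs_rule = "populations with < 2 typed individuals excluded per locus",
        aggregation = "ratio of per-locus averages",
        ci_method = "percentile, closed endpoints",
        pca = list(imputation = "mean dosage", scaling = cfg$pca_scaling)
      )
    )
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
    list(out_dir = cfg$out_dir, family = fam$summary, multilocus = multi,
         subsampling = sub_summary, manifest_path = manifest_path)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                 stage, conditionMessage(e), cfg$out_dir), call. = FALSE)
  })
  invisible(result)
}
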