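#' Diploid multi-population genotype matrix
#'
#' `geno_mat` is the package's core container: an individuals-by-loci table of
#' unordered diploid allele pairs with an explicit missing sentinel (`NA`),
#' a population label per individual, and an optional RAD-tag label per locus
#' (used by [select_single_snp()]). Allele codes are per-locus small
#' non-negative integers; loci are anonymous, so codes carry no meaning across
#' loci. Internally the calls are stored as two integer matrices with the
#' smaller allele first, which makes the pair unordered by construction.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each call; `NA` in both marks a missing call. Row names are
#'   individual IDs, column names are locus IDs.
#' @param pop Character or factor vector of population labels, one per
#'   individual (recycled names are taken from `a1` row names if unnamed).
#' @param tags Optional character vector of RAD-tag labels, one per locus.
#' @return An object of class `geno_mat`.
#' @examples
#' a1 <- matrix(c(0L, 0L, 1L, 1L), 2, 2, dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' a2 <- matrix(c(0L, 1L, 1L, 1L), 2, 2, dimnames = dimnames(a1))
#' gm <- geno_mat(a1, a2, pop = c("A", "B"))
#' gm
#' @export
geno_mat <- function(a1, a2, pop, tags = NULL) {
  if (!is.matrix(a1) || !is.matrix(a2) || !identical(dim(a1), dim(a2))) {
    stop("`a1` and `a2` must be matrices of identical dimension", call. = FALSE)
  }
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if ((nrow(a1) > 0 && is.null(rownames(a1))) ||
      (ncol(a1) > 0 && is.null(colnames(a1)))) {
    stop("`a1` must carry individual IDs as row names and locus IDs as column names",
         call. = FALSE)
  }
  rn <- rownames(a1); cn <- colnames(a1)
  dimnames(a1) <- list(if (is.null(rn)) character(0) else rn,
                       if (is.null(cn)) character(0) else cn)
  dimnames(a2) <- dimnames(a1)
  if (anyDuplicated(rownames(a1))) stop("duplicate individual IDs", call. = FALSE)
  if (anyDuplicated(colnames(a1))) stop("duplicate locus IDs", call. = FALSE)
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing calls are not allowed: `a1` and `a2` must be NA together",
         call. = FALSE)
  }
  if (any(a1 < 0L, na.rm = TRUE) || any(a2 < 0L, na.rm = TRUE)) {
    stop("allele codes must be non-negative integers", call. = FALSE)
  }
  # unordered pair: canonicalise so a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  pop <- as.character(pop)
  if (length(pop) != nrow(a1)) {
    stop("`pop` must give one population label per individual", call. = FALSE)
  }
  if (anyNA(pop)) stop("every individual must belong to a population", call. = FALSE)
  names(pop) <- rownames(a1)
  if (!is.null(tags)) {
    tags <- as.character(tags)
    if (length(tags) != ncol(a1)) {
      stop("`tags` must give one RAD-tag label per locus", call. = FALSE)
    }
    names(tags) <- colnames(a1)
  }
  structure(list(a1 = a1, a2 = a2, pop = pop, tags = tags), class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf(
    "<geno_mat> %d individuals x %d loci, %d populations, %.1f%% missing calls%s\n",
    n_ind(x), n_loci(x), length(unique(x$pop)), 100 * miss,
    if (is.null(x$tags)) "" else sprintf(", %d RAD tags", length(unique(x$tags)))
  ))
  invisible(x)
}

#' Dimensions and labels of a genotype matrix
#'
#' @param gm A [geno_mat()].
#' @return `n_ind()`/`n_loci()` return counts; `individuals()`, `loci()` and
#'   `populations()` return character vectors (`populations()` in first-seen
#'   order); `pop_of()` returns the named individual-to-population map.
#' @export
n_ind <- function(gm) nrow(gm$a1)

#' @rdname n_ind
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' @rdname n_ind
#' @export
individuals <- function(gm) rownames(gm$a1)

#' @rdname n_ind
#' @export
loci <- function(gm) colnames(gm$a1)

#' @rdname n_ind
#' @export
populations <- function(gm) unique(unname(gm$pop))

#' @rdname n_ind
#' @export
pop_of <- function(gm) gm$pop

#' Subset a genotype matrix
#'
#' Both functions preserve the order given in `keep` and carry the population
#' map and RAD tags along.
#'
#' @param gm A [geno_mat()].
#' @param keep Character vector of locus or individual IDs (or a
#'   logical/integer index into the current order).
#' @return A [geno_mat()].
#' @export
subset_loci <- function(gm, keep) {
  geno_mat(gm$a1[, keep, drop = FALSE], gm$a2[, keep, drop = FALSE],
           pop = gm$pop, tags = if (is.null(gm$tags)) NULL else gm$tags[keep])
}

#' @rdname subset_loci
#' @export
subset_individuals <- function(gm, keep) {
  geno_mat(gm$a1[keep, , drop = FALSE], gm$a2[keep, , drop = FALSE],
           pop = gm$pop[keep], tags = gm$tags)
}

#' Relabel populations
#'
#' @param gm A [geno_mat()].
#' @param new_pop Character vector of new population labels, one per
#'   individual (in the matrix's individual order), or — when shorter than
#'   the individual count — a named vector mapping old population labels to
#'   new ones.
#' @return A [geno_mat()].
#' @export
set_populations <- function(gm, new_pop) {
  if (length(new_pop) == n_ind(gm)) {
    return(geno_mat(gm$a1, gm$a2, pop = unname(new_pop), tags = gm$tags))
  }
  if (!is.null(names(new_pop))) {
    missing_lab <- setdiff(unique(gm$pop), names(new_pop))
    if (length(missing_lab) > 0) {
      stop("no new label for population(s): ", paste(missing_lab, collapse = ", "),
           call. = FALSE)
    }
    new_pop <- unname(new_pop[gm$pop])
  }
  geno_mat(gm$a1, gm$a2, pop = new_pop, tags = gm$tags)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a genotype matrix
#'
#' @param x A [geno_mat()].
#' @param ... Unused.
#' @return A tibble with one row per (individual, locus) cell and columns
#'   `individual`, `population`, `locus`, `allele1`, `allele2` (both `NA` for
#'   a missing call; `allele1 <= allele2`).
#' @export
as_tibble.geno_mat <- function(x, ...) {
  tibble::tibble(
    individual = rep(individuals(x), times = n_loci(x)),
    population = rep(unname(x$pop), times = n_loci(x)),
    locus = rep(loci(x), each = n_ind(x)),
    allele1 = as.integer(x$a1),
    allele2 = as.integer(x$a2)
  )
}

#' @method all.equal geno_mat
#' @export
all.equal.geno_mat <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

#' Per-locus typed-individual counts
#'
#' @param gm A [geno_mat()].
#' @return Named integer vector: for each locus, the number of individuals
#'   with a non-missing call.
#' @export
typed_per_locus <- function(gm) {
  colSums(!is.na(gm$a1))
}

#' Missingness bookkeeping for a genotype panel
#'
#' Summarises how missing calls are distributed over loci, individuals and
#' populations. The per-population figure is reported under two readings:
#' `rate_cells`, the fraction of missing (individual, locus) cells among the
#' population's members (the default reading), and `rate_loci_any`, the
#' fraction of loci missing in at least one of the population's members.
#'
#' @param gm A [geno_mat()].
#' @return A list of three tibbles: `per_locus` (`locus`, `n_typed`,
#'   `rate_missing`), `per_individual` (`individual`, `population`,
#'   `rate_missing`), `per_population` (`population`, `rate_cells`,
#'   `rate_loci_any`).
#' @examples
#' gm <- simulate_snp_panel(sim_config(n_pops = 2, n_per_pop = 4, n_loci = 10,
#'                                     target_fst = 0.1, seed = 1))$matrix
#' missingness_summary(gm)$per_population
#' @export
missingness_summary <- function(gm) {
  miss <- is.na(gm$a1)
  per_locus <- tibble::tibble(
    locus = loci(gm),
    n_typed = as.integer(colSums(!miss)),
    rate_missing = unname(colMeans(miss))
  )
  per_individual <- tibble::tibble(
    individual = individuals(gm),
    population = unname(gm$pop),
    rate_missing = unname(rowMeans(miss))
  )
  pops <- populations(gm)
  per_population <- tibble::tibble(
    population = pops,
    rate_cells = vapply(pops, function(p) {
      mean(miss[gm$pop == p, , drop = FALSE])
    }, 0, USE.NAMES = FALSE),
    rate_loci_any = vapply(pops, function(p) {
      mean(colSums(miss[gm$pop == p, , drop = FALSE]) > 0)
    }, 0, USE.NAMES = FALSE)
  )
  list(per_locus = per_locus, per_individual = per_individual,
       per_population = per_population)
}
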