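#' Read a population map
#'
#' A popmap is a headerless two-column TSV: individual ID, population label.
#' Population assignment is always explicit — it is never parsed out of
#' sample names.
#'
#' @param path Path to the popmap file.
#' @return A tibble with columns `individual` and `population`.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("individual", "population"))
  if (ncol(tab) != 2) stop("popmap must have exactly two columns", call. = FALSE)
  if (anyDuplicated(tab$individual)) {
    stop("duplicate individual in popmap: ",
         tab$individual[duplicated(tab$individual)][1], call. = FALSE)
  }
  tibble::as_tibble(tab)
}

resolve_popmap <- function(popmap, ids) {
  if (is.character(popmap) && length(popmap) == 1) popmap <- read_popmap(popmap)
  popmap <- as.data.frame(popmap)
  if (!all(c("individual", "population") %in% names(popmap))) {
    stop("popmap needs columns `individual` and `population`", call. = FALSE)
  }
  missing_ids <- setdiff(ids, popmap$individual)
  if (length(missing_ids) > 0) {
    stop("individual(s) absent from popmap: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(popmap$population, popmap$individual)[ids]
}

#' Read genotypes from a VCF file
#'
#' Builds a [geno_mat()] from the GT field of a diploid VCF. Allele codes
#' follow the VCF convention (REF = 0, i-th ALT = i). Phase separators are
#' accepted and discarded; `./.` and half-calls become missing. All other
#' FORMAT fields (DP, GQ, ...) are ignored: the analyses downstream start
#' from called genotypes. RAD-tag labels are taken from the CHROM column
#' (one tag per assembled RAD contig); when CHROM merely repeats the record
#' ID no tag information is present and `tags` is left `NULL`.
#'
#' @param path Path to a VCF (v4.x) file, plain text or bgzipped.
#' @param popmap Path to a popmap TSV or a data frame with columns
#'   `individual` and `population`; must cover every sample in the VCF.
#' @return A [geno_mat()].
#' @export
read_vcf <- function(path, popmap) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample in VCF: ", samples[duplicated(samples)][1], call. = FALSE)
  }
  chrom <- vcfR::getCHROM(vcf)
  id <- vcfR::getID(vcf)
  pos <- vcfR::getPOS(vcf)
  locus_ids <- ifelse(is.na(id) | id == ".", paste0(chrom, "_", pos), id)
  if (anyDuplicated(locus_ids)) {
    locus_ids <- make.unique(locus_ids, sep = "_dup")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  # rows = loci, cols = samples; parse into two allele matrices
  n_loc <- nrow(gt)
  a1 <- matrix(NA_integer_, length(samples), n_loc,
               dimnames = list(samples, locus_ids))
  a2 <- a1
  for (j in seq_len(n_loc)) {
    calls <- gt[j, ]
    parts <- strsplit(calls, "[/|]")
    lens <- lengths(parts)
    bad <- which(!is.na(calls) & lens != 2)
    if (length(bad) > 0) {
      stop(sprintf("non-diploid GT '%s' for sample %s at record %s",
                   calls[bad[1]], samples[bad[1]], locus_ids[j]), call. = FALSE)
    }
    al <- suppressWarnings(vapply(parts, function(p) {
      if (length(p) != 2) return(c(NA_integer_, NA_integer_))
      as.integer(p)
    }, integer(2)))
    # half-calls (one '.') -> fully missing
    al[, is.na(al[1, ]) | is.na(al[2, ])] <- NA_integer_
    a1[, j] <- al[1, ]
    a2[, j] <- al[2, ]
  }
  tags <- if (all(chrom == locus_ids)) NULL else stats::setNames(chrom, locus_ids)
  geno_mat(a1, a2, pop = resolve_popmap(popmap, samples), tags = tags)
}

vcf_allele_symbol <- function(code) {
  base <- c("A", "C", "G", "T")
  ifelse(code < 4, base[code + 1], paste0("N", code))
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal GT-only VCF v4.2. Allele codes are written as-is in the
#' GT field; REF/ALT columns carry synthetic nucleotide symbols (the loci are
#' anonymous tags, so the symbols only serve format validity). CHROM holds
#' the RAD tag when present, otherwise the locus ID. The popmap is not part
#' of the VCF; use [write_popmap()] alongside.
#'
#' @param gm A [geno_mat()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  chrom <- if (is.null(gm$tags)) loci(gm) else unname(gm$tags)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=radfst",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals(gm)), collapse = "\t")
  )
  recs <- vapply(seq_len(n_loci(gm)), function(j) {
    x1 <- gm$a1[, j]
    x2 <- gm$a2[, j]
    max_code <- max(c(x1, x2, 1L), na.rm = TRUE)
    alt <- paste(vcf_allele_symbol(seq_len(max_code)), collapse = ",")
    gt <- ifelse(is.na(x1), "./.", paste0(x1, "/", x2))
    # POS indexes the SNP within its tag so records stay unique per CHROM
    pos <- if (is.null(gm$tags)) 1L else sum(gm$tags[seq_len(j)] == gm$tags[j])
    paste(c(chrom[j], pos, loci(gm)[j], vcf_allele_symbol(0L), alt, ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, recs), path)
  invisible(path)
}

#' @rdname read_popmap
#' @param gm A [geno_mat()].
#' @param path Output path.
#' @export
write_popmap <- function(gm, path) {
  utils::write.table(
    data.frame(individual = individuals(gm), population = unname(gm$pop)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a genepop file
#'
#' Supports the classic genepop dialect with 2- or 3-digit allele coding:
#' a title line, one locus name per line (or one comma-separated line),
#' then `POP`-delimited blocks of `individual , 003005 ...` rows. Allele
#' code 0 (`00`/`000`) marks a missing allele; a call with one missing
#' allele is treated as entirely missing. Populations are labelled
#' `pop1`, `pop2`, ... in file order.
#'
#' @param path Path to a genepop file.
#' @return A [geno_mat()].
#' @export
read_genepop <- function(path) {
  raw <- trimws(readLines(path))
  raw <- raw[raw != ""]
  if (length(raw) < 3) stop("genepop file too short", call. = FALSE)
  body <- raw[-1]
  pop_rows <- grepl("^pop$", body, ignore.case = TRUE)
  first_pop <- which(pop_rows)[1]
  if (is.na(first_pop)) stop("genepop file has no POP line", call. = FALSE)
  locus_lines <- body[seq_len(first_pop - 1)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[locus_ids != ""]
  if (anyDuplicated(locus_ids)) stop("duplicate locus name in genepop header", call. = FALSE)

  ind_ids <- character()
  pops <- character()
  entries <- list()
  pop_idx <- 0L
  for (line in body[first_pop:length(body)]) {
    if (grepl("^pop$", line, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L
      next
    }
    bits <- strsplit(line, ",")[[1]]
    if (length(bits) != 2) {
      stop("malformed genepop individual line: ", line, call. = FALSE)
    }
    codes <- strsplit(trimws(bits[2]), "[ \t]+")[[1]]
    if (length(codes) != length(locus_ids)) {
      stop(sprintf("individual '%s' has %d genotype entries, expected %d",
                   trimws(bits[1]), length(codes), length(locus_ids)), call. = FALSE)
    }
    ind_ids <- c(ind_ids, trimws(bits[1]))
    pops <- c(pops, paste0("pop", pop_idx))
    entries[[length(entries) + 1L]] <- codes
  }
  widths <- unique(nchar(unlist(entries)))
  if (length(widths) != 1 || !widths %in% c(4L, 6L)) {
    stop("inconsistent allele digit width in genepop file (need uniform 2- or 3-digit coding)",
         call. = FALSE)
  }
  d <- widths / 2L
  if (anyDuplicated(ind_ids)) ind_ids <- make.unique(ind_ids, sep = "_")
  mat <- do.call(rbind, entries)
  a1 <- matrix(as.integer(substr(mat, 1L, d)), nrow(mat), ncol(mat))
  a2 <- matrix(as.integer(substr(mat, d + 1L, 2L * d)), nrow(mat), ncol(mat))
  # allele code 0 = missing allele; any missing allele voids the call
  miss <- a1 == 0L | a2 == 0L
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(ind_ids, locus_ids)
  geno_mat(a1, a2, pop = pops)
}

#' Read and write the plain TSV genotype dialect
#'
#' The dialect is a single TSV: an optional first comment line
#' `#tags<TAB>tag1<TAB>...` carrying the RAD-tag of each locus, then a header
#' row `individual<TAB>population<TAB><locus IDs...>`, then one row per
#' individual with cells `a/b` (allele codes, unordered) or `.` for missing.
#' The round trip through [write_matrix_tsv()] and [read_matrix_tsv()] is
#' lossless, including missingness, population labels and tags.
#'
#' @param gm A [geno_mat()].
#' @param path File path.
#' @return `read_matrix_tsv()` returns a [geno_mat()]; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @export
write_matrix_tsv <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(gm$tags)) {
    writeLines(paste(c("#tags", unname(gm$tags)), collapse = "\t"), con)
  }
  writeLines(paste(c("individual", "population", loci(gm)), collapse = "\t"), con)
  cells <- matrix(ifelse(is.na(gm$a1), ".", paste0(gm$a1, "/", gm$a2)),
                  n_ind(gm), n_loci(gm))
  rows <- vapply(seq_len(n_ind(gm)), function(i) {
    paste(c(individuals(gm)[i], unname(gm$pop)[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty TSV matrix file", call. = FALSE)
  tags <- NULL
  if (startsWith(lines[1], "#tags")) {
    tags <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "individual" || header[2] != "population") {
    stop("TSV matrix header must start with 'individual<TAB>population'", call. = FALSE)
  }
  locus_ids <- header[-(1:2)]
  if (!is.null(tags) && length(tags) != length(locus_ids)) {
    stop("#tags line length does not match locus count", call. = FALSE)
  }
  body <- lines[-1]
  n <- length(body)
  a1 <- matrix(NA_integer_, n, length(locus_ids))
  a2 <- a1
  ids <- character(n)
  pops <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop(sprintf("row %d has %d fields, expected %d", i, length(fields),
                   length(header)), call. = FALSE)
    }
    ids[i] <- fields[1]
    pops[i] <- fields[2]
    cells <- fields[-(1:2)]
    ok <- cells == "." | grepl("^[0-9]+/[0-9]+$", cells)
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop(sprintf("malformed cell '%s' at row %d (individual %s), locus %s",
                   cells[j], i, ids[i], locus_ids[j]), call. = FALSE)
    }
    typed <- cells != "."
    if (any(typed)) {
      parts <- do.call(rbind, strsplit(cells[typed], "/", fixed = TRUE))
      a1[i, typed] <- as.integer(parts[, 1])
      a2[i, typed] <- as.integer(parts[, 2])
    }
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, locus_ids)
  geno_mat(a1, a2, pop = pops,
           tags = if (is.null(tags)) NULL else stats::setNames(tags, locus_ids))
}
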