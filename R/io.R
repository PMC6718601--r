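# Readers/writers for the plain-text formats the pipeline touches: BED,
# bedGraph, chromosome sizes, sample sheet, TSS annotation and expression
# matrices. Coordinates are uniformly 0-based half-open; writers can emit
# "#" header comment lines carrying pipeline version and parameters, and all
# readers skip such lines.

.header_comments <- function(params = NULL, seed = NULL) {
  h <- sprintf("# chromage %s", as.character(utils::packageVersion("chromage")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%s", format(seed)))
  if (length(params))
    h <- c(h, sprintf("# %s=%s", names(params),
                      vapply(params, function(p) paste(format(p, scientific = FALSE),
                                                       collapse = ","), "")))
  h
}

.read_noncomment_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  structure(lines[keep], line_numbers = which(keep))
}

.fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a chromosome-size table
#'
#' Two-column TSV: chromosome name, length in bp. Row order defines
#' chromosome order.
#' @param path File path.
#' @return A [chrom_sizes()] vector.
#' @export
read_chrom_sizes <- function(path) {
  lines <- .read_noncomment_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("chrom sizes file needs 2 tab-separated columns")
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (any(is.na(len))) stop("non-numeric chromosome length in ", path)
  chrom_sizes(stats::setNames(len, nm))
}

#' Write a chromosome-size table
#' @param sizes A [chrom_sizes()] vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), .fmt_coord(unname(sizes)), sep = "\t"), path)
  invisible(path)
}

#' Read a BED file
#'
#' Parses BED3+ with 0-based half-open coordinates. Columns beyond the sixth
#' are retained verbatim so passthrough writes preserve them. Comment,
#' `track` and `browser` lines are skipped.
#'
#' @param path File path.
#' @param chrom_sizes Optional [chrom_sizes()] for validation.
#' @return data.frame with chrom/start/end and any of name/score/strand plus
#'   `extraN` passthrough columns; parse failures report the offending line
#'   number.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- .read_noncomment_lines(path)
  lineno <- attr(lines, "line_numbers")
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated columns",
                 lineno[which(nf < 3L)[1]], path))
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  start <- suppressWarnings(as.numeric(getcol(2L)))
  end <- suppressWarnings(as.numeric(getcol(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 lineno[bad[1]], path))
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("invalid interval on line %d in %s: requires 0 <= start < end",
                 lineno[bad[1]], path))
  x <- data.frame(chrom = getcol(1L), start = start, end = end,
                  stringsAsFactors = FALSE)
  maxf <- max(nf)
  opt <- c("name", "score", "strand")
  for (i in 4L:max(maxf, 3L)) {
    if (i > maxf) break
    colname <- if (i <= 6L) opt[i - 3L] else paste0("extra", i - 6L)
    x[[colname]] <- getcol(i)
  }
  validate_intervals(x, chrom_sizes, what = "BED interval")
  attr(x, "n_fields") <- maxf
  x
}

#' Write a BED file
#'
#' Emits chrom/start/end plus whatever optional BED columns are present
#' (name, score, strand, passthrough extras), reproducing a file read with
#' [read_bed()] byte-identically.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @param comments Optional character vector of header lines (written with a
#'   leading `#` if not already present).
#' @export
write_bed <- function(x, path, comments = NULL) {
  cols <- list(x$chrom, .fmt_coord(x$start), .fmt_coord(x$end))
  for (colname in c("name", "score", "strand",
                    grep("^extra", names(x), value = TRUE))) {
    if (!is.null(x[[colname]])) {
      v <- x[[colname]]
      cols[[length(cols) + 1L]] <- if (is.numeric(v)) .fmt_coord(v) else as.character(v)
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (!is.null(comments))
    lines <- c(ifelse(grepl("^#", comments), comments, paste0("# ", comments)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four columns: chrom, start, end, value (0-based half-open). Runs are
#' sorted and checked for overlaps; the library size is derived as
#' `sum(value x run length) / read_length`.
#'
#' @param path File path.
#' @param chrom_sizes Optional [chrom_sizes()] for validation.
#' @param read_length Read-length equivalent in bp (default 100).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL, read_length = 100) {
  lines <- .read_noncomment_lines(path)
  if (length(lines) == 0L)
    return(coverage_track(character(), numeric(), numeric(), numeric(),
                          read_length = read_length, chrom_sizes = chrom_sizes))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 4L) stop("bedGraph requires exactly 4 columns: ", path)
  coverage_track(dt[[1L]], dt[[2L]], dt[[3L]], dt[[4L]],
                 read_length = read_length, chrom_sizes = chrom_sizes)
}

#' Write a bedGraph coverage track
#' @param track A [coverage_track()] or run data.frame.
#' @inheritParams write_bed
#' @export
write_bedgraph <- function(track, path, comments = NULL) {
  lines <- paste(track$chrom, .fmt_coord(track$start), .fmt_coord(track$end),
                 .fmt_coord(track$value), sep = "\t")
  if (!is.null(comments))
    lines <- c(ifelse(grepl("^#", comments), comments, paste0("# ", comments)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression matrix
#'
#' TSV with a header row of sample ids and a first column of gene ids.
#' Values must be non-negative with no missing entries; duplicated gene ids
#' are rejected.
#'
#' @param path File path.
#' @param sample_sheet Optional sample sheet; when given, the matrix columns
#'   must exactly match its expression-assay sample ids (mismatches are
#'   listed in the error).
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL) {
  lines <- .read_noncomment_lines(path)
  dt <- data.table::fread(text = lines, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene_id in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression values must be non-negative")
  if (!is.null(sample_sheet)) {
    expected <- sample_sheet$sample_id[sample_sheet$assay == "expression"]
    extra <- setdiff(colnames(m), expected)
    missing <- setdiff(expected, colnames(m))
    if (length(extra) || length(missing))
      stop("expression matrix samples disagree with sample sheet; ",
           if (length(extra)) paste0("unknown: ", paste(extra, collapse = ","), "; ") else "",
           if (length(missing)) paste0("absent: ", paste(missing, collapse = ",")) else "")
  }
  m
}

#' Write a gene expression matrix
#' @param m Genes x samples numeric matrix with dimnames.
#' @inheritParams write_bed
#' @export
write_expression_matrix <- function(m, path, comments = NULL) {
  dt <- data.table::data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(ifelse(grepl("^#", comments), comments, paste0("# ", comments)), con)
  writeLines(paste(names(dt), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(dt, function(v)
    if (is.numeric(v)) .fmt_coord(v) else as.character(v)), sep = "\t")), con)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with header columns `sample_id`, `age`, `coarse_group`, `fine_group`,
#' `assay`. Coarse groups must be `young`/`aged`; when `age_cutoff` is given,
#' labels are checked for consistency (young iff age <= cutoff).
#'
#' @param path File path.
#' @param age_cutoff Optional numeric cutoff for the young/aged split.
#' @return data.frame with an attribute `fine_order`: fine groups ordered by
#'   mean age.
#' @export
read_sample_sheet <- function(path, age_cutoff = NULL) {
  lines <- .read_noncomment_lines(path)
  x <- as.data.frame(data.table::fread(text = lines, header = TRUE, sep = "\t"))
  needed <- c("sample_id", "age", "coarse_group", "fine_group", "assay")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  if (!all(x$coarse_group %in% c("young", "aged")))
    stop("coarse_group must be 'young' or 'aged'")
  if (!is.null(age_cutoff)) {
    bad <- which((x$age <= age_cutoff) != (x$coarse_group == "young"))
    if (length(bad))
      stop("coarse_group inconsistent with age cutoff for sample(s): ",
           paste(x$sample_id[bad], collapse = ", "))
  }
  attr(x, "fine_order") <- fine_group_order(x)
  x
}

#' Ordered fine-group labels of a sample sheet
#'
#' Fine groups ordered by their mean sample age (the declared aging order).
#' @param sheet Sample-sheet data.frame.
#' @return Character vector of fine-group labels, youngest first.
#' @export
fine_group_order <- function(sheet) {
  mean_age <- tapply(sheet$age, sheet$fine_group, mean)
  names(sort(mean_age))
}

#' Write a sample sheet
#' @param sheet Sample-sheet data.frame.
#' @inheritParams write_bed
#' @export
write_sample_sheet <- function(sheet, path, comments = NULL) {
  .write_tsv(sheet, path, comments)
}

#' Read a TSS annotation
#'
#' TSV with header columns `gene_id`, `chrom`, `tss`, `strand` (0-based TSS
#' coordinate).
#' @param path File path.
#' @param chrom_sizes Optional [chrom_sizes()] for validation.
#' @return data.frame with unique gene ids.
#' @export
read_tss <- function(path, chrom_sizes = NULL) {
  lines <- .read_noncomment_lines(path)
  x <- as.data.frame(data.table::fread(text = lines, header = TRUE, sep = "\t"))
  miss <- setdiff(c("gene_id", "chrom", "tss", "strand"), names(x))
  if (length(miss)) stop("TSS annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$gene_id))
    stop("duplicated gene_id in TSS annotation: ",
         paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", "))
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(x$tss < 0)) stop("tss positions must be >= 0")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("TSS chromosome(s) absent from size table: ", paste(unknown, collapse = ", "))
    over <- which(x$tss >= unname(chrom_sizes[x$chrom]))
    if (length(over))
      stop("tss position beyond chromosome length for gene ", x$gene_id[over[1]])
  }
  x
}

#' Write a TSS annotation
#' @param tss TSS data.frame (gene_id/chrom/tss/strand).
#' @inheritParams write_bed
#' @export
write_tss <- function(tss, path, comments = NULL) {
  .write_tsv(tss, path, comments)
}

# Generic TSV writer with optional "#" comment header.
.write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(ifelse(grepl("^#", comments), comments, paste0("# ", comments)), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x))
    writeLines(do.call(paste, c(lapply(x, function(v)
      if (is.numeric(v)) .fmt_coord(v) else as.character(v)), sep = "\t")), con)
  invisible(path)
}

.read_tsv <- function(path) {
  lines <- .read_noncomment_lines(path)
  as.data.frame(data.table::fread(text = lines, header = TRUE, sep = "\t"))
}
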