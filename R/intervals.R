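# Genomic intervals are plain data.frames with columns chrom, start, end
# (0-based half-open, BED convention) plus optional name/score/strand
# columns. Chromosome order follows the chrom-sizes table wherever one is
# supplied, otherwise lexicographic order.

#' Chromosome size table
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names are
#'   chromosome identifiers; the name order defines chromosome order for all
#'   downstream binning and sorting.
#' @return A named numeric vector of class `chrom_sizes`.
#' @export
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chr2 = 5e5))
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names: ",
         paste(unique(names(lengths)[duplicated(names(lengths))]), collapse = ", "))
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive finite numbers")
  storage.mode(lengths) <- "double"
  structure(lengths, class = "chrom_sizes")
}

#' Construct a genomic-interval table
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open coordinates.
#' @param name Optional labels.
#' @param score Optional non-negative scores.
#' @param chrom_sizes Optional [chrom_sizes()] table used for validation.
#' @return A data.frame with columns chrom, start, end (and name/score when
#'   given).
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              chrom_sizes = NULL) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x, chrom_sizes)
  x
}

#' Validate an interval table
#'
#' Checks the half-open coordinate invariants (0 <= start < end) and, when a
#' chromosome-size table is given, that every interval lies on a known
#' chromosome and within its length.
#'
#' @param x Interval data.frame (chrom/start/end).
#' @param chrom_sizes Optional [chrom_sizes()] table.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s %d violates 0 <= start < end (%s:%s-%s)", what, bad[1],
                 x$chrom[bad[1]], format(x$start[bad[1]], scientific = FALSE),
                 format(x$end[bad[1]], scientific = FALSE)))
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) absent from size table: ", paste(unknown, collapse = ", "))
    over <- which(x$end > unname(chrom_sizes[x$chrom]))
    if (length(over))
      stop(sprintf("%s %d extends past the end of %s", what, over[1],
                   x$chrom[over[1]]))
  }
  invisible(x)
}

# Rank of each chromosome for sorting: chrom-sizes order when available,
# otherwise lexicographic.
.chrom_rank <- function(chrom, chrom_sizes = NULL) {
  lev <- if (!is.null(chrom_sizes)) names(chrom_sizes) else sort(unique(chrom))
  match(chrom, lev)
}

#' Sort intervals by (chromosome, start, end)
#'
#' @inheritParams validate_intervals
#' @return `x` reordered.
#' @export
sort_intervals <- function(x, chrom_sizes = NULL) {
  x[order(.chrom_rank(x$chrom, chrom_sizes), x$start, x$end), , drop = FALSE]
}

# 0-based half-open -> IRanges (1-based closed)
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Union-merge overlapping intervals
#'
#' Computes the minimal set of maximal intervals covering exactly the input
#' union. Intervals that merely touch (end == start, half-open abutment) are
#' *not* merged.
#'
#' @inheritParams validate_intervals
#' @return Sorted data.frame of non-overlapping intervals (chrom/start/end).
#' @export
#' @examples
#' merge_union(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15)))
merge_union <- function(x, chrom_sizes = NULL) {
  validate_intervals(x, chrom_sizes)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- split(x[c("start", "end")], x$chrom)
  out <- lapply(names(parts), function(ch) {
    r <- IRanges::reduce(.as_iranges(parts[[ch]]$start, parts[[ch]]$end),
                         min.gapwidth = 0L)
    data.frame(chrom = ch, start = as.numeric(IRanges::start(r)) - 1,
               end = as.numeric(IRanges::end(r)))
  })
  sort_intervals(do.call(rbind, out), chrom_sizes)
}

#' Overlapping pairs between two interval tables
#'
#' @param a,b Interval data.frames. Overlap requires at least one shared base
#'   (half-open convention; abutment is not overlap).
#' @return data.frame with columns `a` and `b`: row indices of overlapping
#'   pairs.
#' @export
interval_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a = integer(), b = integer()))
  res <- lapply(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(.as_iranges(a$start[ia], a$end[ia]),
                                  .as_iranges(b$start[ib], b$end[ib]))
    data.frame(a = ia[S4Vectors::queryHits(hits)],
               b = ib[S4Vectors::subjectHits(hits)])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(a = integer(), b = integer()) else out
}
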