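# Coverage tracks: piecewise-constant signal over the genome, stored as
# sorted, non-overlapping runs (chrom/start/end/value). Bases not covered by
# any run carry signal 0 (sparse bedGraph convention). Library size is
# expressed as a read-equivalent count derived from the total signal mass
# and a configurable read length, so RPKM stays well-defined when only
# coverage (not alignments) is available.

#' Construct a coverage track
#'
#' @param chrom,start,end,value Run coordinates (0-based half-open) and
#'   non-negative signal values.
#' @param read_length Read-length equivalent (bp) used to convert signal mass
#'   into a read count for library-size normalization. Default 100.
#' @param chrom_sizes Optional [chrom_sizes()] table for validation.
#' @param sort Sort runs by (chrom, start) before validating. Default TRUE.
#' @return data.frame of class `coverage_track` with attributes
#'   `read_length` and `total_mapped`.
#' @export
coverage_track <- function(chrom, start, end, value, read_length = 100,
                           chrom_sizes = NULL, sort = TRUE) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (sort) x <- sort_intervals(x, chrom_sizes)
  validate_intervals(x, chrom_sizes, what = "coverage run")
  if (nrow(x) && any(!is.finite(x$value) | x$value < 0))
    stop("coverage values must be finite and >= 0")
  # overlap check on sorted runs
  if (nrow(x) > 1L) {
    same <- x$chrom[-1L] == x$chrom[-nrow(x)]
    ov <- which(same & x$start[-1L] < x$end[-nrow(x)])
    if (length(ov))
      stop(sprintf("overlapping coverage runs: %s:%s-%s and %s:%s-%s",
                   x$chrom[ov[1]], format(x$start[ov[1]], scientific = FALSE),
                   format(x$end[ov[1]], scientific = FALSE),
                   x$chrom[ov[1] + 1L],
                   format(x$start[ov[1] + 1L], scientific = FALSE),
                   format(x$end[ov[1] + 1L], scientific = FALSE)))
  }
  rownames(x) <- NULL
  attr(x, "read_length") <- read_length
  attr(x, "total_mapped") <- sum(x$value * (x$end - x$start)) / read_length
  class(x) <- c("coverage_track", "data.frame")
  x
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d runs on %d chromosome(s); total_mapped = %.4g (read length %g)\n",
              nrow(x), length(unique(x$chrom)), total_mapped(x),
              attr(x, "read_length")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Total signal mass of a track
#'
#' Sum of value x run length over all runs (signal-base units).
#' @param track A [coverage_track()].
#' @return Numeric scalar.
#' @export
total_mass <- function(track) sum(track$value * (track$end - track$start))

#' Read-equivalent library size
#'
#' `total_mass(track) / read_length`; the denominator for CPM/RPKM scaling.
#' @inheritParams total_mass
#' @return Numeric scalar.
#' @export
total_mapped <- function(track) {
  tm <- attr(track, "total_mapped")
  if (is.null(tm)) total_mass(track) / attr(track, "read_length") else tm
}

#' Scale a track to counts-per-million read equivalents
#'
#' Rescales signal so all tracks share the same total mass
#' (1e6 read-equivalents), removing library-size differences.
#' @inheritParams total_mass
#' @return A [coverage_track()] with scaled values.
#' @export
cpm_scale <- function(track) {
  tm <- total_mapped(track)
  if (!is.finite(tm) || tm <= 0) stop("track has zero total mass; cannot CPM-scale")
  out <- track
  out$value <- track$value * 1e6 / tm
  attr(out, "total_mapped") <- 1e6
  out
}

# Joint piecewise-constant segmentation of two tracks over the full genome.
# Returns chrom/start/end/va/vb covering every base of every chromosome in
# `sizes` (gaps carry 0).
.segment_pair <- function(a, b, sizes) {
  out <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    ch <- names(sizes)[k]; L <- unname(sizes[k])
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(0, L, ra$start, ra$end, rb$start, rb$end)))
    bp <- bp[bp >= 0 & bp <= L]
    s <- bp[-length(bp)]; e <- bp[-1L]
    lookup <- function(r) {
      if (nrow(r) == 0L) return(numeric(length(s)))
      i <- findInterval(s, r$start)
      v <- numeric(length(s))
      hit <- i >= 1L
      hit[hit] <- s[hit] < r$end[i[hit]]
      v[hit] <- r$value[i[hit]]
      v
    }
    out[[k]] <- data.frame(chrom = ch, start = s, end = e,
                           va = lookup(ra), vb = lookup(rb))
  }
  do.call(rbind, out)
}

# Merge adjacent runs with identical values (run-length encode).
.rle_merge <- function(x, value_col = "value") {
  if (nrow(x) <= 1L) return(x)
  v <- x[[value_col]]
  new_run <- c(TRUE, x$chrom[-1L] != x$chrom[-nrow(x)] |
                 x$start[-1L] != x$end[-nrow(x)] |
                 v[-1L] != v[-nrow(x)])
  id <- cumsum(new_run)
  data.frame(chrom = x$chrom[new_run],
             start = x$start[new_run],
             end = tapply(x$end, id, function(z) z[length(z)])[as.character(seq_len(max(id)))],
             value = v[new_run], row.names = NULL)
}

#' Signal mass of a track over regions
#'
#' For each region, the sum of value x overlap length over all runs
#' intersecting it. Uncovered bases contribute 0.
#'
#' @param track A [coverage_track()] (or plain run data.frame).
#' @param regions Interval data.frame.
#' @return Numeric vector, one mass per region row.
#' @export
region_mass <- function(track, regions) {
  validate_intervals(regions, what = "region")
  out <- numeric(nrow(regions))
  if (nrow(regions) == 0L || nrow(track) == 0L) return(out)
  for (ch in intersect(unique(regions$chrom), unique(track$chrom))) {
    ir <- which(regions$chrom == ch); it <- which(track$chrom == ch)
    hits <- IRanges::findOverlaps(
      .as_iranges(track$start[it], track$end[it]),
      .as_iranges(regions$start[ir], regions$end[ir]))
    if (length(hits) == 0L) next
    q <- it[S4Vectors::queryHits(hits)]; s <- ir[S4Vectors::subjectHits(hits)]
    w <- pmin(track$end[q], regions$end[s]) - pmax(track$start[q], regions$start[s])
    m <- rowsum(track$value[q] * w, group = s)
    out[as.integer(rownames(m))] <- out[as.integer(rownames(m))] + m[, 1L]
  }
  out
}

#' Length-weighted mean signal over regions
#'
#' `region_mass / region length`; the aggregation used both for genomic bins
#' and for atlas entries.
#' @inheritParams region_mass
#' @return Numeric vector of per-region mean signal.
#' @export
region_mean_signal <- function(track, regions) {
  region_mass(track, regions) / (regions$end - regions$start)
}
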