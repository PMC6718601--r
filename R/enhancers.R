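# Typical/super-enhancer calling. H3K27ac peaks further than 5 kb from any
# TSS are enhancers; nearby distal peaks are stitched (ROSE convention,
# 12.5 kb); each stitched region is ranked by background-corrected signal
# mass over its constituents; the rank-vs-signal curve scaled to the unit
# square is cut where its discrete slope first reaches 1 (tangent rule) --
# regions above that signal are super-enhancers.

#' Keep peaks distal to all TSSs
#'
#' A peak is retained iff its gap to the nearest TSS exceeds `min_dist`,
#' where the gap is 0 when a TSS falls inside the peak and otherwise the
#' distance from the nearer peak edge to the TSS. The comparison is strict
#' (gap must be *larger than* `min_dist`).
#'
#' @param peaks Interval data.frame.
#' @param tss TSS annotation (gene_id/chrom/tss/strand); must be non-empty.
#' @param min_dist Exclusion distance in bp. Default 5000.
#' @return The distal subset of `peaks` with an added `tss_gap` column
#'   (Inf on chromosomes without any TSS).
#' @export
distal_filter <- function(peaks, tss, min_dist = 5000) {
  if (is.null(tss) || nrow(tss) == 0L)
    stop("TSS annotation is empty; distal filter undefined")
  validate_intervals(peaks, what = "peak")
  gap <- rep(Inf, nrow(peaks))
  for (ch in intersect(unique(peaks$chrom), unique(tss$chrom))) {
    ip <- which(peaks$chrom == ch)
    pos <- sort(tss$tss[tss$chrom == ch])
    s <- peaks$start[ip]; e <- peaks$end[ip]
    j <- findInterval(s, pos)                    # largest tss position <= start
    left <- ifelse(j >= 1L, s - pos[pmax(j, 1L)], Inf)
    nxt <- pos[pmin(j + 1L, length(pos))]        # smallest tss position > start
    right <- ifelse(j < length(pos),
                    ifelse(nxt <= e - 1, 0, nxt - (e - 1)), Inf)
    gap[ip] <- pmin(left, right)
  }
  out <- peaks[gap > min_dist, , drop = FALSE]
  out$tss_gap <- gap[gap > min_dist]
  rownames(out) <- NULL
  out
}

#' Stitch nearby distal peaks into candidate enhancer regions
#'
#' Consecutive non-overlapping peaks on a chromosome are joined whenever the
#' gap between them is at most `stitch_distance`; the stitched span runs
#' from the first constituent's start to the last one's end.
#'
#' @param peaks Non-overlapping interval data.frame (pre-merged).
#' @param stitch_distance Maximum gap in bp (ROSE default 12500).
#' @return data.frame of stitched regions (chrom/start/end/name/
#'   n_constituents) with a `constituents` list-column of the member peaks.
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  validate_intervals(peaks, what = "peak")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), n_constituents = integer()))
  p <- sort_intervals(peaks)
  if (nrow(p) > 1L) {
    same <- p$chrom[-1L] == p$chrom[-nrow(p)]
    if (any(same & p$start[-1L] < p$end[-nrow(p)]))
      stop("stitch() requires non-overlapping peaks; merge them first")
  }
  new_region <- c(TRUE, p$chrom[-1L] != p$chrom[-nrow(p)] |
                    p$start[-1L] - p$end[-nrow(p)] > stitch_distance)
  id <- cumsum(new_region)
  groups <- split(seq_len(nrow(p)), id)
  out <- data.frame(
    chrom = vapply(groups, function(i) p$chrom[i[1L]], ""),
    start = vapply(groups, function(i) p$start[i[1L]], 0),
    end = vapply(groups, function(i) p$end[i[length(i)]], 0),
    n_constituents = lengths(groups))
  out$name <- sprintf("stitched_%05d", seq_len(nrow(out)))
  out$constituents <- I(lapply(groups, function(i) {
    k <- p[i, intersect(c("chrom", "start", "end", "name"), names(p)), drop = FALSE]
    rownames(k) <- NULL
    k
  }))
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "name", "n_constituents", "constituents")]
}

#' Background-corrected signal mass of stitched regions
#'
#' Each region's signal is `max(0, sum over constituents of (chip mass -
#' control mass))`, so gaps between constituents contribute nothing and
#' negative enrichment floors at 0. The tracks are used as given and are
#' expected to be on a common scale (see [cpm_scale()]).
#'
#' @param stitched Output of [stitch()].
#' @param chip ChIP [coverage_track()], CPM-scaled to the control's mass.
#' @param control Optional input [coverage_track()]; NULL means no
#'   background subtraction.
#' @return `stitched` with an added numeric `signal` column.
#' @export
enhancer_signal <- function(stitched, chip, control = NULL) {
  if (nrow(stitched) == 0L) { stitched$signal <- numeric(0); return(stitched) }
  cons <- do.call(rbind, lapply(seq_len(nrow(stitched)), function(i)
    cbind(stitched$constituents[[i]][c("chrom", "start", "end")], .region = i)))
  chip_mass <- region_mass(chip, cons)
  ctrl_mass <- if (is.null(control)) 0 else region_mass(control, cons)
  net <- rowsum(chip_mass - ctrl_mass, group = cons$.region)
  signal <- numeric(nrow(stitched))
  signal[as.integer(rownames(net))] <- net[, 1L]
  stitched$signal <- pmax(0, signal)
  stitched
}

#' Tangent (slope-1) cutoff on a rank-ordered signal curve
#'
#' Signals are sorted ascending; ranks are scaled to x in [0,1] and signals
#' to y in [0,1] by their maximum. On this scaling a line of slope 1 (the
#' unit diagonal) separates the flat body of the curve from its steep tail:
#' the cutoff is the last point of the curve lying strictly below the
#' diagonal, i.e. the point past which the curve has risen faster than
#' slope 1 for good. Regions with signal strictly greater than the cutoff
#' signal are super-enhancers; equal-signal ties on the super side of the
#' boundary are all included by construction. A curve that never dips below
#' the diagonal (e.g. all-equal signals, or signal linear in rank) yields
#' zero super-enhancers. Scale-invariant by construction.
#'
#' @param signal Numeric vector of non-negative region signals (>= 3 values,
#'   positive total).
#' @return List: `is_super` (logical, parallel to `signal`), `cutoff_signal`
#'   (numeric, NA when no cutoff), `n_super`.
#' @export
rose_cutoff <- function(signal) {
  n <- length(signal)
  if (n < 3L) stop("need at least 3 regions to place a cutoff")
  if (any(signal < 0) || sum(signal) <= 0)
    stop("signals must be non-negative with positive total")
  s <- sort(signal)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- s / s[n]
  dip <- which(y - x < 0)
  if (length(dip) == 0L)  # curve never dips below the diagonal: no elbow
    return(list(is_super = rep(FALSE, n), cutoff_signal = NA_real_, n_super = 0L))
  cutoff <- s[dip[length(dip)]]
  list(is_super = signal > cutoff, cutoff_signal = cutoff,
       n_super = sum(signal > cutoff))
}

#' Call typical and super-enhancers
#'
#' Applies the tangent cutoff to stitched-region signals and returns the
#' ranked call set (rank 1 = strongest). The super-enhancer block is always
#' a prefix of the descending ranking.
#'
#' @param stitched Output of [enhancer_signal()] (must carry `signal`).
#' @param parameters Optional named list recorded alongside the calls (e.g.
#'   tss_exclusion, stitch_distance).
#' @return List of class `se_call_set`: `enhancers` (ranked data.frame with
#'   `rank` and `is_super`), `cutoff_rank`, `cutoff_signal`, `parameters`.
#' @export
call_super_enhancers <- function(stitched, parameters = list()) {
  if (is.null(stitched$signal)) stop("run enhancer_signal() first")
  cut <- rose_cutoff(stitched$signal)
  ord <- order(-stitched$signal, .chrom_rank(stitched$chrom), stitched$start)
  enh <- stitched[ord, , drop = FALSE]
  enh$rank <- seq_len(nrow(enh))
  enh$is_super <- cut$is_super[ord]
  rownames(enh) <- NULL
  structure(list(enhancers = enh, cutoff_rank = cut$n_super,
                 cutoff_signal = cut$cutoff_signal, parameters = parameters),
            class = "se_call_set")
}

#' @export
print.se_call_set <- function(x, ...) {
  cat(sprintf("se_call_set: %d regions; %d super-enhancers (cutoff signal %.4g), %d typical\n",
              nrow(x$enhancers), x$cutoff_rank, x$cutoff_signal,
              nrow(x$enhancers) - x$cutoff_rank))
  invisible(x)
}

#' Group-level super-enhancer sets and their Venn partition
#'
#' Each group's SE set is the union-merge of its member samples' SE spans;
#' two group SEs are shared iff their spans overlap by at least one base.
#'
#' @param se_sets Named list of [call_super_enhancers()] results (per
#'   sample).
#' @param groups Named character vector sample id -> group label (exactly 2
#'   groups, each with >= 1 sample).
#' @return List: `group_sets` (per group, SE spans with a `shared` flag) and
#'   `venn` (named counts: specific per group and shared per group).
#' @export
se_group_profiles <- function(se_sets, groups) {
  groups <- groups[names(se_sets)]
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2L) stop("se_group_profiles requires exactly 2 groups")
  gset <- lapply(lev, function(g) {
    spans <- do.call(rbind, lapply(names(groups)[groups == g], function(s) {
      e <- se_sets[[s]]$enhancers
      e[e$is_super, c("chrom", "start", "end"), drop = FALSE]
    }))
    if (is.null(spans) || nrow(spans) == 0L)
      return(data.frame(chrom = character(), start = numeric(), end = numeric()))
    merge_union(spans)
  })
  names(gset) <- lev
  ov <- interval_overlaps(gset[[1L]], gset[[2L]])
  gset[[1L]]$shared <- seq_len(nrow(gset[[1L]])) %in% ov$a
  gset[[2L]]$shared <- seq_len(nrow(gset[[2L]])) %in% ov$b
  venn <- c(sum(!gset[[1L]]$shared), sum(gset[[1L]]$shared),
            sum(gset[[2L]]$shared), sum(!gset[[2L]]$shared))
  names(venn) <- c(paste0(lev[1L], "_specific"), paste0(lev[1L], "_shared"),
                   paste0(lev[2L], "_shared"), paste0(lev[2L], "_specific"))
  list(group_sets = gset, venn = venn)
}

#' Sample-sample correlation of super-enhancer signals
#'
#' Spearman rank correlation (midranks for ties) between samples over an
#' SE x sample signal matrix. Zero-variance columns yield NA entries and a
#' warning; the diagonal is fixed at 1.
#'
#' @param m SE x sample numeric matrix (>= 3 rows).
#' @param method Correlation method, default `"spearman"`.
#' @return Symmetric sample x sample correlation matrix.
#' @export
se_correlation <- function(m, method = "spearman") {
  if (nrow(m) < 3L) stop("need at least 3 super-enhancers for correlation")
  zero_var <- apply(m, 2L, function(col) stats::var(col) == 0)
  if (any(zero_var))
    warning("zero-variance sample column(s): ",
            paste(colnames(m)[zero_var], collapse = ", "))
  r <- suppressWarnings(stats::cor(m, method = method))
  diag(r) <- 1
  r
}
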