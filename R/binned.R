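# Genome-binned differential signal. The genome is tiled into fixed-width
# bins; each sample's input-normalized coverage is aggregated per bin; an
# aged sample's deviation from the young cohort is expressed as a z-score
# (number of young-cohort SDs from the young mean), and bins with z above
# +2 / below -2 are called gained / lost. Per-sample gain/loss fractions are
# compared between coarse age groups with a rank-sum test.

#' Tile the genome into fixed-width bins
#'
#' Each chromosome is covered by `ceiling(L / width)` bins of width `width`,
#' the last bin truncated at the chromosome end. Bins are concatenated in
#' chromosome-table order.
#'
#' @param sizes A [chrom_sizes()] table.
#' @param width Bin width in bp (> 0). Default 1e6.
#' @return data.frame of bins (chrom/start/end/name).
#' @export
#' @examples
#' make_bins(chrom_sizes(c(chrA = 2.5e6)), width = 1e6)
make_bins <- function(sizes, width = 1e6) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("bin width must be a positive number")
  out <- lapply(names(sizes), function(ch) {
    L <- unname(sizes[ch])
    n <- ceiling(L / width)
    start <- (seq_len(n) - 1) * width
    data.frame(chrom = ch, start = start, end = pmin(start + width, L))
  })
  bins <- do.call(rbind, out)
  bins$name <- sprintf("%s:%s-%s", bins$chrom, .fmt_coord(bins$start),
                       .fmt_coord(bins$end))
  bins
}

#' Normalize ChIP coverage by its input control
#'
#' Both tracks are CPM-scaled to equal total mass, then a per-base ratio
#' `(chip + pseudocount) / (control + pseudocount)` is computed on the joint
#' segmentation of the two tracks (bases covered by neither carry ratio 1)
#' and run-length encoded.
#'
#' @param chip,control [coverage_track()]s on the same chromosome universe.
#' @param sizes A [chrom_sizes()] table (defines the universe).
#' @param pseudocount Added to both CPM values. Default 1.
#' @return A [coverage_track()] of per-base enrichment ratios.
#' @export
input_normalize <- function(chip, control, sizes, pseudocount = 1) {
  if (total_mass(control) <= 0) stop("control track has zero total mass")
  if (total_mass(chip) <= 0) stop("chip track has zero total mass")
  a <- cpm_scale(chip); b <- cpm_scale(control)
  seg <- .segment_pair(a, b, sizes)
  seg$value <- (seg$va + pseudocount) / (seg$vb + pseudocount)
  seg <- .rle_merge(seg[c("chrom", "start", "end", "value")])
  coverage_track(seg$chrom, seg$start, seg$end, seg$value,
                 read_length = attr(chip, "read_length"), chrom_sizes = sizes,
                 sort = FALSE)
}

#' Per-bin normalized counts for one sample
#'
#' Length-weighted mean signal per bin (uncovered bases contribute 0).
#' @param track A [coverage_track()].
#' @param bins Bins from [make_bins()].
#' @return Numeric vector, one value per bin.
#' @export
bin_counts <- function(track, bins) region_mean_signal(track, bins)

#' Bin x sample signal matrix
#'
#' @param tracks Named list of [coverage_track()]s (names are sample ids).
#' @param bins Bins from [make_bins()].
#' @return Numeric matrix bins x samples; rownames are bin names.
#' @export
bin_signal_matrix <- function(tracks, bins) {
  stopifnot(length(tracks) > 0L, !is.null(names(tracks)))
  m <- vapply(tracks, bin_counts, numeric(nrow(bins)), bins = bins)
  m <- matrix(m, nrow = nrow(bins), dimnames = list(bins$name, names(tracks)))
  m
}

#' Young-cohort z-scores for one sample
#'
#' Per bin, `z = (x_test - mean(young)) / sd(young)` with the sample (n-1)
#' standard deviation. When the test sample itself belongs to the young
#' cohort it is excluded from the reference (leave-one-out) to avoid
#' self-comparison bias. Bins with zero young-cohort dispersion are
#' undefined (NA).
#'
#' @param values Bin x sample numeric matrix with column names.
#' @param young_ids Sample ids forming the young reference cohort (>= 2
#'   after any leave-one-out exclusion).
#' @param test_id Sample id to score.
#' @return Numeric vector of z-scores (NA where undefined) with attribute
#'   `reference` naming the cohort actually used.
#' @export
bin_zscores <- function(values, young_ids, test_id) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  miss <- setdiff(c(young_ids, test_id), colnames(values))
  if (length(miss)) stop("sample(s) absent from matrix: ", paste(miss, collapse = ", "))
  ref <- setdiff(young_ids, test_id)
  if (length(ref) < 2L)
    stop("need at least 2 young reference samples (after leave-one-out)")
  y <- values[, ref, drop = FALSE]
  mu <- rowMeans(y)
  sdev <- sqrt(rowSums((y - mu)^2) / (ncol(y) - 1L))
  z <- (values[, test_id] - mu) / sdev
  z[sdev == 0] <- NA_real_
  attr(z, "reference") <- ref
  z
}

#' Classify bins from z-scores
#'
#' Strict thresholds: increased iff z > `z_hi`, decreased iff z < `z_lo`;
#' NA z-scores are undefined.
#'
#' @param z Numeric z-score vector (NA = undefined).
#' @param z_lo,z_hi Thresholds (defaults -2, +2), `z_lo < z_hi`.
#' @return Factor with levels increased/decreased/unchanged/undefined.
#' @export
classify_bins <- function(z, z_lo = -2, z_hi = 2) {
  if (z_lo >= z_hi) stop("z_lo must be < z_hi")
  call <- rep("unchanged", length(z))
  call[!is.na(z) & z > z_hi] <- "increased"
  call[!is.na(z) & z < z_lo] <- "decreased"
  call[is.na(z)] <- "undefined"
  factor(call, levels = c("increased", "decreased", "unchanged", "undefined"))
}

#' Summarize bin calls for one sample
#'
#' Counts per category and fractions of increased/decreased bins computed
#' over defined bins only.
#' @param calls Factor from [classify_bins()].
#' @return One-row data.frame of counts and fractions.
#' @export
call_summary <- function(calls) {
  n <- table(calls)
  defined <- sum(n[c("increased", "decreased", "unchanged")])
  data.frame(n_bins = length(calls),
             n_defined = defined,
             n_increased = as.integer(n["increased"]),
             n_decreased = as.integer(n["decreased"]),
             n_undefined = as.integer(n["undefined"]),
             frac_increased = if (defined > 0) as.integer(n["increased"]) / defined else NA_real_,
             frac_decreased = if (defined > 0) as.integer(n["decreased"]) / defined else NA_real_)
}

#' Z-scores, calls and summaries for every sample
#'
#' Scores each column of the bin matrix against the young cohort
#' (leave-one-out for young samples themselves) and classifies bins. By
#' default each sample's bin values are first divided by that sample's
#' median bin value: the median bin is background-dominated, so this
#' removes the residual library-composition shift that equal-mass CPM
#' scaling leaves when samples differ in total in-peak mass, without
#' touching relative bin-level gains.
#'
#' @inheritParams bin_zscores
#' @param z_lo,z_hi Classification thresholds.
#' @param sample_scale `"median"` (default) to median-center each sample's
#'   bin values, `"none"` to use them as is.
#' @return List with `z` (bin x sample matrix), `calls` (same shape,
#'   character) and `summary` (per-sample data.frame with fractions).
#' @export
bin_differential <- function(values, young_ids, z_lo = -2, z_hi = 2,
                             sample_scale = c("median", "none")) {
  sample_scale <- match.arg(sample_scale)
  if (sample_scale == "median") {
    med <- apply(values, 2L, stats::median)
    ok <- is.finite(med) & med > 0
    values[, ok] <- sweep(values[, ok, drop = FALSE], 2L, med[ok], "/")
  }
  samples <- colnames(values)
  z <- vapply(samples, function(s) as.numeric(bin_zscores(values, young_ids, s)),
              numeric(nrow(values)))
  rownames(z) <- rownames(values)
  calls <- apply(z, 2L, function(col) as.character(classify_bins(col, z_lo, z_hi)))
  rownames(calls) <- rownames(values)
  summ <- do.call(rbind, lapply(samples, function(s)
    cbind(data.frame(sample_id = s),
          call_summary(classify_bins(z[, s], z_lo, z_hi)))))
  list(z = z, calls = calls, summary = summ)
}

#' Compare per-sample bin fractions between coarse groups
#'
#' Two-sided (by default) Wilcoxon rank-sum test of a per-sample fraction
#' (e.g. fraction of increased bins) between the aged and young groups. The
#' exact null distribution is used for group sizes <= 10 when there are no
#' ties, the normal approximation otherwise.
#'
#' @param fractions Named numeric vector, one fraction per sample.
#' @param groups Named character vector mapping sample id to `young`/`aged`.
#' @param alternative Passed to [stats::wilcox.test()]; the test is
#'   aged-versus-young, so `"greater"` asks whether aged fractions exceed
#'   young.
#' @return List with `statistic`, `p.value`, group medians and sizes.
#' @export
compare_group_fractions <- function(fractions, groups,
                                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(fractions)), !is.null(names(groups)))
  groups <- groups[names(fractions)]
  ya <- fractions[groups == "aged"]; yy <- fractions[groups == "young"]
  if (length(ya) < 2L || length(yy) < 2L)
    stop("each coarse group needs at least 2 samples")
  exact <- length(ya) <= 10L && length(yy) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(ya, yy, alternative = alternative,
                                            exact = exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied data: no evidence of a difference
  list(statistic = unname(wt$statistic), p.value = p,
       median_aged = stats::median(ya), median_young = stats::median(yy),
       n_aged = length(ya), n_young = length(yy), alternative = alternative)
}
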