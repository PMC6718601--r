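# Cross-sample peak atlas. Peaks from all samples are pooled; overlapping
# peaks (transitive, >= 1 shared base) collapse into one atlas entry
# spanning their union. Entries whose overlap cluster contains peaks from
# >= 2 distinct samples are annotated "merged", single-sample entries
# "nonoverlapping" -- both are retained, so the distinction is metadata.

#' Build a universal peak atlas across samples
#'
#' Peaks are first self-merged within each sample (so per-sample support is
#' well-defined), then pooled; transitive overlap clusters become atlas
#' entries spanning the union of their members, with support = the set of
#' contributing samples.
#'
#' @param peaks_by_sample Named list (sample id -> interval data.frame).
#' @param chrom_sizes Optional [chrom_sizes()] table.
#' @return List of class `peak_atlas`: `entries` (chrom/start/end/name/
#'   n_support/samples/category) and `provenance` (entry -> source peaks).
#' @export
build_atlas <- function(peaks_by_sample, chrom_sizes = NULL) {
  stopifnot(length(peaks_by_sample) >= 1L, !is.null(names(peaks_by_sample)))
  merged <- lapply(peaks_by_sample, merge_union, chrom_sizes = chrom_sizes)
  pooled <- do.call(rbind, lapply(names(merged), function(s) {
    if (nrow(merged[[s]]) == 0L) return(NULL)
    cbind(merged[[s]][c("chrom", "start", "end")], sample_id = s)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L)
    stop("no peaks supplied to build_atlas")
  entries <- merge_union(pooled, chrom_sizes)
  hits <- interval_overlaps(entries, pooled)
  support <- split(pooled$sample_id[hits$b], hits$a)
  n_support <- integer(nrow(entries))
  samples <- character(nrow(entries))
  idx <- as.integer(names(support))
  n_support[idx] <- vapply(support, function(s) length(unique(s)), 0L)
  samples[idx] <- vapply(support, function(s) paste(sort(unique(s)), collapse = ","), "")
  entries$name <- sprintf("atlas_%05d", seq_len(nrow(entries)))
  entries$n_support <- n_support
  entries$samples <- samples
  entries$category <- ifelse(n_support >= 2L, "merged", "nonoverlapping")
  prov <- data.frame(entry = entries$name[hits$a],
                     sample_id = pooled$sample_id[hits$b],
                     chrom = pooled$chrom[hits$b],
                     start = pooled$start[hits$b],
                     end = pooled$end[hits$b])
  prov <- prov[order(match(prov$entry, entries$name), prov$sample_id, prov$start), ]
  rownames(prov) <- NULL
  structure(list(entries = entries, provenance = prov), class = "peak_atlas")
}

#' @export
print.peak_atlas <- function(x, ...) {
  cat(sprintf("peak_atlas: %d entries (%d merged across >=2 samples, %d single-sample)\n",
              nrow(x$entries), sum(x$entries$category == "merged"),
              sum(x$entries$category == "nonoverlapping")))
  invisible(x)
}

#' Atlas-entry x sample signal matrix
#'
#' Length-weighted mean signal of each sample's coverage track over each
#' atlas entry (same aggregation contract as [bin_counts()]).
#'
#' @param atlas A [build_atlas()] result (or plain entry data.frame).
#' @param tracks Named list of [coverage_track()]s covering all samples of
#'   interest.
#' @param sample_ids Samples to include; defaults to all track names.
#' @return Numeric matrix entries x samples.
#' @export
atlas_signal_matrix <- function(atlas, tracks, sample_ids = names(tracks)) {
  entries <- if (inherits(atlas, "peak_atlas")) atlas$entries else atlas
  miss <- setdiff(sample_ids, names(tracks))
  if (length(miss)) stop("missing track(s) for sample(s): ", paste(miss, collapse = ", "))
  m <- vapply(sample_ids, function(s) region_mean_signal(tracks[[s]], entries),
              numeric(nrow(entries)))
  matrix(m, nrow = nrow(entries), dimnames = list(entries$name, sample_ids))
}

#' Write a peak atlas to disk
#'
#' Entries as BED6 (name = entry id, score = support count) plus a TSV
#' provenance table.
#' @param atlas A [build_atlas()] result.
#' @param bed_path,provenance_path Output paths.
#' @param comments Optional header comment lines.
#' @export
write_atlas <- function(atlas, bed_path, provenance_path, comments = NULL) {
  e <- atlas$entries
  bed <- data.frame(chrom = e$chrom, start = e$start, end = e$end,
                    name = e$name, score = e$n_support, strand = ".")
  write_bed(bed, bed_path, comments)
  .write_tsv(atlas$provenance, provenance_path, comments)
  invisible(bed_path)
}
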