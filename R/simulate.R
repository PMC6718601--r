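# Synthetic aging cohort with known ground truth. Background coverage is
# negative-binomial noise on a coarse grid, refined to 100-bp windows
# around enhancer loci that carry Gaussian-shaped H3K27ac enrichment. A
# planted subset of loci (and their 1:1 target genes, the labelled ECM-like
# module) scales its enrichment and expression by multiplier^(group index)
# across the ordered fine age groups; everything is deterministic given the
# seed. Peaks are emitted from the true enrichment (peak calling itself is
# out of scope), so the pipeline's own stages are tested in isolation.

#' Cohort simulation configuration
#'
#' @param n_chroms,chrom_length Genome shape (chromosomes x bp).
#' @param bin_width Bin width the cohort is meant to be analysed at.
#' @param group_sizes Named integer vector: ChIP/expression samples per fine
#'   group, youngest group first.
#' @param group_ages Named list of per-sample ages (same names/lengths as
#'   `group_sizes`).
#' @param age_cutoff Young/aged coarse split (young iff age <= cutoff).
#' @param n_genes,n_enhancer_loci Gene universe size and number of enhancer
#'   loci (each locus sits 6.5-8.5 kb from its own target gene's TSS so it
#'   survives the 5-kb distal filter yet stays that gene's nearest
#'   neighbour).
#' @param planted_fraction Fraction of loci (and their genes) that respond
#'   to age.
#' @param effect_multiplier Per-successive-group signal/expression
#'   multiplier for planted loci (1 = null cohort).
#' @param strong_fraction,strong_boost Fraction of loci with boosted
#'   amplitude (the super-enhancer-like heavy tail) and the boost factor.
#' @param bg_mean,bg_dispersion Negative-binomial background coverage depth
#'   (mu, size).
#' @param bg_resolution,peak_resolution Background / in-peak simulation
#'   window sizes in bp (peak must divide background).
#' @param peak_width_mean,peak_width_sd Gaussian enrichment width
#'   distribution (bp; truncated to [400, 2000]).
#' @param peak_amplitude Baseline enrichment amplitude (depth units above
#'   background).
#' @param expr_base_meanlog,expr_base_sdlog,expr_noise_sd Lognormal
#'   baseline expression and multiplicative noise (sd of log).
#' @param read_length Read-length equivalent used for library sizes.
#' @param seed RNG seed.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_chroms = 2L, chrom_length = 10e6, bin_width = 1e5,
                          group_sizes = c(adolescent = 3L, adult = 2L,
                                          aging = 2L, aged = 2L),
                          group_ages = list(adolescent = c(15, 18, 22),
                                            adult = c(32, 38),
                                            aging = c(52, 58),
                                            aged = c(72, 76)),
                          age_cutoff = 50,
                          n_genes = 1000L, n_enhancer_loci = 400L,
                          planted_fraction = 0.1, effect_multiplier = 1.8,
                          strong_fraction = 0.05, strong_boost = 10,
                          bg_mean = 20, bg_dispersion = 50,
                          bg_resolution = 1000L, peak_resolution = 100L,
                          peak_width_mean = 1000, peak_width_sd = 300,
                          peak_amplitude = 200,
                          expr_base_meanlog = 3, expr_base_sdlog = 1,
                          expr_noise_sd = 0.2,
                          read_length = 100, seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(n_chroms, chrom_length, bin_width, n_genes, n_enhancer_loci,
            bg_resolution, peak_resolution, read_length) <= 0))
    stop("counts and sizes must be positive")
  if (is.null(names(group_sizes)) || !setequal(names(group_sizes), names(group_ages)))
    stop("group_sizes and group_ages must share the same group names")
  if (any(lengths(group_ages)[names(group_sizes)] != group_sizes))
    stop("group_ages lengths must match group_sizes")
  if (effect_multiplier <= 0) stop("effect_multiplier must be > 0")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must be in [0, 1]")
  if (n_enhancer_loci > n_genes)
    stop("n_enhancer_loci cannot exceed n_genes (loci map 1:1 to genes)")
  if (bg_resolution %% peak_resolution != 0)
    stop("peak_resolution must divide bg_resolution")
  structure(cfg, class = "cohort_config")
}

#' Default desk-scale cohort
#'
#' Two 10-Mb chromosomes analysed at 100-kb bins, fine groups sized
#' (3, 2, 2, 2), 1,000 genes, 400 enhancer loci with 10% planted at
#' multiplier 1.8.
#' @param seed RNG seed (default 1).
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_desk_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

# Deterministic genome layout: gene tiles, TSSs, enhancer loci and the
# planted/strong subsets. Consumes RNG.
.cohort_layout <- function(cfg) {
  sizes <- chrom_sizes(stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                       sprintf("chr%d", seq_len(cfg$n_chroms))))
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1L)))
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(k) {
    ng <- per_chrom[k]
    tile <- floor(cfg$chrom_length / ng)
    data.frame(chrom = names(sizes)[k],
               tss = (seq_len(ng) - 1L) * tile + floor(tile / 4) +
                 sample(-1000:1000, ng, replace = TRUE),
               tile = tile)
  }))
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  host <- sort(sample(nrow(genes), cfg$n_enhancer_loci))
  loci <- data.frame(locus_id = sprintf("locus_%04d", seq_along(host)),
                     chrom = genes$chrom[host],
                     gene_id = genes$gene_id[host])
  loci$center <- genes$tss[host] + sample(6500:8500, length(host), replace = TRUE)
  w <- pmin(2000, pmax(400, stats::rnorm(length(host), cfg$peak_width_mean,
                                         cfg$peak_width_sd)))
  loci$sigma <- w / 4
  loci$amplitude <- cfg$peak_amplitude * stats::rlnorm(length(host), 0, 0.5)
  strong <- sample(length(host), round(cfg$strong_fraction * length(host)))
  loci$strong <- seq_along(host) %in% strong
  loci$amplitude[loci$strong] <- loci$amplitude[loci$strong] * cfg$strong_boost
  planted <- sort(sample(length(host), round(cfg$planted_fraction * length(host))))
  loci$planted <- seq_along(host) %in% planted
  genes$planted <- genes$gene_id %in% loci$gene_id[loci$planted]
  list(sizes = sizes, genes = genes, loci = loci)
}

# One sample's ChIP coverage (background + enrichment scaled by the group
# multiplier for planted loci) and its matched input. Depth units; values
# are NB-distributed integers; runs RLE-merged.
.simulate_sample_tracks <- function(cfg, layout, group_index) {
  sizes <- layout$sizes
  bg_sd <- sqrt(cfg$bg_mean + cfg$bg_mean^2 / cfg$bg_dispersion)
  build <- function(with_peaks) {
    runs <- vector("list", length(sizes) * 2L)
    ri <- 0L
    for (ch in names(sizes)) {
      L <- unname(sizes[ch])
      bs <- seq(0, L - 1, by = cfg$bg_resolution)
      bg <- data.frame(start = bs, end = pmin(bs + cfg$bg_resolution, L),
                       value = stats::rnbinom(length(bs), size = cfg$bg_dispersion,
                                              mu = cfg$bg_mean))
      if (with_peaks) {
        lch <- layout$loci[layout$loci$chrom == ch, , drop = FALSE]
        fine <- vector("list", nrow(lch))
        for (i in seq_len(nrow(lch))) {
          A <- lch$amplitude[i] *
            if (lch$planted[i]) cfg$effect_multiplier^group_index else 1
          s3 <- lch$sigma[i] * 3
          span0 <- max(0, floor((lch$center[i] - s3) / cfg$bg_resolution) * cfg$bg_resolution)
          span1 <- min(L, ceiling((lch$center[i] + s3) / cfg$bg_resolution) * cfg$bg_resolution)
          fs <- seq(span0, span1 - 1, by = cfg$peak_resolution)
          mid <- fs + cfg$peak_resolution / 2
          e <- A * exp(-(mid - lch$center[i])^2 / (2 * lch$sigma[i]^2))
          fine[[i]] <- data.frame(start = fs,
                                  end = fs + cfg$peak_resolution,
                                  value = stats::rnbinom(length(fs),
                                                         size = cfg$bg_dispersion,
                                                         mu = cfg$bg_mean + e))
        }
        fine <- do.call(rbind, fine)
        if (!is.null(fine) && nrow(fine)) {
          drop <- rep(FALSE, nrow(bg))
          # refined spans are snapped to the background grid, so dropping
          # overlapped background windows leaves no gaps
          ov <- interval_overlaps(cbind(chrom = ch, bg),
                                  cbind(chrom = ch, fine))
          drop[unique(ov$a)] <- TRUE
          bg <- bg[!drop, , drop = FALSE]
          bg <- rbind(bg, fine)
          bg <- bg[order(bg$start), , drop = FALSE]
        }
      }
      ri <- ri + 1L
      runs[[ri]] <- cbind(chrom = ch, bg)
    }
    x <- do.call(rbind, runs[seq_len(ri)])
    x <- .rle_merge(x)
    coverage_track(x$chrom, x$start, x$end, x$value,
                   read_length = cfg$read_length, chrom_sizes = sizes,
                   sort = FALSE)
  }
  chip <- build(TRUE)
  input <- build(FALSE)
  list(chip = chip, input = input, bg_sd = bg_sd)
}

# True-enrichment peak calls for one group: the span where enrichment
# exceeds background mean + 3 sd, snapped to the fine grid.
.true_peaks <- function(cfg, layout, group_index) {
  thr <- 3 * sqrt(cfg$bg_mean + cfg$bg_mean^2 / cfg$bg_dispersion)
  loci <- layout$loci
  A <- loci$amplitude * ifelse(loci$planted, cfg$effect_multiplier^group_index, 1)
  h <- ifelse(A > thr, loci$sigma * sqrt(2 * log(pmax(A / thr, 1))), NA_real_)
  keep <- !is.na(h) & h > 0
  p <- data.frame(chrom = loci$chrom[keep],
                  start = pmax(0, floor((loci$center[keep] - h[keep]) /
                                          cfg$peak_resolution) * cfg$peak_resolution),
                  end = pmin(cfg$chrom_length,
                             ceiling((loci$center[keep] + h[keep]) /
                                       cfg$peak_resolution) * cfg$peak_resolution),
                  name = loci$locus_id[keep])
  sort_intervals(p, layout$sizes)
}

#' Simulate a synthetic aging cohort
#'
#' Generates the full fixture set: chromosome sizes, TSS annotation, sample
#' sheet, per-sample ChIP and input coverage, per-sample true-enrichment
#' peak calls, an expression matrix, and the ground-truth manifest of
#' planted loci/genes. Deterministic given `config$seed`; when `dir` is
#' given, everything is also written as the plain-text formats the package
#' reads.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory for fixture files.
#' @return List of class `aging_cohort`: config, chrom_sizes, tss,
#'   sample_sheet, expression, chip_tracks, input_tracks, peaks (per ChIP
#'   sample), truth (loci/genes/ecm_genes/group multipliers), fine_order.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- .with_seed(config$seed, {
    layout <- .cohort_layout(config)
    fine_order <- names(config$group_sizes)
    chip_ids <- sprintf("C%02d", seq_len(sum(config$group_sizes)))
    expr_ids <- sprintf("E%02d", seq_len(sum(config$group_sizes)))
    fine <- rep(fine_order, config$group_sizes)
    ages <- unlist(config$group_ages[fine_order], use.names = FALSE)
    coarse <- ifelse(ages <= config$age_cutoff, "young", "aged")
    sheet <- rbind(
      data.frame(sample_id = chip_ids, age = ages, coarse_group = coarse,
                 fine_group = fine, assay = "H3K27ac"),
      data.frame(sample_id = expr_ids, age = ages, coarse_group = coarse,
                 fine_group = fine, assay = "expression"))
    gidx <- match(fine, fine_order) - 1L
    chip_tracks <- list(); input_tracks <- list(); peaks <- list()
    for (i in seq_along(chip_ids)) {
      tr <- .simulate_sample_tracks(config, layout, gidx[i])
      chip_tracks[[chip_ids[i]]] <- tr$chip
      input_tracks[[chip_ids[i]]] <- tr$input
      peaks[[chip_ids[i]]] <- .true_peaks(config, layout, gidx[i])
    }
    base <- stats::rlnorm(nrow(layout$genes), config$expr_base_meanlog,
                          config$expr_base_sdlog)
    expr <- vapply(seq_along(expr_ids), function(i) {
      eff <- ifelse(layout$genes$planted, config$effect_multiplier^gidx[i], 1)
      round(base * eff * exp(stats::rnorm(nrow(layout$genes), 0,
                                          config$expr_noise_sd)), 4)
    }, numeric(nrow(layout$genes)))
    dimnames(expr) <- list(layout$genes$gene_id, expr_ids)
    s3 <- layout$loci$sigma * 3
    truth <- list(
      loci = cbind(layout$loci,
                   start = pmax(0, layout$loci$center - s3),
                   end = pmin(config$chrom_length, layout$loci$center + s3)),
      genes = layout$genes[c("gene_id", "chrom", "tss", "strand", "planted")],
      ecm_genes = layout$genes$gene_id[layout$genes$planted],
      group_multipliers = stats::setNames(
        config$effect_multiplier^(seq_along(fine_order) - 1L), fine_order))
    structure(list(config = config, chrom_sizes = layout$sizes,
                   tss = layout$genes[c("gene_id", "chrom", "tss", "strand")],
                   sample_sheet = sheet, expression = expr,
                   chip_tracks = chip_tracks, input_tracks = input_tracks,
                   peaks = peaks, truth = truth, fine_order = fine_order),
              class = "aging_cohort")
  })
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.aging_cohort <- function(x, ...) {
  cat(sprintf("aging_cohort: %d chroms x %s bp, %d ChIP samples (%s), %d genes, %d loci (%d planted), multiplier %.2f, seed %d\n",
              length(x$chrom_sizes), format(x$config$chrom_length, scientific = FALSE),
              length(x$chip_tracks), paste(x$fine_order, collapse = "<"),
              nrow(x$tss), nrow(x$truth$loci), sum(x$truth$loci$planted),
              x$config$effect_multiplier, x$config$seed))
  invisible(x)
}

#' Write a cohort as fixture files
#'
#' Emits exactly the formats the package reads: chrom_sizes.tsv, tss.tsv,
#' sample_sheet.tsv, expression.tsv, coverage/<id>_{chip,input}.bedgraph,
#' peaks/<id>.bed, plus the ground-truth manifest (manifest_loci.tsv,
#' manifest_genes.tsv, manifest_params.txt).
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "coverage"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  hdr <- .header_comments(seed = cohort$config$seed)
  write_chrom_sizes(cohort$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  write_tss(cohort$tss, file.path(dir, "tss.tsv"), hdr)
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"), hdr)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"), hdr)
  for (s in names(cohort$chip_tracks)) {
    write_bedgraph(cohort$chip_tracks[[s]],
                   file.path(dir, "coverage", paste0(s, "_chip.bedgraph")))
    write_bedgraph(cohort$input_tracks[[s]],
                   file.path(dir, "coverage", paste0(s, "_input.bedgraph")))
    write_bed(cohort$peaks[[s]], file.path(dir, "peaks", paste0(s, ".bed")))
  }
  loci <- cohort$truth$loci
  loci$sigma <- round(loci$sigma, 4); loci$amplitude <- round(loci$amplitude, 4)
  .write_tsv(loci, file.path(dir, "manifest_loci.tsv"), hdr)
  .write_tsv(cohort$truth$genes, file.path(dir, "manifest_genes.tsv"), hdr)
  gm <- cohort$truth$group_multipliers
  writeLines(c(hdr,
               sprintf("multiplier_%s=%s", names(gm), format(gm, scientific = FALSE)),
               sprintf("effect_multiplier=%s",
                       format(cohort$config$effect_multiplier, scientific = FALSE)),
               sprintf("n_planted=%d", sum(loci$planted))),
             file.path(dir, "manifest_params.txt"))
  invisible(dir)
}

#' Read a cohort fixture directory
#'
#' Inverse of [write_cohort()] (the ground-truth manifest is reloaded when
#' present).
#' @param dir Fixture directory.
#' @param read_length Read-length equivalent for coverage tracks.
#' @return List shaped like [simulate_cohort()]'s result (without `config`).
#' @export
read_cohort <- function(dir, read_length = 100) {
  sizes <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  tss <- read_tss(file.path(dir, "tss.tsv"), sizes)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"), sheet)
  chip_ids <- sheet$sample_id[sheet$assay != "expression"]
  chip_tracks <- lapply(stats::setNames(chip_ids, chip_ids), function(s)
    read_bedgraph(file.path(dir, "coverage", paste0(s, "_chip.bedgraph")),
                  sizes, read_length))
  input_tracks <- lapply(stats::setNames(chip_ids, chip_ids), function(s)
    read_bedgraph(file.path(dir, "coverage", paste0(s, "_input.bedgraph")),
                  sizes, read_length))
  peaks <- lapply(stats::setNames(chip_ids, chip_ids), function(s)
    read_bed(file.path(dir, "peaks", paste0(s, ".bed")), sizes))
  truth <- NULL
  if (file.exists(file.path(dir, "manifest_loci.tsv"))) {
    loci <- .read_tsv(file.path(dir, "manifest_loci.tsv"))
    genes <- .read_tsv(file.path(dir, "manifest_genes.tsv"))
    truth <- list(loci = loci, genes = genes,
                  ecm_genes = genes$gene_id[genes$planted])
  }
  structure(list(chrom_sizes = sizes, tss = tss, sample_sheet = sheet,
                 expression = expr, chip_tracks = chip_tracks,
                 input_tracks = input_tracks, peaks = peaks, truth = truth,
                 fine_order = fine_group_order(sheet)),
            class = "aging_cohort")
}
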