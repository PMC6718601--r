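# End-to-end orchestration: simulate/load -> binned differential -> peak
# atlas -> enhancer calling -> trend clustering -> integration, with every
# stage output written as TSV/BED carrying a provenance header (package
# version, seed, parameters) and a final report of per-stage counts plus
# ground-truth recovery when a manifest is present.

#' Pipeline configuration
#'
#' Defaults follow the analysis parameters where stated (1 Mb bins, z
#' thresholds +/-2, 5 kb TSS exclusion, 2-fold change) and package defaults
#' elsewhere (12.5 kb stitch distance, c = 2 / m = 50 model profiles, 1,000
#' permutations).
#'
#' @param output_dir Where stage outputs are written.
#' @param input_dir Fixture directory readable by [read_cohort()]
#'   (alternative to `synthetic`).
#' @param synthetic A [cohort_config()]; the cohort is simulated into
#'   `output_dir/fixtures` and read back from disk.
#' @param bin_width Genomic bin width in bp.
#' @param z_lo,z_hi Bin z-score call thresholds.
#' @param tss_min_dist Distal-enhancer TSS exclusion distance (bp).
#' @param stitch_distance Peak stitching distance (bp).
#' @param min_fold,fc_pseudocount End-to-end fold-change filter before
#'   trend clustering.
#' @param stem_c,stem_m,n_permutations,alpha Model-profile clustering
#'   parameters.
#' @param de_alpha,lfc_min Differential-expression call thresholds.
#' @param norm_pseudocount Pseudocount for input normalization.
#' @param expressed_floor Mean-expression floor defining the gene universe.
#' @param read_length Read-length equivalent for library sizes.
#' @param seed Seed for every stochastic step.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, input_dir = NULL, synthetic = NULL,
                            bin_width = 1e6, z_lo = -2, z_hi = 2,
                            tss_min_dist = 5000, stitch_distance = 12500,
                            min_fold = 2, fc_pseudocount = 0.1,
                            stem_c = 2, stem_m = 50, n_permutations = 1000,
                            alpha = 0.05, de_alpha = 0.05, lfc_min = 1,
                            norm_pseudocount = 1, expressed_floor = 0.1,
                            read_length = 100, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(input_dir) && is.null(synthetic))
    stop("provide either input_dir or a synthetic cohort_config")
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_config"))
    stop("synthetic must be a cohort_config")
  if (cfg$z_lo >= cfg$z_hi) stop("z_lo must be < z_hi")
  structure(cfg, class = "pipeline_config")
}

.param_header <- function(cfg) {
  keep <- setdiff(names(cfg), c("synthetic", "input_dir", "output_dir"))
  .header_comments(params = cfg[keep], seed = cfg$seed)
}

#' Run the aging-epigenome pipeline
#'
#' Executes the stages in order (bins -> atlas -> enhancers -> trends ->
#' integrate), writing each stage's tables under `config$output_dir`. A
#' stage failure writes a `FAILED` marker naming the stage and re-raises.
#' Reruns with an identical config and seed reproduce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run; `"all"` (default) runs
#'   everything. Prerequisite stages of any requested stage are computed
#'   (but only requested stages are written).
#' @return Invisible list with the in-memory stage results and the `report`
#'   data.frame.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("bins", "atlas", "enhancers", "trends", "integrate")
  if (identical(stages, "all")) stages <- order_all
  unknown <- setdiff(stages, c(order_all, "simulate"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  need <- order_all[seq_len(max(c(0L, match(stages, order_all)), na.rm = TRUE))]
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .param_header(config)
  report <- list()
  note <- function(stage, metric, value)
    report[[length(report) + 1L]] <<- data.frame(stage = stage, metric = metric,
                                                 value = as.character(value))
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(c(sprintf("stage=%s", stage), conditionMessage(e)),
                  file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- load / simulate ----------------------------------------------------
  cohort <- run_stage("load", function() {
    if (!is.null(config$synthetic)) {
      fx <- file.path(out_dir, "fixtures")
      simulate_cohort(config$synthetic, dir = fx)
      read_cohort(fx, read_length = config$read_length)
    } else read_cohort(config$input_dir, read_length = config$read_length)
  })
  sheet <- cohort$sample_sheet
  chip <- sheet[sheet$assay != "expression", , drop = FALSE]
  exprs <- sheet[sheet$assay == "expression", , drop = FALSE]
  young_chip <- chip$sample_id[chip$coarse_group == "young"]
  coarse_chip <- stats::setNames(chip$coarse_group, chip$sample_id)
  fine_chip <- stats::setNames(chip$fine_group, chip$sample_id)
  fine_expr <- stats::setNames(exprs$fine_group, exprs$sample_id)
  res <- list(cohort = cohort)

  # ---- bins ---------------------------------------------------------------
  if ("bins" %in% need) run_stage("bins", function() {
    norm <- stats::setNames(lapply(names(cohort$chip_tracks), function(s)
      input_normalize(cohort$chip_tracks[[s]], cohort$input_tracks[[s]],
                      cohort$chrom_sizes, config$norm_pseudocount)),
      names(cohort$chip_tracks))
    bins <- make_bins(cohort$chrom_sizes, config$bin_width)
    bmat <- bin_signal_matrix(norm, bins)
    diffr <- bin_differential(bmat, young_chip, config$z_lo, config$z_hi)
    fr_inc <- stats::setNames(diffr$summary$frac_increased, diffr$summary$sample_id)
    fr_dec <- stats::setNames(diffr$summary$frac_decreased, diffr$summary$sample_id)
    cmp <- list(
      increased_two_sided = compare_group_fractions(fr_inc, coarse_chip, "two.sided"),
      increased_greater = compare_group_fractions(fr_inc, coarse_chip, "greater"),
      decreased_two_sided = compare_group_fractions(fr_dec, coarse_chip, "two.sided"))
    if ("bins" %in% stages) {
      zt <- cbind(bins[c("chrom", "start", "end")],
                  stats::setNames(as.data.frame(round(diffr$z, 4)),
                                  paste0("z_", colnames(diffr$z))),
                  stats::setNames(as.data.frame(diffr$calls),
                                  paste0("call_", colnames(diffr$calls))))
      .write_tsv(zt, file.path(out_dir, "bins_z.tsv"), hdr)
      .write_tsv(diffr$summary, file.path(out_dir, "bins_summary.tsv"), hdr)
      cmp_df <- do.call(rbind, lapply(names(cmp), function(k)
        data.frame(comparison = k, statistic = cmp[[k]]$statistic,
                   p = cmp[[k]]$p.value, median_young = cmp[[k]]$median_young,
                   median_aged = cmp[[k]]$median_aged)))
      .write_tsv(cmp_df, file.path(out_dir, "bins_group_comparison.tsv"), hdr)
    }
    note("bins", "n_bins", nrow(bins))
    note("bins", "mean_frac_increased_young",
         round(mean(fr_inc[names(coarse_chip)[coarse_chip == "young"]]), 6))
    note("bins", "mean_frac_increased_aged",
         round(mean(fr_inc[names(coarse_chip)[coarse_chip == "aged"]]), 6))
    note("bins", "p_increased_greater", signif(cmp$increased_greater$p.value, 6))
    res$norm_tracks <<- norm
    res$bins <<- list(bins = bins, matrix = bmat, differential = diffr,
                      comparison = cmp)
  })

  # ---- atlas --------------------------------------------------------------
  if ("atlas" %in% need) run_stage("atlas", function() {
    atlas <- build_atlas(cohort$peaks, cohort$chrom_sizes)
    if ("atlas" %in% stages)
      write_atlas(atlas, file.path(out_dir, "atlas.bed"),
                  file.path(out_dir, "atlas_provenance.tsv"), hdr)
    note("atlas", "n_entries", nrow(atlas$entries))
    note("atlas", "n_merged", sum(atlas$entries$category == "merged"))
    res$atlas <<- atlas
  })

  # ---- enhancers ----------------------------------------------------------
  if ("enhancers" %in% need) run_stage("enhancers", function() {
    pars <- list(tss_exclusion = config$tss_min_dist,
                 stitch_distance = config$stitch_distance)
    se_sets <- list()
    distal_by_sample <- list()
    for (s in names(cohort$peaks)) {
      distal <- distal_filter(merge_union(cohort$peaks[[s]], cohort$chrom_sizes),
                              cohort$tss, config$tss_min_dist)
      distal_by_sample[[s]] <- distal
      st <- stitch(distal, config$stitch_distance)
      st <- enhancer_signal(st, cpm_scale(cohort$chip_tracks[[s]]),
                            cpm_scale(cohort$input_tracks[[s]]))
      se_sets[[s]] <- call_super_enhancers(st, pars)
    }
    groups <- se_group_profiles(se_sets, coarse_chip)
    union_se <- merge_union(do.call(rbind, lapply(groups$group_sets, function(g)
      g[c("chrom", "start", "end")])))
    secor <- if (nrow(union_se) >= 3L) {
      union_se$name <- sprintf("se_%04d", seq_len(nrow(union_se)))
      m <- vapply(names(res$norm_tracks), function(s)
        region_mean_signal(res$norm_tracks[[s]], union_se),
        numeric(nrow(union_se)))
      se_correlation(matrix(m, nrow = nrow(union_se),
                            dimnames = list(union_se$name, names(res$norm_tracks))))
    } else NULL
    if ("enhancers" %in% stages) {
      dir.create(file.path(out_dir, "enhancers"), showWarnings = FALSE)
      for (s in names(se_sets)) {
        e <- se_sets[[s]]$enhancers
        ranked <- data.frame(rank = e$rank, chrom = e$chrom, start = e$start,
                             end = e$end, n_constituents = e$n_constituents,
                             signal = round(e$signal, 4), is_super = e$is_super)
        .write_tsv(ranked, file.path(out_dir, "enhancers",
                                     paste0(s, "_ranked.tsv")), hdr)
        write_bed(e[e$is_super, c("chrom", "start", "end", "name")],
                  file.path(out_dir, "enhancers", paste0(s, "_SE.bed")), hdr)
        write_bed(e[!e$is_super, c("chrom", "start", "end", "name")],
                  file.path(out_dir, "enhancers", paste0(s, "_TE.bed")), hdr)
      }
      .write_tsv(data.frame(category = names(groups$venn),
                            count = as.integer(groups$venn)),
                 file.path(out_dir, "se_venn.tsv"), hdr)
      if (!is.null(secor))
        .write_tsv(cbind(data.frame(sample_id = rownames(secor)),
                         as.data.frame(round(secor, 4))),
                   file.path(out_dir, "se_correlation.tsv"), hdr)
    }
    n_se <- vapply(se_sets, function(x) x$cutoff_rank, 0L)
    note("enhancers", "mean_n_super", round(mean(n_se), 2))
    note("enhancers", "mean_n_typical",
         round(mean(vapply(se_sets, function(x) nrow(x$enhancers), 0L) - n_se), 2))
    for (k in names(groups$venn)) note("enhancers", k, groups$venn[[k]])
    res$enhancers <<- list(se_sets = se_sets, groups = groups,
                           distal_by_sample = distal_by_sample,
                           se_correlation = secor)
  })

  # ---- trends -------------------------------------------------------------
  if ("trends" %in% need) run_stage("trends", function() {
    constituents <- distal_filter(res$atlas$entries, cohort$tss,
                                  config$tss_min_dist)
    rpkm_mat <- region_rpkm_matrix(constituents, cohort$chip_tracks)
    ogm_enh <- group_means(rpkm_mat, fine_chip, cohort$fine_order)
    filt_enh <- fold_change_filter(ogm_enh, min_fold = config$min_fold,
                                   pseudocount = config$fc_pseudocount)
    tps_enh <- cluster_trends(filt_enh, c = config$stem_c, m = config$stem_m,
                              n_permutations = config$n_permutations,
                              alpha = config$alpha, seed = config$seed)
    activated <- select_trend_members(tps_enh, "increasing")
    deactivated <- select_trend_members(tps_enh, "decreasing")

    ogm_expr <- group_means(cohort$expression, fine_expr, cohort$fine_order)
    filt_expr <- fold_change_filter(ogm_expr, min_fold = config$min_fold,
                                    pseudocount = config$fc_pseudocount)
    tps_expr <- cluster_trends(filt_expr, c = config$stem_c, m = config$stem_m,
                               n_permutations = config$n_permutations,
                               alpha = config$alpha, seed = config$seed)
    up_genes <- select_trend_members(tps_expr, "increasing")
    down_genes <- select_trend_members(tps_expr, "decreasing")
    if ("trends" %in% stages) {
      write_trend_tables(tps_enh, ogm_enh, file.path(out_dir, "trends_enhancer"), hdr)
      write_trend_tables(tps_expr, ogm_expr, file.path(out_dir, "trends_expression"), hdr)
      .write_tsv(data.frame(feature = activated, direction = "increasing"),
                 file.path(out_dir, "activated_constituents.tsv"), hdr)
      .write_tsv(data.frame(gene_id = c(up_genes, down_genes),
                            direction = rep(c("increasing", "decreasing"),
                                            c(length(up_genes), length(down_genes)))),
                 file.path(out_dir, "trend_genes.tsv"), hdr)
    }
    note("trends", "n_constituents", nrow(constituents))
    note("trends", "n_constituents_fold_pass", nrow(filt_enh))
    note("trends", "n_activated_constituents", length(activated))
    note("trends", "n_deactivated_constituents", length(deactivated))
    note("trends", "n_genes_fold_pass", nrow(filt_expr))
    note("trends", "n_increasing_genes", length(up_genes))
    note("trends", "n_decreasing_genes", length(down_genes))
    res$trends <<- list(constituents = constituents, rpkm = rpkm_mat,
                        enhancer = tps_enh, expression = tps_expr,
                        activated = activated, deactivated = deactivated,
                        up_genes = up_genes, down_genes = down_genes)
  })

  # ---- integrate ----------------------------------------------------------
  if ("integrate" %in% need) run_stage("integrate", function() {
    tr <- res$trends
    assign <- nearest_gene(tr$constituents, cohort$tss)
    activated_genes <- sort(unique(assign$gene_id[assign$feature %in% tr$activated]))
    universe <- rownames(cohort$expression)[
      rowMeans(cohort$expression) >= config$expressed_floor]
    ov <- overlap_enrichment(intersect(activated_genes, universe),
                             intersect(tr$up_genes, universe), universe)
    de <- two_group_de(cohort$expression,
                       exprs$sample_id[exprs$coarse_group == "young"],
                       exprs$sample_id[exprs$coarse_group == "aged"],
                       alpha = config$de_alpha, lfc_min = config$lfc_min)
    targets <- lapply(split(chip$sample_id, chip$coarse_group), function(ids) {
      sort(unique(unlist(lapply(ids, function(s) {
        d <- res$enhancers$distal_by_sample[[s]]
        if (nrow(d) == 0L) character(0) else nearest_gene(d, cohort$tss)$gene_id
      }))))
    })
    ecm <- cohort$truth$ecm_genes
    ecm_summary <- if (length(ecm)) geneset_fraction_summary(de, ecm) else NULL
    ecm_active <- if (length(ecm))
      geneset_active_enhancer_fraction(ecm, targets) else NULL
    if ("integrate" %in% stages) {
      .write_tsv(assign, file.path(out_dir, "nearest_gene.tsv"), hdr)
      .write_tsv(data.frame(metric = c("n_activated_genes", "n_up_genes",
                                       "n_universe", "n_overlap", "fraction", "p"),
                            value = c(ov$n_a, ov$n_b, ov$n_universe, ov$n_overlap,
                                      signif(ov$fraction, 6), signif(ov$p, 6))),
                 file.path(out_dir, "overlap_enrichment.tsv"), hdr)
      de_out <- de
      for (k in c("mean_a", "mean_b", "lfc", "t", "df"))
        de_out[[k]] <- round(de_out[[k]], 4)
      de_out$p <- signif(de_out$p, 6)
      .write_tsv(de_out, file.path(out_dir, "differential_expression.tsv"), hdr)
      if (!is.null(ecm_summary))
        .write_tsv(data.frame(metric = c(paste0("frac_", names(ecm_summary)),
                                         paste0("active_enhancer_frac_",
                                                names(ecm_active))),
                              value = signif(c(ecm_summary, ecm_active), 6)),
                   file.path(out_dir, "ecm_geneset.tsv"), hdr)
    }
    note("integrate", "n_activated_genes", length(activated_genes))
    note("integrate", "overlap_fraction", signif(ov$fraction, 6))
    note("integrate", "overlap_p", signif(ov$p, 6))
    note("integrate", "n_de_up", sum(de$call == "up"))
    note("integrate", "n_de_down", sum(de$call == "down"))
    truth_scores <- NULL
    if (!is.null(cohort$truth)) {
      loci <- cohort$truth$loci
      planted <- loci[loci$planted, , drop = FALSE]
      act_regions <- tr$constituents[tr$constituents$name %in% tr$activated, ,
                                     drop = FALSE]
      hits <- interval_overlaps(planted, act_regions)
      locus_recall <- if (nrow(planted)) length(unique(hits$a)) / nrow(planted) else NA
      hit_all <- interval_overlaps(loci[loci$planted, ], act_regions)
      act_precision <- if (nrow(act_regions))
        length(unique(hit_all$b)) / nrow(act_regions) else NA
      inter <- intersect(activated_genes, tr$up_genes)
      ecm_recall <- if (length(ecm)) mean(ecm %in% inter) else NA
      truth_scores <- c(planted_locus_recall = locus_recall,
                        activated_precision = act_precision,
                        ecm_intersection_recall = ecm_recall)
      for (k in names(truth_scores))
        note("truth", k, signif(truth_scores[[k]], 6))
    }
    res$integration <<- list(assign = assign, activated_genes = activated_genes,
                             universe = universe, overlap = ov, de = de,
                             targets = targets, ecm_summary = ecm_summary,
                             ecm_active = ecm_active, truth_scores = truth_scores)
  })

  report_df <- do.call(rbind, report)
  .write_tsv(report_df, file.path(out_dir, "report.tsv"), hdr)
  writeLines(hdr, file.path(out_dir, "run_manifest.txt"))
  res$report <- report_df
  invisible(res)
}

#' Write trend-clustering tables
#'
#' Profiles, assignments and significance of a [cluster_trends()] result as
#' TSVs under `prefix`_{profiles,assignments,significance}.tsv.
#' @param tps A `trend_profile_set`.
#' @param ogm The group-mean matrix it was fitted to.
#' @param prefix Output path prefix.
#' @param comments Header comment lines.
#' @export
write_trend_tables <- function(tps, ogm, prefix, comments = NULL) {
  prof <- as.data.frame(unclass(tps$profiles))
  names(prof) <- colnames(ogm)
  prof <- cbind(data.frame(profile = seq_len(nrow(prof))), prof,
                monotone_up = monotone_profiles(tps$profiles, "increasing"),
                monotone_down = monotone_profiles(tps$profiles, "decreasing"))
  .write_tsv(prof, paste0(prefix, "_profiles.tsv"), comments)
  .write_tsv(data.frame(feature = names(tps$assignments),
                        profile = as.integer(tps$assignments)),
             paste0(prefix, "_assignments.tsv"), comments)
  sig <- tps$significance
  sig$expected <- round(sig$expected, 4)
  sig$p <- signif(sig$p, 6); sig$p_adj <- signif(sig$p_adj, 6)
  .write_tsv(sig, paste0(prefix, "_significance.tsv"), comments)
  invisible(prefix)
}
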