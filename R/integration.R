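# Enhancer-gene integration: nearest-TSS target assignment for enhancer
# constituents, exact hypergeometric overlap of gene sets, a simplified
# Welch two-group differential-expression test on log2 values, and gene-set
# summaries (up/down fractions; fraction of a set targeted by at least one
# active enhancer per condition).

#' Assign each constituent its nearest gene
#'
#' Distance is measured from the constituent midpoint (integer floor of
#' (start+end)/2) to the TSS position, with no distance cap; ties resolve to
#' the lexicographically smaller gene id. The signed distance is positive
#' when the constituent lies downstream of the TSS in the gene's strand
#' orientation.
#'
#' @param constituents Interval data.frame (a `name` column is used as the
#'   feature id when present, else row numbers).
#' @param tss TSS annotation (gene_id/chrom/tss/strand), non-empty.
#' @return data.frame: feature, gene_id, distance (signed bp). Constituents
#'   on chromosomes without any annotated TSS get NA with a warning.
#' @export
nearest_gene <- function(constituents, tss) {
  if (is.null(tss) || nrow(tss) == 0L) stop("TSS annotation is empty")
  validate_intervals(constituents, what = "constituent")
  feature <- if (!is.null(constituents$name)) constituents$name
             else as.character(seq_len(nrow(constituents)))
  mid <- floor((constituents$start + constituents$end) / 2)
  gene <- rep(NA_character_, nrow(constituents))
  dist <- rep(NA_real_, nrow(constituents))
  for (ch in unique(constituents$chrom)) {
    ic <- which(constituents$chrom == ch)
    t_ch <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(t_ch) == 0L) next
    # collapse duplicate positions to the lexicographically smallest gene id
    t_ch <- t_ch[order(t_ch$tss, t_ch$gene_id), , drop = FALSE]
    first <- !duplicated(t_ch$tss)
    pos <- t_ch$tss[first]; gid <- t_ch$gene_id[first]; strand <- t_ch$strand[first]
    j <- findInterval(mid[ic], pos)
    for (k in seq_along(ic)) {
      cand <- unique(pmin(pmax(c(j[k], j[k] + 1L), 1L), length(pos)))
      d <- abs(pos[cand] - mid[ic[k]])
      best <- cand[d == min(d)]
      pick <- best[order(gid[best])][1L]
      sgn <- if (strand[pick] == "+") sign(mid[ic[k]] - pos[pick])
             else sign(pos[pick] - mid[ic[k]])
      gene[ic[k]] <- gid[pick]
      dist[ic[k]] <- sgn * abs(mid[ic[k]] - pos[pick])
    }
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " constituent(s) on chromosomes without TSS annotation")
  data.frame(feature = feature, gene_id = gene, distance = dist)
}

#' Hypergeometric overlap of two gene sets
#'
#' Exact upper-tail probability of drawing at least the observed overlap
#' when `|a|` genes are drawn from the universe containing `|b|` successes.
#'
#' @param genes_a,genes_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of the background gene universe.
#' @return List of class `overlap_result`: sizes, overlap members,
#'   `fraction` (overlap / |a|) and hypergeometric `p`.
#' @export
overlap_enrichment <- function(genes_a, genes_b, universe) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  universe <- unique(universe)
  out_a <- setdiff(genes_a, universe); out_b <- setdiff(genes_b, universe)
  if (length(out_a) || length(out_b))
    stop("gene set not contained in universe: ",
         paste(utils::head(c(out_a, out_b), 5L), collapse = ", "))
  ov <- intersect(genes_a, genes_b)
  k <- length(ov)
  p <- stats::phyper(k - 1L, length(genes_b),
                     length(universe) - length(genes_b),
                     length(genes_a), lower.tail = FALSE)
  structure(list(n_a = length(genes_a), n_b = length(genes_b),
                 n_universe = length(universe), n_overlap = k,
                 overlap = ov,
                 fraction = if (length(genes_a)) k / length(genes_a) else NA_real_,
                 p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d of %d set-A genes overlap %d set-B genes (universe %d); fraction %.3f, hypergeometric p = %.3g\n",
              x$n_overlap, x$n_a, x$n_b, x$n_universe, x$fraction, x$p))
  invisible(x)
}

#' Two-group differential expression (Welch t on log2 values)
#'
#' A deliberately simple stand-in for platform-specific differential
#' testing: per gene, a Welch unequal-variance t-test on
#' `log2(x + pseudocount)`, with calls `up` iff `lfc >= lfc_min` and
#' `p < alpha` (symmetrically for `down`). Genes with zero variance in both
#' groups get p = 1 when the means agree and p = 0 when they differ.
#'
#' @param expr Gene x sample non-negative matrix.
#' @param group_a_ids,group_b_ids Column ids of the two groups (>= 2 each);
#'   fold change is B versus A.
#' @param alpha P-value threshold. Default 0.05.
#' @param lfc_min Minimum |log2 fold change| for a call. Default 1.
#' @param pseudocount Log-transform pseudocount. Default 1.
#' @return data.frame per gene: mean_a, mean_b (log2 scale), lfc, t, df, p,
#'   call in {up, down, unchanged}.
#' @export
two_group_de <- function(expr, group_a_ids, group_b_ids, alpha = 0.05,
                         lfc_min = 1, pseudocount = 1) {
  miss <- setdiff(c(group_a_ids, group_b_ids), colnames(expr))
  if (length(miss)) stop("sample(s) absent from matrix: ", paste(miss, collapse = ", "))
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L)
    stop("each group needs at least 2 samples")
  L <- log2(expr + pseudocount)
  A <- L[, group_a_ids, drop = FALSE]; B <- L[, group_b_ids, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  se2 <- vA / nA + vB / nB
  lfc <- mB - mA
  t <- lfc / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  t[degen] <- sign(lfc[degen]) * Inf
  t[degen & lfc == 0] <- 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  call <- rep("unchanged", nrow(expr))
  call[p < alpha & lfc >= lfc_min] <- "up"
  call[p < alpha & lfc <= -lfc_min] <- "down"
  data.frame(gene_id = rownames(expr), mean_a = mA, mean_b = mB, lfc = lfc,
             t = t, df = df, p = p,
             call = factor(call, levels = c("up", "down", "unchanged")),
             row.names = NULL)
}

#' Up/down/unchanged fractions within a gene set
#'
#' @param de A [two_group_de()] result.
#' @param gene_set Non-empty character vector, subset of the DE universe.
#' @return Named numeric vector (up/down/unchanged) summing to 1.
#' @export
geneset_fraction_summary <- function(de, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("gene set is empty")
  miss <- setdiff(gene_set, de$gene_id)
  if (length(miss)) stop("gene(s) absent from DE result: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  calls <- de$call[match(gene_set, de$gene_id)]
  tab <- table(calls) / length(gene_set)
  c(up = unname(tab["up"]), down = unname(tab["down"]),
    unchanged = unname(tab["unchanged"]))
}

#' Fraction of a gene set with at least one active enhancer, per condition
#'
#' "Active" means the gene is the nearest-gene target of at least one
#' enhancer in that condition's call set.
#'
#' @param gene_set Non-empty character vector.
#' @param targets_by_condition Named list: condition -> character vector of
#'   genes targeted by >= 1 active enhancer in that condition.
#' @return Named numeric vector of per-condition fractions.
#' @export
geneset_active_enhancer_fraction <- function(gene_set, targets_by_condition) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("gene set is empty")
  vapply(targets_by_condition,
         function(tg) mean(gene_set %in% tg), numeric(1L))
}
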