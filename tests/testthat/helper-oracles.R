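# Independent brute-force oracles. Each works base-by-base or by exhaustive
# enumeration on small instances and shares no code path with the package
# implementation it checks.

# O(n^2) union via the pairwise strict-overlap graph (>= 1 shared base;
# half-open abutment is not overlap): transitive components, one output
# interval per component spanning min start to max end.
oracle_union <- function(x, max_coord = 2000L) {
  out <- NULL
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    n <- nrow(xi)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            xi$start[i] < xi$end[j] && xi$start[j] < xi$end[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    spans <- do.call(rbind, lapply(unique(comp), function(k)
      data.frame(chrom = ch, start = min(xi$start[comp == k]),
                 end = max(xi$end[comp == k]))))
    out <- rbind(out, spans[order(spans$start), , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# Per-base signal vector for one chromosome of a track.
oracle_expand <- function(track, ch, max_coord) {
  v <- numeric(max_coord)
  ti <- track[track$chrom == ch, , drop = FALSE]
  for (i in seq_len(nrow(ti)))
    v[(ti$start[i] + 1L):ti$end[i]] <- ti$value[i]
  v
}

# Length-weighted mean signal over regions, base by base.
oracle_region_mean <- function(track, regions, max_coord = 2000L) {
  vapply(seq_len(nrow(regions)), function(i) {
    v <- oracle_expand(track, regions$chrom[i], max_coord)
    mean(v[(regions$start[i] + 1L):regions$end[i]])
  }, numeric(1L))
}

# Young-cohort z-scores by direct formula, looped.
oracle_zscores <- function(values, ref_ids, test_id) {
  vapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ref_ids]
    s <- sqrt(sum((y - mean(y))^2) / (length(y) - 1L))
    if (s == 0) NA_real_ else (values[i, test_id] - mean(y)) / s
  }, numeric(1L))
}

# Exhaustive nearest-TSS search with (distance, gene_id) lexicographic ties.
oracle_nearest <- function(constituents, tss) {
  vapply(seq_len(nrow(constituents)), function(i) {
    mid <- floor((constituents$start[i] + constituents$end[i]) / 2)
    cand <- tss[tss$chrom == constituents$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    d <- abs(cand$tss - mid)
    cand$gene_id[order(d, cand$gene_id)][1L]
  }, character(1L))
}

# Spearman as rank-then-Pearson, computed by explicit formula.
oracle_spearman <- function(m) {
  r <- apply(m, 2L, rank)
  k <- ncol(m)
  out <- diag(1, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- r[, i] - mean(r[, i]); b <- r[, j] - mean(r[, j])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# Exact upper-tail overlap probability by enumerating every |a|-subset of a
# small universe.
oracle_hyper <- function(n_universe, n_a, n_b, k_observed) {
  draws <- utils::combn(n_universe, n_a)
  b_set <- seq_len(n_b)   # which elements are "successes" is arbitrary
  hits <- apply(draws, 2L, function(d) sum(d %in% b_set))
  mean(hits >= k_observed)
}

# Exhaustive index scan for the rank-curve tangent cutoff: walk every index
# of the scaled curve and find the last one strictly below the diagonal.
oracle_rose <- function(signal) {
  n <- length(signal)
  ss <- sort(signal)
  last_below <- NA
  for (i in seq_len(n)) {
    y <- ss[i] / ss[n]; x <- (i - 1) / (n - 1)
    if (y < x) last_below <- i
  }
  if (is.na(last_below)) rep(FALSE, n) else signal > ss[last_below]
}

# Atlas oracle: union mask entries + per-entry support by base sharing.
oracle_atlas <- function(peaks_by_sample, max_coord = 2000L) {
  pooled <- do.call(rbind, lapply(names(peaks_by_sample), function(s)
    cbind(peaks_by_sample[[s]][c("chrom", "start", "end")], sample_id = s)))
  entries <- oracle_union(pooled, max_coord)
  support <- lapply(seq_len(nrow(entries)), function(i) {
    hit <- pooled$chrom == entries$chrom[i] &
      pooled$start < entries$end[i] & pooled$end > entries$start[i]
    sort(unique(pooled$sample_id[hit]))
  })
  entries$samples <- vapply(support, paste, "", collapse = ",")
  entries
}
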