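# Short-series model-profile clustering across ordered age groups. Integer
# model profiles of length T (start 0, per-step change in [-c, c]) are
# enumerated; m representatives are chosen by greedy max-min selection under
# Euclidean distance (the flat profile is always kept and the first pick is
# the profile farthest from flat). Each feature's group-mean series is
# assigned to the profile maximizing Pearson correlation; per-profile
# significance comes from a column-permutation null with a binomial tail and
# Bonferroni correction.

#' Per-group mean matrix over ordered groups
#'
#' @param m Feature x sample numeric matrix with column names.
#' @param group_map Named character vector: sample id -> group label.
#' @param group_order Character vector of group labels, youngest first;
#'   every group must have at least one sample.
#' @return Feature x group matrix of arithmetic means, columns in
#'   `group_order`.
#' @export
group_means <- function(m, group_map, group_order) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  miss <- setdiff(colnames(m), names(group_map))
  if (length(miss)) stop("sample(s) without group: ", paste(miss, collapse = ", "))
  out <- vapply(group_order, function(g) {
    ids <- intersect(colnames(m), names(group_map)[group_map == g])
    if (length(ids) == 0L) stop("empty group: ", g)
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), group_order))
}

#' Reads/RPKM normalization for genomic regions
#'
#' `RPKM = mass / (length/1000) / (total_mapped/1e6)` where `mass` is the
#' read-equivalent count in the region.
#'
#' @param length_bp Region length(s) in bp (> 0).
#' @param mass Read-equivalent count(s) in the region.
#' @param total_mapped Library size in read equivalents (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(1000, 10, 1e6)  # 10
rpkm <- function(length_bp, mass, total_mapped) {
  if (any(length_bp <= 0)) stop("region length must be > 0")
  if (any(total_mapped <= 0)) stop("library size must be > 0")
  mass / (length_bp / 1000) / (total_mapped / 1e6)
}

#' RPKM matrix of regions across samples
#'
#' Converts raw coverage mass over each region into RPKM using each track's
#' read-length-equivalent library size.
#' @param regions Interval data.frame.
#' @param tracks Named list of raw (un-normalized) [coverage_track()]s.
#' @return Region x sample RPKM matrix (rownames from `regions$name` when
#'   present).
#' @export
region_rpkm_matrix <- function(regions, tracks) {
  len <- regions$end - regions$start
  m <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    counts <- region_mass(tr, regions) / attr(tr, "read_length")
    rpkm(len, counts, total_mapped(tr))
  }, numeric(nrow(regions)))
  m <- matrix(m, nrow = nrow(regions), dimnames = list(regions$name, names(tracks)))
  m
}

#' Filter features by end-to-end fold change
#'
#' Retains rows whose pseudocounted ratio between the first and last group
#' (either direction) is at least `min_fold`.
#'
#' @param ogm Feature x group matrix (ordered groups).
#' @param first_group,last_group Column names to compare; default first and
#'   last column.
#' @param min_fold Minimum fold change, default 2 ("at least twofold").
#' @param pseudocount Added to both values before the ratio. Default 0.1.
#' @return The retained submatrix (attribute `retained`: logical vector over
#'   input rows).
#' @export
fold_change_filter <- function(ogm, first_group = colnames(ogm)[1L],
                               last_group = colnames(ogm)[ncol(ogm)],
                               min_fold = 2, pseudocount = 0.1) {
  stopifnot(all(c(first_group, last_group) %in% colnames(ogm)))
  a <- ogm[, first_group] + pseudocount
  b <- ogm[, last_group] + pseudocount
  keep <- pmax(a, b) / pmin(a, b) >= min_fold
  out <- ogm[keep, , drop = FALSE]
  attr(out, "retained") <- keep
  out
}

# All integer profiles of length T starting at 0 with steps in [-c, c],
# sorted lexicographically. Rows are profiles.
.enumerate_profiles <- function(T, c) {
  steps <- as.matrix(expand.grid(rep(list(seq(-c, c)), T - 1L)))
  prof <- cbind(0L, t(apply(steps, 1L, cumsum)))
  if (T == 2L) prof <- cbind(0L, steps)  # apply drops dims for one column
  colnames(prof) <- NULL
  prof[do.call(order, as.data.frame(prof)), , drop = FALSE]
}

#' Generate model profiles
#'
#' Enumerates all `(2c+1)^(T-1)` candidate profiles and selects `m`
#' representatives by greedy max-min selection under Euclidean distance: the
#' flat (all-zero) profile is always included, the first pick is the profile
#' farthest from flat, and ties resolve to the lexicographically smallest
#' candidate. Deterministic.
#'
#' @param T Number of ordered groups (>= 2).
#' @param c Maximum per-step change (>= 1). Default 2.
#' @param m Number of profiles to keep (<= candidate count). Default 50.
#' @param seed Recorded in the result for provenance (the selection itself
#'   is deterministic).
#' @return Integer matrix m x T of class `trend_profiles` (row ids are
#'   profile ids; row 1 is flat), with parameters in attributes.
#' @export
generate_model_profiles <- function(T, c = 2, m = 50, seed = 1L) {
  stopifnot(T >= 2L, c >= 1L)
  cand <- .enumerate_profiles(T, c)
  if (m > nrow(cand))
    stop(sprintf("m = %d exceeds the %d candidate profiles", m, nrow(cand)))
  flat <- which(rowSums(cand != 0L) == 0L)
  selected <- flat
  mind <- sqrt(rowSums(sweep(cand, 2L, cand[flat, ])^2))
  while (length(selected) < m) {
    pick <- which.max(mind)  # first max = lexicographically smallest tie
    selected <- c(selected, pick)
    d <- sqrt(rowSums(sweep(cand, 2L, cand[pick, ])^2))
    mind <- pmin(mind, d)
  }
  prof <- cand[selected, , drop = FALSE]
  rownames(prof) <- seq_len(m)
  structure(prof, class = c("trend_profiles", class(prof)),
            T = T, c = c, m = m, seed = seed)
}

# Row-standardize (z-score rows); constant rows -> NA rows.
.zrows <- function(m) {
  mu <- rowMeans(m)
  sdev <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  (m - mu) / sdev
}

#' Assign features to model profiles
#'
#' Each row (its group-mean series) goes to the profile maximizing Pearson
#' correlation; ties break to the lower profile id. The flat profile has
#' undefined correlation and never receives members. Constant rows must be
#' excluded upstream.
#'
#' @param rows Feature x group numeric matrix (no constant rows).
#' @param profiles A [generate_model_profiles()] matrix.
#' @return Integer vector of profile ids, named by feature.
#' @export
assign_to_profiles <- function(rows, profiles) {
  stopifnot(ncol(rows) == ncol(profiles))
  zr <- .zrows(rows)
  if (anyNA(zr)) stop("constant row(s) reached assign_to_profiles; filter them first")
  zp <- .zrows(profiles)
  ok <- which(!is.na(zp[, 1L]))  # drop flat (zero variance)
  corr <- zr %*% t(zp[ok, , drop = FALSE]) / (ncol(rows) - 1L)
  best <- ok[max.col(corr, ties.method = "first")]
  stats::setNames(as.integer(best), rownames(rows))
}

# All permutations of 1..n, one per row (lexicographic order).
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation significance of profile memberships
#'
#' The null distribution of per-profile member counts is estimated by
#' permuting each row's T group values uniformly (all T! orders equally
#' likely) and re-assigning; `p = P(Binomial(N, expected/N) >= observed)`
#' with the permutation-averaged expected count, Bonferroni-corrected over
#' the m profiles.
#'
#' @param rows Feature x group matrix (no constant rows).
#' @param profiles A [generate_model_profiles()] matrix.
#' @param n_permutations Number of permutation rounds (>= 100). Default 1000.
#' @param alpha Significance level on the corrected p. Default 0.05.
#' @param seed RNG seed for the permutations.
#' @return data.frame per profile: observed, expected, p, p_adj,
#'   significant.
#' @export
profile_significance <- function(rows, profiles, n_permutations = 1000,
                                 alpha = 0.05, seed = 1L) {
  if (n_permutations < 100) stop("need at least 100 permutations")
  m <- nrow(profiles); N <- nrow(rows); Tn <- ncol(rows)
  obs <- tabulate(assign_to_profiles(rows, profiles), nbins = m)
  zr <- .zrows(rows)              # permutation-invariant standardization
  zp <- .zrows(profiles)
  ok <- which(!is.na(zp[, 1L]))
  zp_ok <- t(zp[ok, , drop = FALSE]) / (Tn - 1L)
  perms <- .all_permutations(Tn)
  null_counts <- numeric(m)
  rows_idx <- rep(seq_len(N), times = Tn)
  .with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      pid <- sample.int(nrow(perms), N, replace = TRUE)
      zperm <- matrix(zr[cbind(rows_idx, as.vector(perms[pid, ]))], N, Tn)
      best <- ok[max.col(zperm %*% zp_ok, ties.method = "first")]
      null_counts <- null_counts + tabulate(best, nbins = m)
    }
  })
  expected <- null_counts / n_permutations
  p <- stats::pbinom(obs - 1L, N, pmin(1, expected / N), lower.tail = FALSE)
  p_adj <- pmin(1, p * m)
  data.frame(profile = seq_len(m), observed = obs, expected = expected,
             p = p, p_adj = p_adj, significant = p_adj < alpha)
}

#' Cluster a group-mean matrix against model profiles
#'
#' Convenience wrapper: log2-transforms (pseudocount 1), drops constant and
#' all-zero rows, generates profiles, assigns features and scores profile
#' significance.
#'
#' @param ogm Feature x ordered-group matrix of non-negative values.
#' @param c,m,n_permutations,alpha,seed Passed through to profile
#'   generation/significance.
#' @param log_transform Apply `log2(x + pseudocount)` first. Default TRUE.
#' @param pseudocount Log-transform pseudocount. Default 1.
#' @return List of class `trend_profile_set`: `profiles`, `assignments`,
#'   `significance`, `excluded` (ids of constant rows), `parameters`.
#' @export
cluster_trends <- function(ogm, c = 2, m = 50, n_permutations = 1000,
                           alpha = 0.05, seed = 1L, log_transform = TRUE,
                           pseudocount = 1) {
  x <- if (log_transform) log2(ogm + pseudocount) else ogm
  constant <- apply(x, 1L, function(r) max(r) == min(r))
  excluded <- rownames(x)[constant]
  x <- x[!constant, , drop = FALSE]
  if (nrow(x) == 0L) stop("no non-constant rows to cluster")
  profiles <- generate_model_profiles(ncol(x), c = c, m = m, seed = seed)
  assignments <- assign_to_profiles(x, profiles)
  significance <- profile_significance(x, profiles,
                                       n_permutations = n_permutations,
                                       alpha = alpha, seed = seed)
  structure(list(profiles = profiles, assignments = assignments,
                 significance = significance, excluded = excluded,
                 parameters = list(c = c, m = m,
                                   n_permutations = n_permutations,
                                   alpha = alpha, seed = seed,
                                   log_transform = log_transform,
                                   pseudocount = pseudocount)),
            class = "trend_profile_set")
}

#' @export
print.trend_profile_set <- function(x, ...) {
  cat(sprintf("trend_profile_set: %d profiles (T = %d), %d assigned features, %d significant profiles, %d constant rows excluded\n",
              nrow(x$profiles), ncol(x$profiles), length(x$assignments),
              sum(x$significance$significant), length(x$excluded)))
  invisible(x)
}

#' Profile monotonicity
#'
#' @param profiles A profile matrix.
#' @param direction `"increasing"` (non-decreasing with >= 1 strict step) or
#'   `"decreasing"`.
#' @return Logical vector over profiles.
#' @export
monotone_profiles <- function(profiles, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  apply(profiles, 1L, function(p) {
    d <- diff(p)
    if (direction == "increasing") all(d >= 0) && any(d > 0) else all(d <= 0) && any(d < 0)
  })
}

#' Members of significant monotone profiles
#'
#' Selects the features assigned to significant profiles whose vectors are
#' monotone in the requested direction ("activated enhancers" on constituent
#' input with `direction = "increasing"`; up-/down-regulated genes on
#' expression input).
#'
#' @param tps A [cluster_trends()] result.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return Character vector of selected feature ids.
#' @export
select_trend_members <- function(tps, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  mono <- monotone_profiles(tps$profiles, direction)
  sig <- tps$significance$significant
  keep_profiles <- which(mono & sig)
  names(tps$assignments)[tps$assignments %in% keep_profiles]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
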