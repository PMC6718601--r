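test_that("distal filter drops peaks within 5 kb of a TSS, strictly", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000, strand = "+")
  peaks <- data.frame(chrom = "chr1",
                      start = c(106001, 99000, 105000),
                      end = c(107000, 101000, 106000))
  kept <- distal_filter(peaks, tss, min_dist = 5000)
  expect_equal(kept$start, 106001)          # gap 6001 > 5000
  expect_equal(kept$tss_gap, 6001)
  # TSS inside the peak: gap 0; gap exactly 5000 is not > 5000
  expect_false(99000 %in% kept$start)
  expect_false(105000 %in% kept$start)
  expect_error(distal_filter(peaks, tss[0, ], 5000), "empty")
  # peaks on a chromosome without TSS annotation are kept (infinite gap)
  far <- data.frame(chrom = "chr9", start = 0, end = 100)
  expect_equal(nrow(distal_filter(far, tss)), 1L)
})

test_that("stitching joins peaks within the stitch distance only", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 11000), end = c(1000, 12000))
  expect_equal(nrow(stitch(peaks, 12500)), 1L)   # gap 10000 <= 12500
  peaks2 <- data.frame(chrom = "chr1", start = c(0, 14000), end = c(1000, 15000))
  st2 <- stitch(peaks2, 12500)                   # gap 13000 > 12500
  expect_equal(nrow(st2), 2L)
  st1 <- stitch(peaks[1, , drop = FALSE])
  expect_equal(st1$n_constituents, 1L)
  expect_equal(c(st1$start, st1$end), c(0, 1000))
  overl <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500))
  expect_error(stitch(overl), "non-overlapping")
})

test_that("stitched spans cover first start to last end and gaps respect the limit", {
  set.seed(51)
  for (rep in 1:20) {
    p <- merge_union(rand_intervals(30L, chroms = "chr1", max_coord = 5000L))
    d <- sample(c(50, 150, 400), 1L)
    st <- stitch(p, d)
    for (i in seq_len(nrow(st))) {
      cons <- st$constituents[[i]]
      expect_equal(st$start[i], min(cons$start))
      expect_equal(st$end[i], max(cons$end))
      if (nrow(cons) > 1L)
        expect_true(all(cons$start[-1L] - cons$end[-nrow(cons)] <= d))
    }
    # larger stitch distance never yields more regions
    expect_lte(nrow(stitch(p, d + 200)), nrow(st))
  }
})

test_that("enhancer signal is background-corrected mass over constituents, floored at 0", {
  st <- stitch(data.frame(chrom = "chr1", start = 0, end = 1000))
  chip <- coverage_track("chr1", 0, 1000, 2)
  expect_equal(enhancer_signal(st, chip, chip)$signal, 0)
  expect_equal(enhancer_signal(st, chip, NULL)$signal, 2000)
  strong_ctrl <- coverage_track("chr1", 0, 1000, 5)
  expect_equal(enhancer_signal(st, chip, strong_ctrl)$signal, 0)  # floored

  set.seed(52)
  for (rep in 1:10) {
    p <- merge_union(rand_intervals(12L))
    st <- stitch(p, 100)
    chip <- rand_track(); ctrl <- rand_track()
    got <- enhancer_signal(st, chip, ctrl)$signal
    want <- vapply(seq_len(nrow(st)), function(i) {
      cons <- st$constituents[[i]]
      tot <- 0
      for (j in seq_len(nrow(cons))) {
        idx <- (cons$start[j] + 1L):cons$end[j]
        tot <- tot + sum(oracle_expand(chip, cons$chrom[j], 2000)[idx]) -
          sum(oracle_expand(ctrl, cons$chrom[j], 2000)[idx])
      }
      max(0, tot)
    }, numeric(1L))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("tangent cutoff separates a detached high-signal population exactly", {
  r <- rose_cutoff(c(rep(1, 200), rep(100, 10)))
  expect_equal(r$n_super, 10L)
  expect_equal(which(r$is_super), 201:210)
  expect_equal(rose_cutoff(rep(7, 50))$n_super, 0L)       # flat curve
  expect_equal(rose_cutoff(as.numeric(1:100))$n_super, 0L) # linear in rank
  expect_error(rose_cutoff(c(1, 2)), "at least 3")
  expect_error(rose_cutoff(c(0, 0, 0)), "positive total")
})

test_that("the cutoff is scale-invariant and the SE block is a ranking prefix", {
  set.seed(53)
  for (rep in 1:20) {
    s <- c(rexp(150), runif(8, 50, 150))
    r1 <- rose_cutoff(s)
    r2 <- rose_cutoff(s * runif(1, 0.01, 100))
    expect_identical(r1$is_super, r2$is_super)
    st <- data.frame(chrom = "chr1", start = seq_along(s) * 10,
                     end = seq_along(s) * 10 + 5,
                     name = paste0("r", seq_along(s)),
                     n_constituents = 1L)
    st$constituents <- I(lapply(seq_along(s), function(i) st[i, 1:3]))
    st$signal <- s
    calls <- call_super_enhancers(st)
    expect_equal(calls$cutoff_rank, sum(calls$enhancers$is_super))
    if (calls$cutoff_rank > 0)
      expect_true(all(calls$enhancers$is_super[seq_len(calls$cutoff_rank)]))
    expect_false(any(calls$enhancers$is_super[-seq_len(max(calls$cutoff_rank, 1))]))
  }
})

test_that("two-component signals separated >= 10x are recovered with high precision", {
  hits <- 0L
  for (sd in 1:100) {
    set.seed(sd + 500)
    s <- c(rexp(200), rep(runif(1, 50, 150), 10))
    r <- rose_cutoff(s)
    if (r$n_super == 10L && all(which(r$is_super) == 201:210)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("group SE profiles partition into shared and specific sets", {
  mk <- function(spans, super = TRUE) {
    st <- cbind(spans, name = paste0("r", seq_len(nrow(spans))),
                n_constituents = 1L,
                signal = if (super) c(rep(1, nrow(spans) - 1), 100) else 1)
    st$constituents <- I(lapply(seq_len(nrow(st)), function(i) spans[i, ]))
    call_super_enhancers(st)
  }
  spans <- data.frame(chrom = "chr1",
                      start = c(0, 5000, 10000), end = c(1000, 6000, 11000))
  same <- list(s1 = mk(spans), s2 = mk(spans))
  res <- se_group_profiles(same, c(s1 = "young", s2 = "aged"))
  expect_equal(unname(res$venn["young_specific"]), 0L)
  expect_equal(unname(res$venn["aged_specific"]), 0L)
  expect_equal(unname(res$venn["young_shared"]), 1L)

  other <- data.frame(chrom = "chr2", start = spans$start, end = spans$end)
  disj <- list(s1 = mk(spans), s2 = mk(other))
  res2 <- se_group_profiles(disj, c(s1 = "young", s2 = "aged"))
  expect_equal(unname(res2$venn["young_shared"]), 0L)
  expect_equal(unname(res2$venn["young_specific"]), 1L)
  expect_equal(unname(res2$venn["aged_specific"]), 1L)
})

test_that("SE correlation is Spearman with midranks and flags zero variance", {
  set.seed(54)
  m <- matrix(rlnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, "b"] <- m[, "a"]                       # duplicated sample
  r <- se_correlation(m)
  expect_equal(r["a", "b"], 1)
  m2 <- cbind(m[, "a", drop = FALSE], rev = rev(sort(m[, "a"]))[rank(m[, "a"])])
  expect_equal(se_correlation(m2)["a", "rev"], -1)
  for (rep in 1:20) {
    mm <- matrix(sample(1:5, 30, TRUE) + runif(30, 0, .01), 10, 3,
                 dimnames = list(NULL, c("x", "y", "z")))
    expect_equal(se_correlation(mm), oracle_spearman(mm), tolerance = 1e-9)
  }
  mz <- cbind(m[, 1:2], z = rep(1, 20))
  expect_warning(rz <- se_correlation(mz), "zero-variance")
  expect_true(is.na(rz["a", "z"]))
  expect_error(se_correlation(m[1:2, ]), "at least 3")
})
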