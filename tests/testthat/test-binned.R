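test_that("make_bins tiles chromosomes with a truncated final bin", {
  b <- make_bins(chrom_sizes(c(chrA = 2.5e6)), width = 1e6)
  expect_equal(b$start, c(0, 1e6, 2e6))
  expect_equal(b$end, c(1e6, 2e6, 2.5e6))
  b <- make_bins(chrom_sizes(c(chrA = 800)), width = 1000)
  expect_equal(nrow(b), 1L)
  expect_equal(b$end, 800)
  expect_error(make_bins(chrom_sizes(c(chrA = 100)), width = 0), "positive")
})

test_that("bin lengths conserve total chromosome length for random genomes", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:4, 1L)
    sizes <- chrom_sizes(stats::setNames(sample(1e4:2e6, n), paste0("c", 1:n)))
    w <- sample(c(1e3, 1e4, 1e5, 3e5), 1L)
    b <- make_bins(sizes, w)
    expect_equal(sum(b$end - b$start), sum(sizes))
    expect_true(all(b$end - b$start <= w))
  }
})

test_that("input normalization is 1 for identical or proportional tracks", {
  sizes <- chrom_sizes(c(chr1 = 2000))
  chip <- coverage_track("chr1", c(0, 1000), c(1000, 2000), c(2, 4),
                         chrom_sizes = sizes)
  norm <- input_normalize(chip, chip, sizes)
  expect_true(all(norm$value == 1))
  # doubling the control changes nothing: CPM removes global scale
  ctrl <- coverage_track("chr1", c(0, 1000), c(1000, 2000), c(1, 2),
                         chrom_sizes = sizes)
  norm2 <- input_normalize(chip, ctrl, sizes)
  expect_true(all(abs(norm2$value - 1) < 1e-12))
  empty <- coverage_track(character(), numeric(), numeric(), numeric(),
                          chrom_sizes = sizes)
  expect_error(input_normalize(chip, empty, sizes), "zero total mass")
})

test_that("input normalization matches the per-base oracle on random tracks", {
  set.seed(32)
  sizes <- chrom_sizes(c(chr1 = 2000, chr2 = 2000))
  for (rep in 1:15) {
    chip <- rand_track(); ctrl <- rand_track()
    if (total_mass(chip) == 0 || total_mass(ctrl) == 0) next
    norm <- input_normalize(chip, ctrl, sizes, pseudocount = 1)
    for (ch in c("chr1", "chr2")) {
      a <- oracle_expand(chip, ch, 2000) * 1e6 / (total_mass(chip) / 100)
      b <- oracle_expand(ctrl, ch, 2000) * 1e6 / (total_mass(ctrl) / 100)
      want <- (a + 1) / (b + 1)
      got <- oracle_expand(norm, ch, 2000)
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("bin_counts is the length-weighted mean and matches the base-wise oracle", {
  bins <- make_bins(chrom_sizes(c(chr1 = 2000)), width = 1000)
  full <- coverage_track("chr1", 0, 2000, 3)
  expect_equal(bin_counts(full, bins), c(3, 3))
  half <- coverage_track("chr1", 0, 500, 2)
  expect_equal(bin_counts(half, bins), c(1, 0))

  set.seed(33)
  bins2 <- make_bins(chrom_sizes(c(chr1 = 2000, chr2 = 2000)), width = 250)
  for (rep in 1:15) {
    tr <- rand_track()
    expect_lt(max(abs(bin_counts(tr, bins2) - oracle_region_mean(tr, bins2))),
              1e-9)
  }
})

test_that("bin z-scores follow the young-cohort formula with n-1 sd", {
  m <- matrix(c(8, 10, 12, 10), nrow = 1,
              dimnames = list("b1", c("y1", "y2", "y3", "t")))
  expect_equal(as.numeric(bin_zscores(m, c("y1", "y2", "y3"), "t")), 0)
  m[1, "t"] <- 14
  z <- bin_zscores(m, c("y1", "y2", "y3"), "t")
  expect_equal(as.numeric(z), 2)  # sd = 2 with the n-1 estimator
  expect_equal(as.character(classify_bins(z)), "unchanged")  # strict > 2
  m2 <- matrix(c(10, 10, 10, 99), nrow = 1,
               dimnames = list("b1", c("y1", "y2", "y3", "t")))
  expect_true(is.na(bin_zscores(m2, c("y1", "y2", "y3"), "t")))
  expect_error(bin_zscores(m, "y1", "t"), "at least 2")
})

test_that("young samples are scored against a leave-one-out reference", {
  m <- matrix(c(1, 2, 3, 4), nrow = 1,
              dimnames = list("b1", c("y1", "y2", "y3", "y4")))
  z <- bin_zscores(m, colnames(m), "y4")
  expect_equal(attr(z, "reference"), c("y1", "y2", "y3"))
  expect_equal(as.numeric(z), (4 - 2) / 1)
  expect_error(bin_zscores(m, c("y1", "y2"), "y1"), "after leave-one-out")
})

test_that("z-scores match the looped oracle and are affine-invariant", {
  set.seed(34)
  for (rep in 1:30) {
    ns <- sample(4:8, 1L)
    m <- matrix(rlnorm(40 * ns), 40, ns,
                dimnames = list(NULL, paste0("s", 1:ns)))
    young <- paste0("s", 1:3)
    test <- paste0("s", ns)
    expect_equal(as.numeric(bin_zscores(m, young, test)),
                 oracle_zscores(m, young, test), tolerance = 1e-12)
    a <- runif(1, 0.1, 5); b <- runif(1, -2, 2)
    expect_equal(as.numeric(bin_zscores(a * m + b, young, test)),
                 as.numeric(bin_zscores(m, young, test)), tolerance = 1e-9)
  }
})

test_that("bin calls use strict thresholds and partition all bins", {
  z <- c(2.5, -3, 2, -2, 0, NA)
  calls <- classify_bins(z)
  expect_equal(as.character(calls),
               c("increased", "decreased", "unchanged", "unchanged",
                 "unchanged", "undefined"))
  s <- call_summary(calls)
  expect_equal(s$n_increased + s$n_decreased + s$n_undefined +
                 (s$n_defined - s$n_increased - s$n_decreased), length(z))
  expect_equal(s$frac_increased, 1 / 5)  # fractions over defined bins
  expect_error(classify_bins(z, z_lo = 2, z_hi = 2), "z_lo")
})

test_that("group fraction comparison uses the exact rank-sum distribution", {
  fr <- c(a1 = 0.3, a2 = 0.31, y1 = 0.01, y2 = 0.02)
  grp <- c(a1 = "aged", a2 = "aged", y1 = "young", y2 = "young")
  two <- compare_group_fractions(fr, grp)
  expect_equal(two$p.value, 2 / choose(4, 2))  # minimal attainable, n=(2,2)
  one <- compare_group_fractions(fr, grp, "greater")
  expect_equal(one$p.value, 1 / choose(4, 2))
  # swapping labels flips the direction of the effect
  swapped <- compare_group_fractions(fr, stats::setNames(
    c("young", "young", "aged", "aged"), names(grp)), "greater")
  expect_equal(swapped$p.value, 1)
  same <- compare_group_fractions(c(a1 = .1, a2 = .1, y1 = .1, y2 = .1), grp)
  expect_gt(same$p.value, 0.99)
  expect_error(compare_group_fractions(fr[-1], grp[-1]), "at least 2")
})
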