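test_that("group means average samples within ordered groups", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  gm <- group_means(m, c(s1 = "g1", s2 = "g2", s3 = "g3", s4 = "g4"),
                    paste0("g", 1:4))
  expect_equal(unname(gm), matrix(1:8, 2, 4))  # one sample per group
  gm2 <- group_means(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"), c("a", "b"))
  expect_equal(gm2[, "a"], c(f1 = 2, f2 = 3))
  expect_error(group_means(m, c(s1 = "a", s2 = "a", s3 = "a", s4 = "a"),
                           c("a", "b")), "empty group")
  set.seed(61)
  mm <- matrix(rlnorm(50), 5, 10, dimnames = list(NULL, paste0("s", 1:10)))
  map <- stats::setNames(sample(c("x", "y", "z"), 10, TRUE), colnames(mm))
  while (length(unique(map)) < 3)
    map <- stats::setNames(sample(c("x", "y", "z"), 10, TRUE), colnames(mm))
  gm3 <- group_means(mm, map, c("x", "y", "z"))
  for (g in c("x", "y", "z"))
    expect_equal(gm3[, g], rowMeans(mm[, names(map)[map == g], drop = FALSE]))
})

test_that("rpkm implements the definition and its scale invariances", {
  expect_equal(rpkm(1000, 10, 1e6), 10)
  expect_equal(rpkm(2000, 10, 2e6), 2.5)
  expect_equal(rpkm(1500, 22, 3.3e6), rpkm(1500, 44, 6.6e6))
  expect_error(rpkm(0, 1, 1e6), "length")
  expect_error(rpkm(100, 1, 0), "library")
})

test_that("fold-change filter keeps >= min_fold in either direction", {
  m <- matrix(c(1, 2, 1, 2, 1, 1.9), 3, 2, byrow = TRUE,
              dimnames = list(c("up", "dn", "weak"), c("first", "last")))
  m[2, ] <- c(2, 1)
  out <- fold_change_filter(m, "first", "last", min_fold = 2, pseudocount = 0)
  expect_equal(rownames(out), c("up", "dn"))
  expect_equal(attr(out, "retained"),
               stats::setNames(c(TRUE, TRUE, FALSE), rownames(m)))
})

test_that("model profile enumeration and greedy max-min selection are deterministic", {
  p27 <- generate_model_profiles(T = 4, c = 1, m = 27)
  expect_equal(nrow(p27), 27L)   # 3^(4-1) candidates, all selected
  expect_error(generate_model_profiles(T = 4, c = 1, m = 28), "exceeds")
  p5 <- generate_model_profiles(T = 2, c = 2, m = 5)
  expect_equal(unname(sort(p5[, 2])), -2:2)
  expect_true(all(p5[, 1] == 0))
  # flat always present as profile 1; first pick is farthest from flat
  p <- generate_model_profiles(T = 4, c = 2, m = 10)
  expect_equal(unname(p[1, ]), c(0, 0, 0, 0))
  expect_equal(sqrt(sum(p[2, ]^2)), sqrt(sum(c(0, 2, 4, 6)^2)))
  expect_identical(p, generate_model_profiles(T = 4, c = 2, m = 10))
})

test_that("greedy selection beats random subsets on minimum pairwise distance", {
  p <- generate_model_profiles(T = 4, c = 2, m = 12)
  min_pair <- function(mat) {
    d <- as.matrix(stats::dist(mat))
    min(d[upper.tri(d)])
  }
  got <- min_pair(unclass(p))
  cand <- chromage:::.enumerate_profiles(4L, 2L)
  set.seed(62)
  rand_best <- max(replicate(1000, min_pair(cand[sample(nrow(cand), 12L), ])))
  expect_gte(got, rand_best)
})

test_that("profile assignment maximizes Pearson correlation with lower-id ties", {
  profiles <- structure(rbind(c(0, 0, 0), c(0, 1, 2), c(0, -1, -2)),
                        class = c("trend_profiles", "matrix"))
  rows <- rbind(r1 = c(5, 7, 9),      # affine image of profile 2
                r2 = c(3, 2.5, 0.1),  # decreasing
                r3 = c(1, 2, 300))    # increasing, nonlinear
  expect_equal(unname(assign_to_profiles(rows, profiles)), c(2L, 3L, 2L))
  expect_error(assign_to_profiles(rbind(c(1, 1, 1)), profiles), "constant")

  set.seed(63)
  profs <- generate_model_profiles(T = 5, c = 2, m = 20)
  rows2 <- matrix(rnorm(200 * 5), 200, 5,
                  dimnames = list(paste0("f", 1:200), NULL))
  got <- assign_to_profiles(rows2, profs)
  zp <- chromage:::.zrows(unclass(profs))
  for (i in sample(200, 25)) {
    cors <- apply(unclass(profs), 1L, function(pr)
      if (max(pr) == min(pr)) -Inf else stats::cor(rows2[i, ], pr))
    expect_equal(unname(got[i]), unname(which.max(cors)))
  }
})

test_that("assignment is invariant under positive affine transforms", {
  set.seed(64)
  profs <- generate_model_profiles(T = 4, c = 2, m = 15)
  rows <- matrix(rlnorm(100 * 4), 100, 4,
                 dimnames = list(paste0("f", 1:100), NULL))
  a <- assign_to_profiles(rows, profs)
  b <- assign_to_profiles(rows * 3.7 + 11, profs)
  expect_identical(a, b)
})

test_that("planted monotone rows drive their profile to permutation significance", {
  m <- fold_change_filter(make_trend_matrix(n = 800L, n_planted = 120L, seed = 65))
  tps <- cluster_trends(m, n_permutations = 300, seed = 65)
  sel <- select_trend_members(tps, "increasing")
  expect_gte(mean(planted_ids(120L) %in% sel), 0.9)
  mono_sig <- tps$significance$significant &
    monotone_profiles(tps$profiles, "increasing")
  expect_true(any(mono_sig))
  # permuting each planted row's group values destroys the structure
  set.seed(66)
  m2 <- m
  for (i in seq_len(sum(rownames(m) %in% planted_ids(120L))))
    m2[i, ] <- m2[i, sample(4)]
  tps2 <- cluster_trends(m2, n_permutations = 300, seed = 65)
  expect_lt(sum(tps2$significance$significant), sum(tps$significance$significant))
  sel2 <- select_trend_members(tps2, "increasing")
  expect_lt(length(sel2), length(sel) / 2)
})

test_that("pure-noise rows rarely produce significant profiles", {
  nsig <- vapply(1:5, function(sd) {
    m <- make_trend_matrix(n = 600L, n_planted = 0L, seed = sd + 700)
    tps <- cluster_trends(m, n_permutations = 200, seed = sd)
    sum(tps$significance$significant)
  }, numeric(1L))
  expect_lte(mean(nsig), 0.05 * 50)  # far below alpha x m on average
})

test_that("permutation p-values are Monte-Carlo stable", {
  m <- make_trend_matrix(n = 400L, n_planted = 60L, seed = 67)
  x <- log2(m + 1)
  profs <- generate_model_profiles(4L, 2L, 30L)
  s1 <- profile_significance(x, profs, n_permutations = 400, seed = 1)
  s2 <- profile_significance(x, profs, n_permutations = 800, seed = 2)
  # expected counts agree within 3 Monte-Carlo standard errors
  se <- sqrt(pmax(s1$expected, 1) / 400 * 3)
  big <- s1$expected > 2
  expect_true(all(abs(s1$expected - s2$expected)[big] <
                    3 * sqrt(s1$expected[big]) ))
  expect_identical(profile_significance(x, profs, n_permutations = 400, seed = 1),
                   s1)
})

test_that("trend member selection equals the brute-force filter", {
  m <- make_trend_matrix(n = 500L, n_planted = 80L, seed = 68)
  tps <- cluster_trends(m, n_permutations = 200, seed = 68)
  for (dir in c("increasing", "decreasing")) {
    sel <- select_trend_members(tps, dir)
    mono <- monotone_profiles(tps$profiles, dir)
    want <- names(tps$assignments)[vapply(tps$assignments, function(pid)
      mono[pid] && tps$significance$significant[pid], logical(1L))]
    expect_setequal(sel, want)
  }
  # members of the flat profile (never assigned) and non-selected profiles excluded
  expect_false(any(tps$assignments == 1L))
})
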