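test_that("nearest gene uses midpoints with lexicographic tie-breaking", {
  tss1 <- data.frame(gene_id = "only", chrom = "chr1", tss = 5000, strand = "+")
  cons <- data.frame(chrom = "chr1", start = c(0, 9000), end = c(100, 9100),
                     name = c("c1", "c2"))
  a <- nearest_gene(cons, tss1)
  expect_equal(a$gene_id, c("only", "only"))

  # midpoint 5000 equidistant from geneA (4000) and geneB (6000)
  tss2 <- data.frame(gene_id = c("geneB", "geneA"), chrom = "chr1",
                     tss = c(6000, 4000), strand = c("+", "+"))
  mid <- data.frame(chrom = "chr1", start = 4975, end = 5026, name = "c")
  expect_equal(nearest_gene(mid, tss2)$gene_id, "geneA")

  # signed distance is strand-aware (positive = downstream of the TSS)
  tssm <- data.frame(gene_id = c("plus", "minus"), chrom = c("chr1", "chr2"),
                     tss = c(100, 100), strand = c("+", "-"))
  down <- data.frame(chrom = c("chr1", "chr2"), start = c(200, 200),
                     end = c(300, 300), name = c("p", "m"))
  d <- nearest_gene(down, tssm)
  expect_equal(d$distance, c(150, -150))
  expect_error(nearest_gene(cons, tss1[0, ]), "empty")
})

test_that("nearest gene matches exhaustive search on random layouts", {
  set.seed(71)
  for (rep in 1:40) {
    n_genes <- sample(2:30, 1L)
    tss <- data.frame(gene_id = sprintf("g%03d", sample(999, n_genes)),
                      chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                      tss = sample.int(5e4, n_genes, replace = TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE))
    cons <- rand_intervals(25L, max_coord = 5e4)
    cons$name <- paste0("c", seq_len(nrow(cons)))
    got <- suppressWarnings(nearest_gene(cons, tss))
    expect_equal(got$gene_id, oracle_nearest(cons, tss))
  }
})

test_that("overlap enrichment is the exact hypergeometric upper tail", {
  u <- paste0("g", 1:10)
  r <- overlap_enrichment(u, u, u)
  expect_equal(r$n_overlap, 10L)
  expect_equal(r$p, 1)
  r2 <- overlap_enrichment(u[1:4], u[5:10], u)
  expect_equal(r2$n_overlap, 0L)
  expect_equal(r2$p, 1)      # P(X >= 0) = 1
  expect_error(overlap_enrichment(c(u, "zz"), u, u), "not contained")
})

test_that("hypergeometric p equals enumeration over all draws (universe <= 12)", {
  set.seed(72)
  for (rep in 1:100) {
    N <- sample(5:12, 1L)
    na <- sample(1:(N - 1L), 1L)
    nb <- sample(1:(N - 1L), 1L)
    u <- paste0("g", seq_len(N))
    a <- sample(u, na); b <- sample(u, nb)
    got <- overlap_enrichment(a, b, u)
    expect_equal(got$p, oracle_hyper(N, na, nb, got$n_overlap),
                 tolerance = 1e-12)
  }
})

test_that("two-group DE calls follow the Welch test on log2 values", {
  ids <- paste0("s", 1:6)
  a <- ids[1:3]; b <- ids[4:6]
  same <- matrix(rep(c(4, 9, 1), 6), 3, 6, dimnames = list(paste0("g", 1:3), ids))
  de <- two_group_de(same, a, b)
  expect_true(all(de$call == "unchanged"))
  expect_true(all(de$p == 1))

  quad <- matrix(c(rep(3, 3), rep(15, 3)), 1, 6, byrow = TRUE,
                 dimnames = list("g1", ids))
  de2 <- two_group_de(quad, a, b)
  expect_equal(de2$lfc, 2)   # log2((15+1)/(3+1))
  expect_equal(de2$p, 0)     # zero within-group variance, means differ
  expect_equal(as.character(de2$call), "up")

  set.seed(73)
  m <- matrix(rlnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), ids))
  d1 <- two_group_de(m, a, b)
  d2 <- two_group_de(m, b, a)
  expect_equal(d1$lfc, -d2$lfc)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  # agrees with stats::t.test where it is defined
  for (g in 1:5) {
    tt <- stats::t.test(log2(m[g, b] + 1), log2(m[g, a] + 1))
    expect_equal(d1$p[g], tt$p.value, tolerance = 1e-10)
  }
  expect_error(two_group_de(m, a[1], b), "at least 2")
})

test_that("gene-set summaries report consistent fractions", {
  ids <- paste0("s", 1:6)
  set.seed(74)
  m <- matrix(rlnorm(40 * 6), 40, 6, dimnames = list(paste0("g", 1:40), ids))
  m[1:8, 4:6] <- m[1:8, 4:6] * 16    # planted up genes
  de <- two_group_de(m, ids[1:3], ids[4:6])
  fr <- geneset_fraction_summary(de, paste0("g", 1:40))
  expect_equal(sum(fr), 1)
  fr_up <- geneset_fraction_summary(de, paste0("g", 1:8))
  expect_gte(fr_up["up"], 0.5)
  still <- geneset_fraction_summary(de, paste0("g", 30:40))
  expect_equal(unname(still["unchanged"]), 1)
  expect_error(geneset_fraction_summary(de, character(0)), "empty")
  expect_error(geneset_fraction_summary(de, "nope"), "absent")
})

test_that("active-enhancer fractions count nearest-gene targets per condition", {
  set_ <- paste0("g", 1:10)
  targets <- list(young = character(0), aged = paste0("g", 1:7))
  fr <- geneset_active_enhancer_fraction(set_, targets)
  expect_equal(unname(fr["young"]), 0)
  expect_equal(unname(fr["aged"]), 0.7)
  all_t <- list(cond = set_)
  expect_equal(unname(geneset_active_enhancer_fraction(set_, all_t)), 1)
  expect_error(geneset_active_enhancer_fraction(character(0), targets), "empty")
})
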