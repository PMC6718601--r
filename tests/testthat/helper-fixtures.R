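# Programmatic fixtures shared across test files.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_coord = 2000L,
                           max_len = 60L) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len)
}

# Random sparse coverage track on small chromosomes (gaps carry 0).
rand_track <- function(n_runs = 30L, chroms = c("chr1", "chr2"),
                       max_coord = 2000L, read_length = 100) {
  runs <- do.call(rbind, lapply(chroms, function(ch) {
    bp <- sort(sample.int(max_coord, 2L * n_runs))
    s <- bp[seq(1L, length(bp), by = 2L)] - 1L
    e <- bp[seq(2L, length(bp), by = 2L)]
    keep <- e > s
    data.frame(chrom = ch, start = s[keep], end = e[keep],
               value = round(stats::runif(sum(keep), 0, 5), 3))
  }))
  coverage_track(runs$chrom, runs$start, runs$end, runs$value,
                 read_length = read_length)
}

# Ordered-group matrix with planted monotone-increasing rows: baseline
# lognormal, planted rows rise geometrically to `fold` end-to-end,
# multiplicative lognormal noise.
make_trend_matrix <- function(n = 2000L, n_planted = 200L, T = 4L, fold = 4,
                              noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  base <- stats::rlnorm(n, 3, 1)
  eff <- matrix(1, n, T)
  if (n_planted > 0L) {
    step <- fold^(1 / (T - 1L))
    eff[seq_len(n_planted), ] <- matrix(step^(0:(T - 1L)), n_planted, T,
                                        byrow = TRUE)
  }
  m <- base * eff * exp(matrix(stats::rnorm(n * T, 0, noise_sd), n, T))
  dimnames(m) <- list(sprintf("f%04d", seq_len(n)), paste0("g", seq_len(T)))
  m
}

planted_ids <- function(n_planted) sprintf("f%04d", seq_len(n_planted))

# Small, fast cohort for unit tests (full desk scale is reserved for the
# acceptance suite).
tiny_cohort_config <- function(seed = 1L, ...) {
  cohort_config(n_chroms = 1L, chrom_length = 2e6, bin_width = 1e5,
                n_genes = 100L, n_enhancer_loci = 40L, seed = seed, ...)
}

chip_ids_of <- function(cohort) {
  sheet <- cohort$sample_sheet
  sheet$sample_id[sheet$assay != "expression"]
}
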