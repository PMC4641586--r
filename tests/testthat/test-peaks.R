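test_that("window counting assigns each read by its 5' base", {
  a <- data.frame(chrom = "chrS", start = c(10L, 60L, 62L), end = c(60L, 110L, 112L),
                  strand = "+", sample_id = "s", read_id = c("r1", "r2", "r3"),
                  stringsAsFactors = FALSE)
  wc <- window_counts(a, chrom_length = 200, window_size = 50)
  expect_equal(wc$counts, c(1L, 2L, 0L, 0L))
  expect_equal(sum(wc$counts), nrow(a))

  # a minus-strand read counts at end - 1
  m <- data.frame(chrom = "chrS", start = 10L, end = 60L, strand = "-",
                  sample_id = "s", read_id = "r1", stringsAsFactors = FALSE)
  expect_equal(window_counts(m, 200, 50)$counts, c(0L, 1L, 0L, 0L))

  none <- a[0, ]
  expect_equal(window_counts(none, 470, 50, chrom = "chrS")$counts,
               integer(10))
})

test_that("the Poisson minimum-read threshold satisfies its definition", {
  k <- poisson_min_reads(1.0, 20000, 0.05)
  expect_equal(k, 9L)
  # direct survival-function oracle: smallest k with P(X >= k) <= alpha/n
  cut <- 0.05 / 20000
  expect_lte(ppois(k - 1, 1.0, lower.tail = FALSE), cut)
  expect_gt(ppois(k - 2, 1.0, lower.tail = FALSE), cut)

  expect_equal(poisson_min_reads(1e-9, 1, 0.05), 1L)
  ks <- vapply(c(0.5, 1, 2, 5), poisson_min_reads, integer(1),
               n_windows = 10000)
  expect_true(all(diff(ks) >= 0))
})

test_that("peak calling thresholds, merges and reports correctly", {
  wc <- promloop:::as_window_counts(c(1L, 0L, 30L, 1L, rep(1L, 16)))
  pk <- call_peaks(wc, alpha = 0.05)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 150L)
  expect_equal(pk$read_count, 30L)
  expect_true(pk$p_value > 0 && pk$p_value <= 1)

  # adjacent significant windows merge into one peak
  wc2 <- promloop:::as_window_counts(c(rep(1L, 8), 30L, 31L, rep(1L, 10)))
  pk2 <- call_peaks(wc2, alpha = 0.05)
  expect_equal(nrow(pk2), 1L)
  expect_equal(c(pk2$start, pk2$end), c(400L, 500L))
  expect_equal(pk2$read_count, 61L)

  expect_equal(nrow(call_peaks(promloop:::as_window_counts(rep(0L, 50)))), 0L)

  bad <- promloop:::as_window_counts(rep(1L, 10), window_size = 25)
  expect_error(call_peaks(promloop:::as_window_counts(rep(1L, 10)), bad),
               "grids do not match")
})

test_that("peak calls equal a brute-force threshold-and-merge oracle", {
  set.seed(23)
  for (i in 1:20) {
    counts <- rpois(400, 2)
    counts[sample(400, 3)] <- counts[sample(400, 3)] + sample(10:30, 3)
    wc <- promloop:::as_window_counts(counts)
    got <- call_peaks(wc, alpha = 0.05)
    lambda <- max(mean(counts), 1e-9)
    k <- poisson_min_reads(lambda, 400, 0.05)
    sig <- which(counts >= k)
    if (length(sig) == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      grp <- cumsum(c(1, diff(sig) > 1))
      want_start <- (sig[!duplicated(grp)] - 1L) * 50L
      want_end <- sig[rev(!duplicated(rev(grp)))] * 50L
      expect_equal(got$start, want_start)
      expect_equal(got$end, want_end)
      expect_equal(got$read_count,
                   as.integer(tapply(counts[sig], grp, sum)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("input-corrected calling scales the background to library size", {
  set.seed(24)
  # input has a coverage bump that must suppress a matching treatment bump
  base <- rpois(500, 2)
  input <- base + c(rep(0L, 200), rep(8L, 20), rep(0L, 280))
  treatment <- rpois(500, 2) + c(rep(0L, 200), rep(8L, 20), rep(0L, 280))
  ti <- promloop:::as_window_counts(treatment)
  ii <- promloop:::as_window_counts(input)
  pk <- call_peaks(ti, ii, alpha = 0.05)
  expect_equal(nrow(pk), 0L)
  # but a treatment-only bump on the same background is found
  treatment2 <- treatment
  treatment2[401:410] <- treatment2[401:410] + 30L
  pk2 <- call_peaks(promloop:::as_window_counts(treatment2), ii)
  expect_true(any(pk2$start <= 20000 & pk2$end >= 20050))
})

test_that("differential enrichment reproduces the worked example", {
  reg <- genomic_intervals("chrS", 0, 100)
  d <- differential_regions(reg, matrix(c(100, 120), 1), matrix(c(25, 30), 1),
                            list(a = c(1e6, 1e6), b = c(1e6, 1e6)),
                            dispersion = 0)
  expect_equal(d$log2_fold_change, 2)       # log2(110 / 27.5), no pseudocount
  expect_equal(d$class, "enriched")
  expect_equal(d$p_value, bf_cond_binom_p(220, 55, 2, 2))
})

test_that("the NB exact test matches edgeR at a fixed dispersion", {
  library(edgeR)
  set.seed(25)
  for (phi in c(0.01, 0.05, 0.2)) {
    ya <- rnbinom(1, size = 1 / phi, mu = 400)
    yb <- rnbinom(1, size = 1 / phi, mu = 150)
    y <- matrix(c(ya, yb), nrow = 1)
    d <- DGEList(counts = y, group = c("a", "b"), lib.size = rep(1e6, 2))
    p_edger <- exactTest(d, dispersion = phi,
                         pair = c("b", "a"))$table$PValue
    expect_equal(promloop:::nb_exact_test(ya, yb, 1, 1, phi), p_edger,
                 tolerance = 1e-8)
  }
})

test_that("differential classification is antisymmetric under group swap", {
  set.seed(26)
  for (i in 1:25) {
    reg <- genomic_intervals("chrS", 0, 100)
    ca <- matrix(rnbinom(2, size = 20, mu = sample(c(30, 200), 1)), 1)
    cb <- matrix(rnbinom(2, size = 20, mu = sample(c(30, 200), 1)), 1)
    ls <- list(a = c(1e6, 1e6), b = c(1e6, 1e6))
    d1 <- differential_regions(reg, ca, cb, ls, dispersion = 0.05)
    d2 <- differential_regions(reg, cb, ca, ls, dispersion = 0.05)
    expect_equal(d1$log2_fold_change, -d2$log2_fold_change, tolerance = 1e-9)
    expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
    flip <- c(enriched = "depleted", depleted = "enriched",
              unchanged = "unchanged")
    expect_equal(unname(flip[d1$class]), d2$class)
  }
})

test_that("degenerate regions are unchanged with p = 1", {
  reg <- genomic_intervals("chrS", c(0, 200), c(100, 300))
  d <- differential_regions(reg, matrix(c(0, 50, 0, 60), 2),
                            matrix(c(0, 50, 0, 55), 2),
                            list(a = c(1e6, 1e6), b = c(1e6, 1e6)))
  expect_equal(d$class[1], "unchanged")
  expect_equal(d$p_value[1], 1)
  expect_equal(d$log2_fold_change[1], 0)
})
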