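test_that("generators are pure functions of parameters and seed", {
  a <- make_toy_gene_model(2e5, 7, seed = 5, gene_offset = 0.1)
  b <- make_toy_gene_model(2e5, 7, seed = 5, gene_offset = 0.1)
  expect_identical(a, b)
  c2 <- make_toy_gene_model(2e5, 7, seed = 6, gene_offset = 0.1)
  expect_false(identical(a$sequence, c2$sequence))

  prom <- a$model$promoter
  distal <- genomic_intervals("chrS", c(1e5, 1.5e5), c(1e5 + 1500, 1.5e5 + 1500))
  p1 <- simulate_pets(prom, distal, 3, 5, genome_length = 2e5, seed = 9)
  p2 <- simulate_pets(prom, distal, 3, 5, genome_length = 2e5, seed = 9)
  expect_identical(p1, p2)

  # the global RNG stream is untouched by seeded generators
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(make_toy_gene_model(2e5, 3, seed = 1,
                                               gene_offset = 0.1))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("toy gene model has the documented architecture", {
  gm <- make_toy_gene_model(3e5, 7, seed = 2, gene_offset = 0.1)
  m <- gm$model
  expect_equal(nrow(m$start_exons), 7L)
  expect_equal(anyDuplicated(m$start_exons$name), 0L)
  expect_equal(m$cancer_exon, "5u")
  widths <- m$start_exons$end - m$start_exons$start
  expect_true(all(widths >= 80 & widths <= 300))
  # promoter spans -179/+25 around the cancer exon TSS: 204 bp
  expect_equal(m$promoter$end - m$promoter$start, 204L)
  ctss <- m$start_exons$tss[m$start_exons$name == "5u"]
  expect_equal(m$promoter$start, ctss - 179L)
  expect_equal(m$promoter$end, ctss + 25L)
  expect_equal(nchar(gm$sequence), 3e5)
  expect_error(make_toy_gene_model(1e4, 7, seed = 2), "genome too short")
})

test_that("variant read simulation honours means, dispersion and errors", {
  gm <- make_toy_gene_model(2e5, 3, seed = 3, gene_offset = 0.1)
  meta <- data.frame(sample_id = "s1", condition = "c",
                     stringsAsFactors = FALSE)
  zero <- simulate_variant_reads(gm$model, meta,
                                 list(c = c("1u" = 0, "2u" = 0, "3u" = 0)),
                                 background_mean = 0, genome_length = 2e5,
                                 seed = 4)
  expect_equal(nrow(zero$alignments), 0L)

  # dispersion 0 degenerates to Poisson(mean): count near 1000
  ab <- list(c = c("1u" = 1000, "2u" = 0, "3u" = 0))
  sim <- simulate_variant_reads(gm$model, meta, ab, dispersion = 0,
                                background_mean = 0, genome_length = 2e5,
                                seed = 5)
  n <- nrow(sim$alignments)
  expect_true(n >= 900 && n <= 1100)
  ex1 <- gm$model$start_exons[1, ]
  expect_true(all(sim$alignments$start >= ex1$start &
                    sim$alignments$end <= ex1$end))
  expect_equal(sim$meta$total_mapped_reads, n)

  expect_error(
    simulate_variant_reads(gm$model, meta, ab, read_length = 500,
                           background_mean = 0, genome_length = 2e5, seed = 1),
    "read_length")
})

test_that("ChIP simulation plants enrichment on a Poisson background", {
  peaks <- data.frame(start = 5000, end = 5500, enrichment = 8)
  sim <- simulate_chip_experiment(5e4, background_rate = 2, peaks, seed = 6)
  tw <- window_counts(sim$treatment, 5e4, 50)
  inside <- tw$counts[101:110]
  outside <- tw$counts[-(101:110)]
  expect_gt(mean(inside), 8)         # expected 16
  expect_lt(abs(mean(outside) - 2), 0.3)
  iw <- window_counts(sim$input, 5e4, 50)
  expect_lt(abs(mean(iw$counts) - 2), 0.3)
  expect_error(
    simulate_chip_experiment(1e4, 2, data.frame(start = 9000, end = 11000,
                                                enrichment = 8), seed = 1),
    "outside")
  expect_error(
    simulate_chip_experiment(1e4, 2, data.frame(start = 0, end = 100,
                                                enrichment = 1), seed = 1),
    "enrichment")
})

test_that("PET simulation anchors true pairs on the promoter", {
  prom <- genomic_intervals("chrS", 10000, 10204)
  distal <- genomic_intervals("chrS", c(5e4, 9e4, 1.3e5, 1.7e5, 1.9e5),
                              c(5e4, 9e4, 1.3e5, 1.7e5, 1.9e5) + 1500)
  sim <- simulate_pets(prom, distal, n_true_per_region = 3, n_noise = 0,
                       genome_length = 2e5, seed = 7)
  expect_equal(nrow(sim$pets), 15L)
  o1 <- overlaps_any(genomic_intervals(sim$pets$chrom1, sim$pets$start1,
                                       sim$pets$end1), prom)
  o2 <- overlaps_any(genomic_intervals(sim$pets$chrom2, sim$pets$start2,
                                       sim$pets$end2), prom)
  expect_true(all(xor(o1, o2)))
  expect_error(simulate_pets(prom, genomic_intervals("chrS", 10100, 11000),
                             seed = 1),
               "disjoint")
})

test_that("planted motifs are recovered by scanning, with strand", {
  set.seed(31)
  s <- rand_dna(300)
  inst <- data.frame(name = c("HRE", "HRE"), consensus = "RCGTG",
                     position = c(50L, 120L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  planted <- plant_motifs(s, inst, seed = 8)
  hits <- scan_motifs(planted, data.frame(name = "HRE", consensus = "RCGTG",
                                          both_strands = TRUE))
  expect_true(any(hits$position == 50 & hits$strand == "+"))
  expect_true(any(hits$position == 120 & hits$strand == "-"))
  expect_identical(plant_motifs(s, inst[0, ], seed = 1), s)
  overlapping <- data.frame(name = "HRE", consensus = "RCGTG",
                            position = c(10L, 12L), strand = "+")
  expect_error(plant_motifs(s, overlapping, seed = 1), "overlapping")
})

test_that("methylation simulation respects conversion and coverage", {
  sim <- simulate_methylation(c(10L, 20L, 30L), "methylated", coverage = 200,
                              conversion_rate = 1, dropout = 0, seed = 9)
  expect_equal(sim$records$unmethylated, c(0L, 0L, 0L))
  expect_true(all(sim$records$methylated > 0))

  none <- simulate_methylation(c(10L, 20L), "unmethylated", coverage = 0,
                               conversion_rate = 0.99, dropout = 0, seed = 9)
  expect_true(nrow(none$records) == 0 ||
                all(none$records$methylated + none$records$unmethylated == 0))
})

test_that("generated files survive the core round trips", {
  gm <- make_toy_gene_model(2e5, 5, seed = 13, gene_offset = 0.1)
  meta <- data.frame(sample_id = "s1", condition = "c")
  ab <- list(c = setNames(rep(50, 5), gm$model$start_exons$name))
  sim <- simulate_variant_reads(gm$model, meta, ab, background_mean = 100,
                                genome_length = 2e5, seed = 14)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(sim$alignments, p)
  expect_equal(read_alignments_tsv(p), sim$alignments, ignore_attr = TRUE)
  tb <- withr::local_tempfile(fileext = ".json")
  write_truth_bundle(sim$truth, tb)
  back <- read_truth_bundle(tb)
  expect_equal(back$dispersion, sim$truth$dispersion)
})
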