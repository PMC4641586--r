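# a small two-exon model used across counting tests; exons overlap so the
# multi-assignment rule is exercised
toy_model <- gene_model(
  gene_id = "g", chrom = "chrS", strand = "+",
  start_exons = data.frame(name = c("5u", "9u", "ov"),
                           start = c(120L, 1000L, 180L),
                           end = c(220L, 1150L, 320L),
                           tss = c(120L, 1000L, 180L)),
  promoter = genomic_intervals("chrS", 0, 100),
  cancer_exon = "5u", muscle_exon = "9u")

aln <- function(start, end, strand = "+", id = NULL, sample = "s1") {
  data.frame(chrom = "chrS", start = start, end = end, strand = strand,
             sample_id = sample,
             read_id = if (is.null(id)) sprintf("r%d", seq_along(start)) else id,
             stringsAsFactors = FALSE)
}

test_that("start-exon counting uses >=1 bp overlap with multi-assignment", {
  cnt <- count_start_exon_reads(aln(100, 150), toy_model)
  expect_equal(unname(cnt["5u"]), 1L)   # overlaps [120,220) by 30 bp
  expect_equal(unname(cnt["9u"]), 0L)
  cnt2 <- count_start_exon_reads(aln(500, 550), toy_model)
  expect_true(all(cnt2 == 0L))          # counted nowhere
  # read spanning both overlapping exons contributes to each
  cnt3 <- count_start_exon_reads(aln(190, 240), toy_model)
  expect_equal(unname(cnt3[c("5u", "ov")]), c(1L, 1L))
  # two blocks of one spliced read hitting the same exon count once
  spliced <- aln(c(121, 200), c(140, 215), id = c("r1", "r1"))
  expect_equal(unname(count_start_exon_reads(spliced, toy_model)["5u"]), 1L)
})

test_that("RPKM follows its definition and rejects bad denominators", {
  expect_equal(compute_rpkm(0, 200, 1e6), 0)
  expect_equal(compute_rpkm(100, 1000, 1e6), 100)
  expect_equal(compute_rpkm(300, 600, 2e6), 250)
  expect_error(compute_rpkm(1, 0, 1e6), "feature_length")
  expect_error(compute_rpkm(1, 100, 0), "total_mapped_reads")
})

test_that("RPKM is invariant under joint scaling of counts and library", {
  set.seed(17)
  for (i in 1:100) {
    cnt <- sample(0:5000, 1); len <- sample(80:2000, 1)
    tot <- sample(1e5:1e7, 1); f <- sample(2:50, 1)
    expect_equal(compute_rpkm(cnt * f, len, tot * f),
                 compute_rpkm(cnt, len, tot))
  }
})

test_that("GRO-Seq windows count 5' ends, stranded, 0.6 kb normalised", {
  m <- gene_model(gene_id = "g", chrom = "chrS", strand = "+",
                  start_exons = data.frame(name = "5u", start = 1000L,
                                           end = 1200L, tss = 1000L),
                  promoter = genomic_intervals("chrS", 821, 1025))
  meta <- data.frame(sample_id = "s1", condition = "c",
                     total_mapped_reads = 1e6)
  # window [900, 1500); 5' end at 950 counted, 1499 counted, 1500 not
  a <- aln(c(950, 1499, 1500, 880, 950), c(1000, 1540, 1550, 930, 1000),
           strand = c("+", "+", "+", "+", "-"))
  rec <- groseq_tss_rpkm(a, m, meta)
  expect_equal(rec$raw_count, 2L)  # minus-strand read excluded when stranded
  expect_equal(rec$feature_length, 600)
  rec6 <- groseq_tss_rpkm(aln(rep(1000, 6), rep(1050, 6)), m, meta)
  expect_equal(rec6$rpkm, 10)      # 6 / 0.6 / 1

  # mirrored minus-strand gene gives identical counts
  L <- 3000L
  mm <- gene_model(gene_id = "g", chrom = "chrS", strand = "-",
                   start_exons = data.frame(name = "5u",
                                            start = L - 1200L, end = L - 1000L,
                                            tss = L - 1001L),
                   promoter = genomic_intervals("chrS", L - 1025, L - 821))
  am <- aln(L - c(1000, 1540, 1550, 930), L - c(950, 1499, 1500, 880),
            strand = "-")
  recm <- groseq_tss_rpkm(am, mm, meta)
  expect_equal(recm$raw_count, 2L)
  expect_equal(recm$rpkm, rec$rpkm)
})

test_that("GRO-Seq window counts equal a brute-force per-read check", {
  set.seed(18)
  m <- make_toy_gene_model(2e5, 5, seed = 44, gene_offset = 0.1)$model
  starts <- sample.int(2e5 - 60, 800) - 1L
  strands <- sample(c("+", "-"), 800, replace = TRUE)
  a <- aln(starts, starts + 50L, strand = strands)
  meta <- data.frame(sample_id = "s1", condition = "c",
                     total_mapped_reads = 1e6)
  rec <- groseq_tss_rpkm(a, m, meta)
  for (i in seq_len(nrow(m$start_exons))) {
    tss <- m$start_exons$tss[i]
    pos5 <- ifelse(strands == "-", starts + 49L, starts)
    want <- sum(strands == "+" & pos5 >= tss - 100 & pos5 < tss + 500)
    expect_equal(rec$raw_count[rec$unit_name == m$start_exons$name[i]], want)
  }
})

test_that("one-way ANOVA matches hand computation on fixtures", {
  r <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  g <- list(c(1, 2, 3), c(101, 102, 103))
  r2 <- one_way_anova(g)
  # independent arithmetic: SSB = 3*(50^2+50^2) = 15000 on 1 df,
  # SSW = 2 + 2 = 4 on 4 df -> F = 15000 / 1
  ssb <- 3 * sum((sapply(g, mean) - mean(unlist(g)))^2)
  ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
  expect_equal(r2$F, (ssb / 1) / (ssw / 4))
  expect_equal(r2$F, 15000)
  expect_equal(r2$p, pf(15000, 1, 4, lower.tail = FALSE))

  # exchangeability within groups
  r3 <- one_way_anova(list(c(3, 1, 2), c(103, 101, 102)))
  expect_equal(r3$F, r2$F)

  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least two values")
  expect_error(one_way_anova(list(1:3, c(1, NA, 3))), "finite")
})

test_that("Tukey-Kramer agrees with TukeyHSD and the k=2 t-test identity", {
  set.seed(19)
  # unbalanced three-group fixture: compare adjusted p with TukeyHSD
  g <- list(a = rnorm(5, 0), b = rnorm(7, 1), c = rnorm(4, 3))
  tk <- tukey_kramer(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  hsd <- TukeyHSD(aov(y ~ grp, data = df))$grp
  for (i in seq_len(nrow(tk))) {
    key <- paste(tk$group_b[i], tk$group_a[i], sep = "-")
    expect_equal(tk$p_adj[i], hsd[key, "p adj"], tolerance = 1e-6)
  }
  # identical groups are never significant
  expect_false(any(tukey_kramer(list(c(1, 2, 3), c(1, 2, 3)))$significant))
  # k = 2: decision equals the pooled two-sided t-test (q = sqrt(2) |t|)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(5, sample(c(0, 2), 1))
    tk2 <- tukey_kramer(list(x, y), alpha = 0.05)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(tk2$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-9)
    expect_equal(tk2$significant, tt$p.value < 0.05)
  }
  # studentized-range critical value q(3, 12, 0.05)
  expect_equal(qtukey(0.95, 3, 12), 3.773, tolerance = 0.01)
})

test_that("condition fold changes report treated/control ratios and flags", {
  rec <- data.frame(
    sample_id = rep(sprintf("s%d", 1:6), each = 1),
    condition = rep(c("t", "c"), each = 3),
    unit_name = "5u", raw_count = 0L, feature_length = 100L,
    rpkm = c(86, 86, 86, 20, 20, 20), stringsAsFactors = FALSE)
  fc <- condition_fold_changes(rec, "t", "c")
  expect_equal(fc$fold_change, 4.3)
  expect_equal(fc$pct_of_control, 430)

  same <- rec; same$rpkm <- rep(c(5, 7, 9), 2)
  fc2 <- condition_fold_changes(same, "t", "c")
  expect_equal(fc2$fold_change, 1)
  expect_equal(fc2$anova_F, 0)

  zero <- rec; zero$rpkm[zero$condition == "c"] <- 0
  fc3 <- condition_fold_changes(zero, "t", "c")
  expect_false(fc3$fold_defined)
  expect_true(is.na(fc3$fold_change))
})
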