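promoter <- genomic_intervals("chrS", 1000, 2000)

pet_row <- function(s1, e1, s2, e2, dataset = "ds1") {
  data.frame(chrom1 = "chrS", start1 = s1, end1 = e1, chrom2 = "chrS",
             start2 = s2, end2 = e2, pet_count = 1L, factor = "PolII",
             dataset_id = dataset, stringsAsFactors = FALSE)
}

test_that("promoter anchoring keeps exactly-one-anchor pairs", {
  pets <- rbind(
    pet_row(1500, 1600, 250000, 250300),   # one anchor on promoter
    pet_row(250000, 250300, 1500, 1600),   # same, swapped order
    pet_row(50000, 50300, 250000, 250300), # neither
    pet_row(1100, 1200, 1500, 1600))       # both
  got <- promoter_anchored_pets(pets, promoter)
  expect_equal(nrow(got), 2L)
  expect_equal(got$distal_start, c(250000L, 250000L))
  expect_equal(got$distal_end, c(250300L, 250300L))
  st <- attr(got, "stats")
  expect_equal(unname(st["both_on_promoter"]), 1L)
  expect_equal(unname(st["neither_on_promoter"]), 1L)
})

test_that("promoter anchoring equals the brute-force double-overlap oracle", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    s1 <- sample.int(3e5, n) - 1L; s2 <- sample.int(3e5, n) - 1L
    pets <- pet_row(s1, s1 + sample(100:500, n, TRUE),
                    s2, s2 + sample(100:500, n, TRUE))
    got <- promoter_anchored_pets(pets, promoter)
    ov <- function(s, e) s < 2000 & 1000 < e
    o1 <- ov(pets$start1, pets$end1); o2 <- ov(pets$start2, pets$end2)
    expect_equal(nrow(got), sum(xor(o1, o2)))
    keep <- which(xor(o1, o2))
    want_start <- ifelse(o1[keep], pets$start2[keep], pets$start1[keep])
    expect_equal(got$distal_start, want_start)
  }
})

test_that("candidate regions merge, filter and name deterministically", {
  pets <- rbind(
    pet_row(1500, 1600, 250000, 250300),
    pet_row(1500, 1600, 250200, 250500),
    pet_row(1500, 1600, 400000, 400200, dataset = "ds2"))
  anchored <- promoter_anchored_pets(pets, promoter)
  reg <- define_candidate_regions(anchored, promoter, merge_gap = 1000)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$region_id, c("A", "B"))
  expect_equal(reg$start[1], 250000L)
  expect_equal(reg$end[1], 250500L)   # union of the two anchors
  expect_equal(reg$n_pets, c(2L, 1L))
  expect_equal(reg$n_datasets, c(1L, 1L))
  expect_equal(reg$distance_to_promoter[1], 250000L - 2000L)

  # two anchors 10 kb apart stay separate at merge_gap 1 kb
  far <- promoter_anchored_pets(rbind(
    pet_row(1500, 1600, 100000, 100200),
    pet_row(1500, 1600, 110000, 110200)), promoter)
  expect_equal(nrow(define_candidate_regions(far, promoter)), 2L)

  # min_support drops singleton regions
  reg2 <- define_candidate_regions(anchored, promoter, min_support = 2)
  expect_equal(reg2$region_id, "A")
})

test_that("evidence matrix cells follow present/absent/no_data semantics", {
  regions <- data.frame(region_id = c("A", "B"), chrom = "chrS",
                        start = c(250000L, 400000L), end = c(250500L, 400200L),
                        stringsAsFactors = FALSE)
  tracks <- list(
    assay_track("DNase", "normoxia",
                genomic_intervals("chrS", 250100, 250200), "d1"),
    assay_track("DNase", "normoxia",
                genomic_intervals("chrS", 90000, 90100), "d2"),
    assay_track("HIF1a", "hypoxia",
                genomic_intervals("chrS", c(250050, 1200), c(250150, 1300)),
                "d3"))
  em <- build_evidence_matrix(regions, promoter, tracks)
  cell <- function(r, a, cc) em$status[em$region_id == r & em$assay == a &
                                         em$condition == cc]
  expect_equal(cell("A", "DNase", "normoxia"), "present")
  expect_equal(cell("B", "DNase", "normoxia"), "absent")
  expect_equal(cell("A", "HIF1a", "hypoxia"), "present")
  expect_equal(cell("promoter", "HIF1a", "hypoxia"), "present")
  expect_equal(cell("A", "HIF1a", "normoxia"), "no_data")
  expect_equal(cell("A", "DNase", "hypoxia"), "no_data")

  # every present cell is traceable to a concrete dataset and peak
  audit <- attr(em, "audit")
  present <- unique(em[em$status == "present", c("region_id", "assay",
                                                 "condition")])
  for (i in seq_len(nrow(present)))
    expect_true(any(audit$region_id == present$region_id[i] &
                      audit$assay == present$assay[i] &
                      audit$condition == present$condition[i]))

  # cells are independent of track input order
  em2 <- build_evidence_matrix(regions, promoter, rev(tracks))
  expect_equal(as.data.frame(em), as.data.frame(em2))

  cm <- crossmark_table(em)
  expect_equal(cm$region_id, c("promoter", "A", "B"))
  expect_equal(cm[cm$region_id == "A", "DNase:normoxia"], "X")
  expect_equal(cm[cm$region_id == "B", "DNase:normoxia"], ".")
  expect_equal(cm[cm$region_id == "A", "DNase:hypoxia"], "")
})

test_that("condition-response classification covers all label cases", {
  regions <- data.frame(region_id = c("D1", "open", "shut", "lost"),
                        chrom = "chrS",
                        start = c(1e5, 2e5, 3e5, 4e5),
                        end = c(1e5, 2e5, 3e5, 4e5) + 1000,
                        stringsAsFactors = FALSE)
  peak_at <- function(s) genomic_intervals("chrS", s + 100, s + 300)
  tracks <- list(
    assay_track("DNase", "control",
                rbind(peak_at(2e5), peak_at(4e5)), "c1"),
    assay_track("DNase", "DHT",
                rbind(peak_at(1e5), peak_at(2e5)), "t1"),
    assay_track("AR", "DHT", peak_at(1e5), "t2"))
  em <- build_evidence_matrix(regions, promoter, tracks)
  lab <- classify_condition_response(em, "DNase", "control", "DHT")
  get <- function(r) lab$label[lab$region_id == r]
  expect_equal(get("D1"), "treatment-gained")   # DNase only under androgen
  expect_equal(get("open"), "constitutive")
  expect_equal(get("shut"), "closed")
  expect_equal(get("lost"), "treatment-lost")
  # AR has no control data anywhere -> never guessed
  lab2 <- classify_condition_response(em, "AR", "control", "DHT")
  expect_true(all(lab2$label == "no_data"))
})
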