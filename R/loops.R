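# Promoter-anchored ChIA-PET integration: select pairs with exactly one
# anchor on the promoter, merge the distal anchors into named candidate
# regions, and build the cross-assay, cross-condition evidence matrix.

.anchor1 <- function(pets) genomic_intervals(pets$chrom1, pets$start1, pets$end1)
.anchor2 <- function(pets) genomic_intervals(pets$chrom2, pets$start2, pets$end2)

#' Select promoter-anchored PET pairs
#'
#' Keeps pairs where exactly one anchor overlaps the promoter by at
#' least 1 bp; the other anchor is returned as the distal anchor.
#' Pairs with both anchors on the promoter, or neither, are excluded;
#' their counts are attached as attribute `"stats"`.
#'
#' @param pets PET pair data frame (see [read_bedpe()]).
#' @param promoter One-row interval data frame.
#' @return The qualifying pairs with added columns `distal_chrom`,
#'   `distal_start`, `distal_end`.
#' @export
promoter_anchored_pets <- function(pets, promoter) {
  assert_intervals(promoter)
  if (nrow(pets) == 0) {
    out <- cbind(pets, distal_chrom = character(0), distal_start = integer(0),
                 distal_end = integer(0))
    attr(out, "stats") <- c(input = 0L, kept = 0L, both_on_promoter = 0L,
                            neither_on_promoter = 0L)
    return(out)
  }
  o1 <- overlaps_any(.anchor1(pets), promoter)
  o2 <- overlaps_any(.anchor2(pets), promoter)
  keep <- xor(o1, o2)
  out <- pets[keep, , drop = FALSE]
  promoter_first <- o1[keep]
  out$distal_chrom <- ifelse(promoter_first, out$chrom2, out$chrom1)
  out$distal_start <- ifelse(promoter_first, out$start2, out$start1)
  out$distal_end <- ifelse(promoter_first, out$end2, out$end1)
  rownames(out) <- NULL
  attr(out, "stats") <- c(input = nrow(pets), kept = sum(keep),
                          both_on_promoter = sum(o1 & o2),
                          neither_on_promoter = sum(!o1 & !o2))
  out
}

#' Merge distal anchors into named candidate regions
#'
#' Distal anchors within `merge_gap` bp of each other merge into one
#' region ([merge_intervals()]); regions supported by fewer than
#' `min_support` pairs are dropped.  Region ids are letters assigned in
#' genomic order (`A`, `B`, ...), mirroring the A...G naming of
#' promoter-interacting regions.  Each region reports its distance to
#' the promoter and the supporting datasets.
#'
#' @param anchored Output of [promoter_anchored_pets()].
#' @param promoter One-row interval data frame.
#' @param merge_gap Merge gap in bp (default 1000).
#' @param min_support Minimum supporting PET pairs per region.
#' @return Data frame: `region_id`, `chrom`, `start`, `end`,
#'   `n_pets`, `n_datasets`, `distance_to_promoter`.
#' @export
define_candidate_regions <- function(anchored, promoter, merge_gap = 1000,
                                     min_support = 1) {
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_pets = integer(),
                      n_datasets = integer(),
                      distance_to_promoter = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(anchored) == 0) return(empty)
  anchors <- genomic_intervals(anchored$distal_chrom, anchored$distal_start,
                               anchored$distal_end)
  merged <- merge_intervals(anchors, gap = merge_gap)
  if (nrow(merged) == 0) return(empty)
  support <- integer(nrow(merged)); nds <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    hit <- anchors$chrom == merged$chrom[i] &
      anchors$start < merged$end[i] & merged$start[i] < anchors$end
    support[i] <- sum(hit)
    nds[i] <- length(unique(anchored$dataset_id[hit]))
  }
  keep <- support >= min_support
  merged <- merged[keep, , drop = FALSE]
  support <- support[keep]; nds <- nds[keep]
  if (nrow(merged) == 0) return(empty)
  ord <- order(merged$chrom, merged$start)
  merged <- merged[ord, , drop = FALSE]
  ids <- make.unique(LETTERS[pmin(seq_len(nrow(merged)), 26)], sep = "")
  out <- data.frame(region_id = ids, chrom = merged$chrom,
                    start = merged$start, end = merged$end,
                    n_pets = support[ord], n_datasets = nds[ord],
                    distance_to_promoter =
                      interval_distance(merged, promoter[rep(1, nrow(merged)), ]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct an assay track
#'
#' A peak set from one dataset of one assay under one condition, the
#' unit from which evidence-matrix cells are derived.
#'
#' @param assay Assay label (e.g. DNase, FAIRE, H3K4me1, H3K27ac, PolII,
#'   p300, HIF1a, ERa, AR, CTCF).
#' @param condition Condition label.
#' @param peaks Interval data frame of peak calls.
#' @param dataset_id Dataset identifier.
#' @return An `assay_track` list.
#' @export
assay_track <- function(assay, condition, peaks, dataset_id) {
  assert_intervals(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  structure(list(assay = assay, condition = condition, peaks = peaks,
                 dataset_id = dataset_id), class = "assay_track")
}

#' Build the region x (assay, condition) evidence matrix
#'
#' For every region (the promoter is included as region `"promoter"`)
#' and every (assay, condition) combination spanned by the supplied
#' tracks, the cell is `present` iff any peak of any matching track
#' overlaps the region by at least 1 bp, `absent` iff at least one
#' matching track exists but none overlaps, and `no_data` iff no track
#' matches the combination.  When multiple datasets disagree, `present`
#' wins; every `present` cell is traceable through the audit attribute
#' (`"audit"`), which records one row per supporting (dataset, peak).
#'
#' @param regions Candidate regions (see [define_candidate_regions()]).
#' @param promoter One-row interval data frame.
#' @param tracks List of [assay_track()] objects.
#' @return Long-format data frame (`region_id`, `assay`, `condition`,
#'   `status`) of class `evidence_matrix`.
#' @export
build_evidence_matrix <- function(regions, promoter, tracks) {
  stopifnot(all(vapply(tracks, inherits, logical(1), "assay_track")))
  rows <- rbind(
    data.frame(region_id = "promoter", chrom = promoter$chrom,
               start = promoter$start, end = promoter$end,
               stringsAsFactors = FALSE),
    regions[, c("region_id", "chrom", "start", "end")])
  assays <- unique(vapply(tracks, `[[`, character(1), "assay"))
  conds <- unique(vapply(tracks, `[[`, character(1), "condition"))
  cells <- list(); audit <- list()
  for (as_ in sort(assays)) for (cc in sort(conds)) {
    matching <- Filter(function(t) t$assay == as_ && t$condition == cc, tracks)
    for (i in seq_len(nrow(rows))) {
      reg <- rows[i, , drop = FALSE]
      status <- "no_data"
      if (length(matching) > 0) {
        status <- "absent"
        for (t in matching) {
          hit <- t$peaks$chrom == reg$chrom &
            t$peaks$start < reg$end & reg$start < t$peaks$end
          if (any(hit)) {
            status <- "present"
            h <- which(hit)
            audit[[length(audit) + 1]] <- data.frame(
              region_id = reg$region_id, assay = as_, condition = cc,
              dataset_id = t$dataset_id, peak_chrom = t$peaks$chrom[h],
              peak_start = t$peaks$start[h], peak_end = t$peaks$end[h],
              stringsAsFactors = FALSE)
          }
        }
      }
      cells[[length(cells) + 1]] <- data.frame(
        region_id = reg$region_id, assay = as_, condition = cc,
        status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("evidence_matrix", class(out))
  attr(out, "regions") <- rows
  attr(out, "audit") <- if (length(audit) > 0) do.call(rbind, audit) else
    data.frame(region_id = character(), assay = character(),
               condition = character(), dataset_id = character(),
               peak_chrom = character(), peak_start = integer(),
               peak_end = integer(), stringsAsFactors = FALSE)
  out
}

#' Crossmark table view of an evidence matrix
#'
#' Wide region-by-(assay, condition) table with `X` for present, `.` for
#' absent and empty for no data.
#'
#' @param matrix An `evidence_matrix`.
#' @return Character data frame, one row per region.
#' @export
crossmark_table <- function(matrix) {
  key <- paste(matrix$assay, matrix$condition, sep = ":")
  regions <- unique(matrix$region_id)
  cols <- unique(key)
  out <- data.frame(region_id = regions, stringsAsFactors = FALSE)
  for (cn in cols) {
    v <- vapply(regions, function(r) {
      s <- matrix$status[matrix$region_id == r & key == cn][1]
      switch(s, present = "X", absent = ".", no_data = "")
    }, character(1))
    out[[cn]] <- unname(v)
  }
  out
}

#' Classify the condition response of each region for one assay
#'
#' `treatment-gained` iff present under treatment and absent in control;
#' `treatment-lost` for the reverse; `constitutive` iff present in both;
#' `closed` iff absent in both; `no_data` when either condition lacks
#' data (never guessed).
#'
#' @param matrix An `evidence_matrix`.
#' @param assay Assay to classify on.
#' @param control_condition,treated_condition Condition labels.
#' @return Data frame `region_id`, `label`.
#' @export
classify_condition_response <- function(matrix, assay, control_condition,
                                        treated_condition) {
  regions <- unique(matrix$region_id)
  lab <- vapply(regions, function(r) {
    ctl <- matrix$status[matrix$region_id == r & matrix$assay == assay &
                           matrix$condition == control_condition]
    trt <- matrix$status[matrix$region_id == r & matrix$assay == assay &
                           matrix$condition == treated_condition]
    if (length(ctl) == 0 || length(trt) == 0 ||
        ctl[1] == "no_data" || trt[1] == "no_data") return("no_data")
    if (trt[1] == "present" && ctl[1] == "absent") return("treatment-gained")
    if (trt[1] == "absent" && ctl[1] == "present") return("treatment-lost")
    if (trt[1] == "present" && ctl[1] == "present") return("constitutive")
    "closed"
  }, character(1))
  data.frame(region_id = regions, label = unname(lab), stringsAsFactors = FALSE)
}
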