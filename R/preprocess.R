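# Read trimming, filtering and masking rules applied before mapping.
# Reads travel as data frames (id, seq, qual) with Phred+33 quality
# strings, as produced by read_fastq().

.phred <- function(qual) utf8ToInt(qual) - 33L

# Modified-Mott quality trimming: per base, error probability
# p = 10^(-Q/10); keep the contiguous segment maximising
# sum(limit - p).  Ties resolve to the leftmost, earliest-start segment.
# Returns c(first, last) 1-based, or c(1, 0) when everything is trimmed.
.mott_segment <- function(q, limit) {
  s <- limit - 10^(-q / 10)
  cs <- cumsum(s)
  best <- 0; bi <- 1L; bj <- 0L
  minv <- 0; mini <- 0L
  for (j in seq_along(cs)) {
    sc <- cs[j] - minv
    if (sc > best + 1e-12) { best <- sc; bi <- mini + 1L; bj <- j }
    if (cs[j] < minv) { minv <- cs[j]; mini <- j }
  }
  c(bi, bj)
}

#' Named preprocessing profiles
#'
#' Parameter sets for the three read classes the pipeline consumes:
#' \describe{
#'   \item{rnaseq}{trim 12 bp from the 5' end and 5 bp from the 3' end,
#'     quality-trim at error-probability limit 0.05, keep reads of at
#'     least 15 bp with at most 2 ambiguous bases.}
#'   \item{groseq}{trim 12 bp from the 5' end, quality limit 0.01,
#'     minimum remaining length 10 bp, at most 2 ambiguous bases.}
#'   \item{chip_bisulfite}{reject reads with mean Phred below 30, then
#'     mask the first 15 and last 5 bases with N.}
#' }
#'
#' @param name One of `"rnaseq"`, `"groseq"`, `"chip_bisulfite"`.
#' @return A list of preprocessing parameters (`mode` is `"trim"` or
#'   `"mask"`).
#' @export
preprocess_profile <- function(name = c("rnaseq", "groseq", "chip_bisulfite")) {
  switch(match.arg(name),
    rnaseq = list(mode = "trim", trim5 = 12L, trim3 = 5L, min_length = 15L,
                  max_ambiguous = 2L, quality_limit = 0.05),
    groseq = list(mode = "trim", trim5 = 12L, trim3 = 0L, min_length = 10L,
                  max_ambiguous = 2L, quality_limit = 0.01),
    chip_bisulfite = list(mode = "mask", min_phred = 30, mask5 = 15L, mask3 = 5L))
}

#' Trim and filter raw reads
#'
#' Applies, in order: fixed trimming (`trim5` bases from the 5' end,
#' `trim3` from the 3' end), modified-Mott quality trimming at
#' `quality_limit` (skipped when `NULL`), then discards reads shorter
#' than `min_length` or with more than `max_ambiguous` N bases.  Input
#' order is preserved; per-stage counts are attached as attribute
#' `"stats"`.
#'
#' @param reads Reads data frame (`id`, `seq`, `qual`).
#' @param profile A profile list with `mode = "trim"` (see
#'   [preprocess_profile()]).
#' @return Surviving reads data frame (possibly empty).
#' @export
trim_and_filter <- function(reads, profile) {
  stopifnot(identical(profile$mode, "trim"))
  n_in <- nrow(reads)
  if (n_in == 0) {
    attr(reads, "stats") <- c(input = 0L, kept = 0L, dropped_short = 0L,
                              dropped_ambiguous = 0L)
    return(reads)
  }
  len <- nchar(reads$seq)
  from <- pmin(profile$trim5 + 1L, len + 1L)
  to <- pmax(len - profile$trim3, 0L)
  seq <- substr(reads$seq, from, to)
  qual <- substr(reads$qual, from, to)
  if (!is.null(profile$quality_limit)) {
    for (i in seq_len(n_in)) {
      if (!nzchar(seq[i])) next
      seg <- .mott_segment(.phred(qual[i]), profile$quality_limit)
      seq[i] <- substr(seq[i], seg[1], seg[2])
      qual[i] <- substr(qual[i], seg[1], seg[2])
    }
  }
  n_amb <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  too_short <- nchar(seq) < profile$min_length
  too_amb <- !too_short & n_amb > profile$max_ambiguous
  keep <- !too_short & !too_amb
  out <- data.frame(id = reads$id[keep], seq = seq[keep], qual = qual[keep],
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(input = n_in, kept = sum(keep),
                          dropped_short = sum(too_short),
                          dropped_ambiguous = sum(too_amb))
  out
}

#' Phred rejection and end masking
#'
#' Rejects reads whose mean Phred score is below `min_phred`; for
#' survivors, replaces the first `mask5` and last `mask3` bases with N
#' (read length unchanged).  Reads too short to mask
#' (`length <= mask5 + mask3`) are rejected and counted.  Counts are
#' attached as attribute `"stats"`.
#'
#' @param reads Reads data frame (`id`, `seq`, `qual`).
#' @param min_phred Mean-Phred rejection threshold.
#' @param mask5,mask3 Bases masked at the 5' / 3' end.
#' @return Surviving reads data frame with masked sequences.
#' @export
phred_filter_and_mask <- function(reads, min_phred = 30, mask5 = 15, mask3 = 5) {
  n_in <- nrow(reads)
  if (n_in == 0) {
    attr(reads, "stats") <- c(input = 0L, kept = 0L, rejected_quality = 0L,
                              rejected_short = 0L)
    return(reads)
  }
  len <- nchar(reads$seq)
  meanq <- vapply(reads$qual, function(q) mean(.phred(q)), numeric(1),
                  USE.NAMES = FALSE)
  low <- meanq < min_phred
  short <- !low & len <= mask5 + mask3
  keep <- !low & !short
  seq <- reads$seq[keep]; l <- len[keep]
  if (length(seq) > 0) {
    if (mask5 > 0) substr(seq, 1L, mask5) <- strrep("N", mask5)
    if (mask3 > 0)
      seq <- paste0(substr(seq, 1L, l - mask3), strrep("N", mask3))
  }
  out <- data.frame(id = reads$id[keep], seq = seq, qual = reads$qual[keep],
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(input = n_in, kept = sum(keep),
                          rejected_quality = sum(low),
                          rejected_short = sum(short))
  out
}
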