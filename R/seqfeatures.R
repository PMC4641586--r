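# IUPAC consensus motif scanning for candidate regulatory elements and
# per-CpG methylation calling within candidate regions.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")

#' Default motif definitions
#'
#' Literature-standard consensus cores for the elements annotated around
#' hormone- and hypoxia-regulated promoters: the hypoxia response
#' element (HRE, `RCGTG` bound by HIF), estrogen response element half
#' site (`RGGTCA`), full and half androgen response elements
#' (`GGWACANNNTGTTCT`, `AGAACA`), the RUNX1 core (`TGTGGT`) and the SP1
#' box (`GGGCGG`).  All are scanned on both strands and can be
#' overridden by supplying your own definition table.
#'
#' @return Data frame with `name`, `consensus`, `both_strands`.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("HRE", "ERE_half", "ARE", "ARE_half", "RUNX1", "SP1"),
    consensus = c("RCGTG", "RGGTCA", "GGWACANNNTGTTCT", "AGAACA",
                  "TGTGGT", "GGGCGG"),
    both_strands = TRUE, stringsAsFactors = FALSE)
}

.check_consensus <- function(consensus) {
  bad <- setdiff(strsplit(toupper(consensus), "")[[1]], names(.IUPAC))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in consensus '", consensus, "': ",
         paste(unique(bad), collapse = ", "))
  toupper(consensus)
}

#' Scan a sequence for IUPAC consensus motifs
#'
#' Exact IUPAC matching (ambiguity codes in the consensus match their
#' base sets; N in the sequence matches nothing but an N code).  For
#' motifs scanned on both strands, minus-strand hits are positions whose
#' reverse-complemented window matches the consensus; they are reported
#' at the window's plus-strand coordinates with `strand = "-"`, and
#' `matched_sequence` is always the plus-strand window.
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param motifs Motif definition data frame (`name`, `consensus`,
#'   `both_strands`); default [default_motifs()].
#' @param offset Genomic start of `sequence` (added to positions).
#' @param chrom Chromosome name attached to hits.
#' @return Data frame: `motif`, `chrom`, `position` (0-based),
#'   `strand`, `matched_sequence`.
#' @export
scan_motifs <- function(sequence, motifs = default_motifs(), offset = 0,
                        chrom = "chrS") {
  subject <- Biostrings::DNAString(toupper(sequence))
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    cons <- .check_consensus(motifs$consensus[i])
    pat <- Biostrings::DNAString(cons)
    strands <- if (isTRUE(motifs$both_strands[i])) c("+", "-") else "+"
    for (s in strands) {
      p <- if (s == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subject, fixed = "subject")
      if (length(m) == 0) next
      st <- IRanges::start(m)
      rows[[length(rows) + 1]] <- data.frame(
        motif = motifs$name[i], chrom = chrom,
        position = st - 1L + offset, strand = s,
        matched_sequence = as.character(m), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(motif = character(), chrom = character(),
                      position = integer(), strand = character(),
                      matched_sequence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-CpG methylation fractions and calls
#'
#' `fraction = methylated / (methylated + unmethylated)`.  Sites covered
#' by fewer than `min_coverage` reads are `no_call`; otherwise the call
#' is `unmethylated` when the fraction is at most `unmeth_max`,
#' `methylated` when at least `meth_min`, and `intermediate` between.
#'
#' @param records CpG count data frame (`chrom`, `pos`, `methylated`,
#'   `unmethylated`).
#' @param min_coverage Minimum total reads for a call.
#' @param unmeth_max,meth_min Fraction thresholds.
#' @return `records` with added `coverage`, `fraction`, `call`.
#' @export
methylation_fraction_and_call <- function(records, min_coverage = 4,
                                          unmeth_max = 0.2, meth_min = 0.8) {
  stopifnot(unmeth_max >= 0, unmeth_max < meth_min, meth_min <= 1)
  cov <- records$methylated + records$unmethylated
  frac <- ifelse(cov > 0, records$methylated / cov, NA_real_)
  call <- ifelse(cov < min_coverage, "no_call",
                 ifelse(frac <= unmeth_max, "unmethylated",
                        ifelse(frac >= meth_min, "methylated", "intermediate")))
  out <- records
  out$coverage <- cov
  out$fraction <- frac
  out$call <- call
  out
}

#' Keep records on one chromosome
#'
#' Exact string match on the `chrom` column, order preserved; the
#' number of dropped records is attached as attribute `"dropped"`.
#'
#' @param records Any data frame with a `chrom` column.
#' @param chrom_name Chromosome to keep.
#' @return The matching records.
#' @export
filter_chromosome <- function(records, chrom_name) {
  keep <- records$chrom == chrom_name
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Annotate candidate regions with motif hits and CpG calls
#'
#' Per region, lists the contained motif hits and methylation calls
#' (>= 1 bp overlap with the region).  Regions without features are
#' retained with empty feature fields; features falling outside all
#' regions are counted in attribute `"unassigned"`.
#'
#' @param regions Candidate regions (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param motif_hits Output of [scan_motifs()] (may be empty).
#' @param methylation_calls Output of
#'   [methylation_fraction_and_call()] (may be empty or `NULL`).
#' @return Long data frame: `region_id`, `feature_type`
#'   (`motif`/`CpG`/`none`), `name`, `position`, `strand`, `value`
#'   (matched sequence or methylation call).
#' @export
annotate_regions <- function(regions, motif_hits, methylation_calls = NULL) {
  mh <- if (is.null(motif_hits)) data.frame() else motif_hits
  mc <- if (is.null(methylation_calls)) data.frame() else methylation_calls
  used_m <- if (nrow(mh) > 0) rep(FALSE, nrow(mh)) else logical(0)
  used_c <- if (nrow(mc) > 0) rep(FALSE, nrow(mc)) else logical(0)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    any_feat <- FALSE
    if (nrow(mh) > 0) {
      w <- nchar(mh$matched_sequence)
      hit <- which(mh$chrom == r$chrom & mh$position < r$end &
                     r$start < mh$position + w)
      used_m[hit] <- TRUE
      for (j in hit) {
        any_feat <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          region_id = r$region_id, feature_type = "motif",
          name = mh$motif[j], position = mh$position[j],
          strand = mh$strand[j], value = mh$matched_sequence[j],
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(mc) > 0) {
      hit <- which(mc$chrom == r$chrom & mc$pos >= r$start & mc$pos < r$end)
      used_c[hit] <- TRUE
      for (j in hit) {
        any_feat <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          region_id = r$region_id, feature_type = "CpG",
          name = sprintf("CpG_%d", mc$pos[j]), position = mc$pos[j],
          strand = "*", value = mc$call[j], stringsAsFactors = FALSE)
      }
    }
    if (!any_feat)
      rows[[length(rows) + 1]] <- data.frame(
        region_id = r$region_id, feature_type = "none", name = NA_character_,
        position = NA_integer_, strand = NA_character_, value = NA_character_,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(region_id = character(), feature_type = character(),
               name = character(), position = integer(), strand = character(),
               value = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unassigned") <- c(motifs = sum(!used_m), cpgs = sum(!used_c))
  out
}
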