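#' Gene model with alternative start exons
#'
#' A `gene_model` describes one gene transcribed from several mutually
#' exclusive first exons ("start exons", labelled `1u`, `2u`, ... as for
#' the human myoglobin gene), each marking its own promoter/TSS.  One
#' start exon is designated the cancer-associated exon (the `5u`
#' analogue) and one the muscle exon (the `9u` analogue, near-silent in
#' epithelial cells).  The promoter interval spans 179 bp upstream to
#' 25 bp downstream of the cancer start exon's first transcribed base.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start_exons Data frame with columns `name`, `start`, `end`,
#'   `tss` (0-based half-open coordinates; `tss` within the exon).
#' @param promoter One-row interval data frame (see [genomic_intervals()]).
#' @param cancer_exon,muscle_exon Names of the designated exons; must
#'   appear in `start_exons$name`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start_exons, promoter,
                       cancer_exon = NULL, muscle_exon = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(start_exons) >= 1)
  need <- c("name", "start", "end", "tss")
  if (!all(need %in% names(start_exons)))
    stop("start_exons must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(start_exons$name))
    stop("start exon names must be unique within a gene model")
  if (any(start_exons$end <= start_exons$start))
    stop("start exon end must be > start")
  bad <- start_exons$tss < start_exons$start | start_exons$tss >= start_exons$end
  if (any(bad))
    stop("tss must lie within [start, end) for exon(s): ",
         paste(start_exons$name[bad], collapse = ", "))
  assert_intervals(promoter)
  stopifnot(nrow(promoter) == 1)
  for (ex in c(cancer_exon, muscle_exon))
    if (!ex %in% start_exons$name)
      stop("designated exon '", ex, "' not among start exons")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand,
                 start_exons = as.data.frame(start_exons),
                 promoter = promoter[, c("chrom", "start", "end"), drop = FALSE],
                 cancer_exon = cancer_exon, muscle_exon = muscle_exon),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model '%s' on %s (%s): %d start exons\n",
              x$gene_id, x$chrom, x$strand, nrow(x$start_exons)))
  cat(sprintf("  promoter: [%d, %d)  (%d bp)\n", x$promoter$start,
              x$promoter$end, x$promoter$end - x$promoter$start))
  if (!is.null(x$cancer_exon))
    cat("  cancer-promoter exon:", x$cancer_exon, "\n")
  if (!is.null(x$muscle_exon))
    cat("  muscle exon:", x$muscle_exon, "\n")
  print(x$start_exons, row.names = FALSE)
  invisible(x)
}

# start exons as an interval data frame (chrom/start/end/strand/name)
start_exon_intervals <- function(model) {
  genomic_intervals(model$chrom, model$start_exons$start,
                    model$start_exons$end, model$strand,
                    name = model$start_exons$name)
}

#' Promoter interval around a start exon's TSS
#'
#' The cancer-active promoter convention: `up` bases upstream through
#' `down` bases downstream of the first transcribed base, oriented by
#' gene strand (defaults give the 204 bp `-179/+25` interval).
#'
#' @param chrom Chromosome.
#' @param tss 0-based position of the first transcribed base.
#' @param strand Gene strand.
#' @param up,down Extent upstream / downstream of the TSS in bp.
#' @return One-row interval data frame.
#' @export
promoter_interval <- function(chrom, tss, strand, up = 179, down = 25) {
  if (strand == "+") {
    genomic_intervals(chrom, max(0, tss - up), tss + down)
  } else {
    genomic_intervals(chrom, max(0, tss - down + 1), tss + up + 1)
  }
}
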