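# Readers/writers for the plain-text formats the pipeline touches.
# Tabular formats go through .parse_lines so that a malformed line is
# reported with its line number and the offending field.  FASTA/FASTQ go
# through Biostrings; GTF import goes through rtracklayer.

# -- generic line-walking table reader ---------------------------------------

# field_types: "c" character, "i" integer, "n" numeric
.parse_lines <- function(path, field_names, field_types,
                         min_fields = length(field_names),
                         sep_re = "[ \t]+", skip_re = "^(#|track\\b|browser\\b)") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl(skip_re, lines))
  if (length(keep) == 0) {
    out <- stats::setNames(rep(list(character()), length(field_names)), field_names)
    for (j in seq_along(out)) {
      out[[j]] <- switch(field_types[j], c = character(), i = integer(), n = numeric())
    }
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[keep]), sep_re)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: expected at least %d fields, found %d",
                 path, keep[bad[1]], min_fields, nf[bad[1]]))
  ncol_use <- min(length(field_names), min(nf))
  out <- vector("list", ncol_use)
  names(out) <- field_names[seq_len(ncol_use)]
  for (j in seq_len(ncol_use)) {
    v <- vapply(fields, `[[`, character(1), j)
    if (field_types[j] %in% c("i", "n")) {
      conv <- suppressWarnings(if (field_types[j] == "i") as.integer(v) else as.numeric(v))
      broken <- which(is.na(conv) & !is.na(v))
      if (length(broken) > 0)
        stop(sprintf("%s: line %d, field '%s': not %s ('%s')",
                     path, keep[broken[1]], field_names[j],
                     if (field_types[j] == "i") "an integer" else "numeric",
                     v[broken[1]]))
      out[[j]] <- conv
    } else {
      out[[j]] <- v
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# -- BED / bedGraph ----------------------------------------------------------

#' Read a BED file (3-6 columns)
#'
#' @param path Path to a BED file; `track`/`browser`/comment lines are
#'   skipped.
#' @return Interval data frame with `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- .parse_lines(path,
                    c("chrom", "start", "end", "name", "score", "strand"),
                    c("c", "i", "n", "c", "n", "c"), min_fields = 3)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  assert_intervals(x)
  x
}

#' Write intervals as BED
#'
#' Writes 6 columns when `name` or `strand` is available, else 3.
#' Rows are ordered by chromosome then start.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param track_name Optional `track name=...` header line.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, track_name = NULL) {
  assert_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track name="%s"', track_name), con)
  if (nrow(x) > 0) {
    if (!is.null(x$name) || !is.null(x$strand)) {
      nm <- if (is.null(x$name)) rep(".", nrow(x)) else x$name
      sc <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
      st <- if (is.null(x$strand)) rep("*", nrow(x)) else x$strand
      writeLines(paste(x$chrom, x$start, x$end, nm, sc, st, sep = "\t"), con)
    } else {
      writeLines(paste(x$chrom, x$start, x$end, sep = "\t"), con)
    }
  }
  invisible(path)
}

read_bedgraph <- function(path) {
  .parse_lines(path, c("chrom", "start", "end", "value"), c("c", "i", "i", "n"))
}

# -- BEDPE (ChIA-PET pairs) --------------------------------------------------

#' Read ChIA-PET pairs from BEDPE
#'
#' Columns 1-6 are the two anchors; column 7 (name) stores
#' `factor|dataset_id`, column 8 (score) the PET count.
#'
#' @param path BEDPE path.
#' @return Data frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `pet_count`, `factor`, `dataset_id`.
#' @export
read_bedpe <- function(path) {
  x <- .parse_lines(path,
                    c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score"),
                    c("c", "i", "i", "c", "i", "i", "c", "n"), min_fields = 6)
  out <- x[c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  out$pet_count <- if (is.null(x$score)) rep(1L, nrow(x)) else as.integer(x$score)
  nm <- if (is.null(x$name)) rep("NA|NA", nrow(x)) else x$name
  parts <- strsplit(nm, "|", fixed = TRUE)
  out$factor <- vapply(parts, `[`, character(1), 1)
  out$dataset_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                           character(1))
  if (nrow(out) > 0 && any(out$pet_count < 1, na.rm = TRUE))
    stop("pet_count must be >= 1")
  out
}

#' Write ChIA-PET pairs as BEDPE
#' @param pets Pair data frame (see [read_bedpe()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pets, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(pets) > 0) {
    nm <- paste(pets$factor, pets$dataset_id, sep = "|")
    writeLines(paste(pets$chrom1, pets$start1, pets$end1,
                     pets$chrom2, pets$start2, pets$end2,
                     nm, pets$pet_count, ".", ".", sep = "\t"), con)
  }
  invisible(path)
}

# -- alignments: simplified TSV and SAM subset -------------------------------

.aln_cols <- c("chrom", "start", "end", "strand", "sample_id", "read_id")

#' Read alignments from the simplified 6-column TSV
#'
#' Tab-separated `chrom start end strand sample_id read_id` with 0-based
#' half-open coordinates; an optional header line is skipped.  This is
#' the binary-free alignment interchange format the synthetic generator
#' emits.
#'
#' @param path TSV path.
#' @return Alignment data frame.
#' @export
read_alignments_tsv <- function(path) {
  x <- .parse_lines(path, .aln_cols, c("c", "c", "c", "c", "c", "c"),
                    min_fields = 6, sep_re = "\t")
  if (nrow(x) > 0 && x$chrom[1] == "chrom") x <- x[-1, , drop = FALSE]  # header
  for (col in c("start", "end")) {
    conv <- suppressWarnings(as.integer(x[[col]]))
    if (any(is.na(conv) & !is.na(x[[col]])))
      stop(path, ": field '", col, "' contains a non-integer value")
    x[[col]] <- conv
  }
  rownames(x) <- NULL
  x
}

#' Write alignments as the simplified 6-column TSV
#' @param x Alignment data frame (`chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `read_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(x, path) {
  utils::write.table(x[, .aln_cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# CIGAR -> reference-space blocks relative to pos0 (0-based leftmost)
.cigar_blocks <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0) stop("unparseable CIGAR: ", cigar)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  typ <- sub("^\\d+", "", ops)
  blocks <- list(); cur_start <- pos0; cur <- pos0
  for (i in seq_along(typ)) {
    if (typ[i] %in% c("M", "=", "X", "D")) {
      cur <- cur + lens[i]
    } else if (typ[i] == "N") {
      if (cur > cur_start) blocks[[length(blocks) + 1]] <- c(cur_start, cur)
      cur <- cur + lens[i]; cur_start <- cur
    }
    # I, S, H, P consume no reference
  }
  if (cur > cur_start) blocks[[length(blocks) + 1]] <- c(cur_start, cur)
  blocks
}

#' Read a plain-text SAM file (minimal subset)
#'
#' Parses only what downstream counting needs: reference name, 1-based
#' position (converted to 0-based), the reference span derived from the
#' CIGAR, and the strand from flag bit 0x10.  Spliced alignments (`N`
#' operations) contribute one row per aligned block, sharing `read_id`.
#' Unmapped records (flag 0x4 or `*` reference) are skipped.
#'
#' @param path SAM path.
#' @param sample_id Sample label attached to every read (default: file
#'   name without extension).
#' @return Alignment data frame as for [read_alignments_tsv()].
#' @export
read_sam <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[sS][aA][mM]$", "", basename(path))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  rows <- list()
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop(sprintf("%s: line %d: SAM record has %d fields, expected >= 6",
                   path, ln, length(f)))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag)) stop(sprintf("%s: line %d, field 'flag': not an integer ('%s')",
                                  path, ln, f[2]))
    if (is.na(pos)) stop(sprintf("%s: line %d, field 'pos': not an integer ('%s')",
                                 path, ln, f[4]))
    if (bitwAnd(flag, 4L) != 0L || f[3] == "*") next
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    for (b in .cigar_blocks(f[6], pos - 1L)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = f[3], start = b[1], end = b[2], strand = strand,
        sample_id = sample_id, read_id = f[1], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sample_id = character(),
                      read_id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write single-block alignments as plain-text SAM
#'
#' @param x Alignment data frame; each row becomes one record with CIGAR
#'   `<span>M`.
#' @param path Output path.
#' @param chrom_lengths Optional named vector for `@SQ` header lines
#'   (default: max end per chromosome).
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, chrom_lengths = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  chroms <- sort(unique(x$chrom))
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch) max(x$end[x$chrom == ch]), numeric(1))
  for (ch in chroms)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, as.integer(chrom_lengths[[ch]])), con)
  if (nrow(x) > 0) {
    flag <- ifelse(x$strand == "-", 16L, 0L)
    cigar <- paste0(x$end - x$start, "M")
    writeLines(paste(x$read_id, flag, x$chrom, x$start + 1L, 255L, cigar,
                     "*", 0L, 0L, "*", "*", sep = "\t"), con)
  }
  invisible(path)
}

# -- FASTA / FASTQ -----------------------------------------------------------

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTQ into a reads data frame
#'
#' @param path FASTQ path.
#' @return Data frame with `id`, `seq`, `qual` (Phred+33 encoded string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = if (is.null(names(x))) sprintf("read%d", seq_along(x)) else names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a reads data frame as FASTQ
#' @param reads Data frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# -- per-CpG methylation counts ----------------------------------------------

#' Read per-CpG methylation counts
#'
#' Tab-separated `chrom pos methylated_count unmethylated_count`
#' (0-based position of the C in each CpG); a header line is skipped.
#'
#' @param path TSV path.
#' @return Data frame with `chrom`, `pos`, `methylated`, `unmethylated`.
#' @export
read_cpg_table <- function(path) {
  x <- .parse_lines(path, c("chrom", "pos", "methylated", "unmethylated"),
                    c("c", "c", "c", "c"), min_fields = 4, sep_re = "\t")
  if (nrow(x) > 0 && x$chrom[1] == "chrom") x <- x[-1, , drop = FALSE]
  for (col in c("pos", "methylated", "unmethylated")) {
    conv <- suppressWarnings(as.integer(x[[col]]))
    if (any(is.na(conv) & !is.na(x[[col]])))
      stop(path, ": field '", col, "' contains a non-integer value")
    x[[col]] <- conv
  }
  rownames(x) <- NULL
  x
}

#' Write per-CpG methylation counts
#' @param x Data frame with `chrom`, `pos`, `methylated`, `unmethylated`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  utils::write.table(
    data.frame(chrom = x$chrom, pos = x$pos, methylated_count = x$methylated,
               unmethylated_count = x$unmethylated),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# -- gene model GTF / BED12 --------------------------------------------------

#' Write a gene model as GTF
#'
#' Emits one `gene` feature carrying the designated-exon attributes, one
#' `start_exon` feature per alternative first exon (with `exon_label`
#' and 1-based `tss` attributes) and one `promoter` feature.
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  at <- function(...) paste0(paste(sprintf('%s "%s";', names(c(...)), c(...)),
                                   collapse = " "))
  ex <- model$start_exons
  gene_attrs <- c(gene_id = model$gene_id)
  if (!is.null(model$cancer_exon)) gene_attrs <- c(gene_attrs, cancer_exon = model$cancer_exon)
  if (!is.null(model$muscle_exon)) gene_attrs <- c(gene_attrs, muscle_exon = model$muscle_exon)
  writeLines(paste(model$chrom, "promloop", "gene",
                   min(ex$start) + 1L, max(ex$end), ".", model$strand, ".",
                   at(gene_attrs), sep = "\t"), con)
  for (i in seq_len(nrow(ex))) {
    writeLines(paste(model$chrom, "promloop", "start_exon",
                     ex$start[i] + 1L, ex$end[i], ".", model$strand, ".",
                     at(c(gene_id = model$gene_id, exon_label = ex$name[i],
                          tss = as.character(ex$tss[i] + 1L))), sep = "\t"), con)
  }
  writeLines(paste(model$chrom, "promloop", "promoter",
                   model$promoter$start + 1L, model$promoter$end, ".",
                   model$strand, ".", at(c(gene_id = model$gene_id)),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a gene model from GTF
#'
#' Expects the layout written by [write_gene_model()] (features
#' `gene`, `start_exon`, `promoter`).  GTF 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention.
#'
#' @param path GTF path.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  m <- as.data.frame(g)
  typ <- as.character(m$type)
  exo <- m[typ == "start_exon", , drop = FALSE]
  if (nrow(exo) == 0) stop(path, ": no start_exon features found")
  prom <- m[typ == "promoter", , drop = FALSE]
  if (nrow(prom) != 1) stop(path, ": expected exactly one promoter feature")
  gene <- m[typ == "gene", , drop = FALSE]
  gene_model(
    gene_id = exo$gene_id[1],
    chrom = as.character(exo$seqnames[1]),
    strand = as.character(exo$strand[1]),
    start_exons = data.frame(name = exo$exon_label,
                             start = exo$start - 1L, end = exo$end,
                             tss = as.integer(exo$tss) - 1L,
                             stringsAsFactors = FALSE),
    promoter = genomic_intervals(as.character(prom$seqnames[1]),
                                 prom$start - 1L, prom$end),
    cancer_exon = if (nrow(gene) == 1 && !is.null(gene$cancer_exon) &&
                        !is.na(gene$cancer_exon)) gene$cancer_exon else NULL,
    muscle_exon = if (nrow(gene) == 1 && !is.null(gene$muscle_exon) &&
                        !is.na(gene$muscle_exon)) gene$muscle_exon else NULL)
}

#' Write a gene model as BED12
#'
#' One BED12 row: blocks are the start exons, thickStart/thickEnd hold
#' the promoter.  Exon labels and designated-exon roles are not
#' representable in BED12 and are regenerated on read.
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed12 <- function(model, path) {
  ex <- model$start_exons[order(model$start_exons$start), , drop = FALSE]
  cs <- min(ex$start); ce <- max(ex$end)
  line <- paste(model$chrom, cs, ce, model$gene_id, 0, model$strand,
                model$promoter$start, model$promoter$end, "0",
                nrow(ex), paste0(paste(ex$end - ex$start, collapse = ","), ","),
                paste0(paste(ex$start - cs, collapse = ","), ","), sep = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Read a gene model from BED12
#'
#' Start exons are the BED blocks, labelled `1u`...`Nu` in transcription
#' order (5' exon first on the gene strand); each exon's TSS is its
#' strand-oriented 5' base; the promoter is taken from
#' thickStart/thickEnd.
#'
#' @param path BED12 path.
#' @return A [gene_model()].
#' @export
read_gene_model_bed12 <- function(path) {
  x <- .parse_lines(path,
                    c("chrom", "start", "end", "name", "score", "strand",
                      "thickStart", "thickEnd", "rgb", "blockCount",
                      "blockSizes", "blockStarts"),
                    c("c", "i", "i", "c", "n", "c", "i", "i", "c", "i", "c", "c"),
                    min_fields = 12)
  if (nrow(x) != 1) stop(path, ": expected exactly one BED12 gene record")
  sizes <- as.integer(strsplit(sub(",$", "", x$blockSizes), ",")[[1]])
  offs <- as.integer(strsplit(sub(",$", "", x$blockStarts), ",")[[1]])
  if (length(sizes) != x$blockCount || length(offs) != x$blockCount)
    stop(path, ": blockCount disagrees with blockSizes/blockStarts")
  st <- x$start + offs; en <- st + sizes
  ord <- if (x$strand == "+") order(st) else order(-st)
  st <- st[ord]; en <- en[ord]
  tss <- if (x$strand == "+") st else en - 1L
  gene_model(gene_id = x$name, chrom = x$chrom, strand = x$strand,
             start_exons = data.frame(name = paste0(seq_along(st), "u"),
                                      start = st, end = en, tss = tss,
                                      stringsAsFactors = FALSE),
             promoter = genomic_intervals(x$chrom, x$thickStart, x$thickEnd))
}

# -- UCSC custom tracks ------------------------------------------------------

#' Write records as a UCSC custom track
#'
#' Intervals become a BED track; window counts (see [window_counts()])
#' become a bedGraph track (only non-zero windows are written).  Rows
#' are ordered by chromosome then start, so output is deterministic.
#'
#' @param records Interval data frame or a `window_counts` object.
#' @param track_name Track name for the header line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_custom_track <- function(records, track_name, path) {
  if (inherits(records, "window_counts")) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
    nz <- which(records$counts != 0)
    if (length(nz) > 0) {
      ws <- records$window_size
      writeLines(paste(records$chrom, (nz - 1L) * ws,
                       pmin(nz * ws, records$chrom_length),
                       records$counts[nz], sep = "\t"), con)
    }
    return(invisible(path))
  }
  if (is.data.frame(records)) {
    return(write_bed(records, path, track_name = track_name))
  }
  stop("records must be a single type: an interval data frame or window counts")
}

# -- dispatcher --------------------------------------------------------------

#' Parse a file of a named standard format
#'
#' Thin dispatcher over the typed readers.  `format` is one of
#' `"BED"`, `"BEDPE"`, `"GTF"`, `"BED12"`, `"SAM"`, `"TSV"` (simplified
#' alignments), `"FASTA"`, `"FASTQ"`, `"CpG-TSV"`, `"bedGraph"`.
#'
#' @param path Input path.
#' @param format Format name.
#' @return Typed records (see the individual readers).
#' @export
parse_records <- function(path, format) {
  switch(toupper(format),
         "BED" = read_bed(path),
         "BEDPE" = read_bedpe(path),
         "GTF" = read_gene_model(path),
         "BED12" = read_gene_model_bed12(path),
         "SAM" = read_sam(path),
         "TSV" = read_alignments_tsv(path),
         "FASTA" = read_fasta(path),
         "FASTQ" = read_fastq(path),
         "CPG-TSV" = read_cpg_table(path),
         "BEDGRAPH" = read_bedgraph(path),
         stop("unknown format: ", format))
}
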