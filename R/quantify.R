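# Start-exon-specific transcript quantification (RNA-Seq), TSS-proximal
# nascent-transcription quantification (GRO-Seq), and the condition
# fold-change statistics (one-way ANOVA + Tukey-Kramer).

#' Count reads per alternative start exon
#'
#' A read is counted for a start exon iff any of its aligned blocks
#' overlaps the exon interval by at least 1 bp.  A read overlapping k
#' start exons contributes 1 to each of the k counts; blocks of a
#' spliced read share a `read_id` and count once per exon.  Counting is
#' unstranded by default (set `stranded = TRUE` to require the read on
#' the gene strand).
#'
#' @param alignments Alignment data frame (`chrom`, `start`, `end`,
#'   `strand`, `sample_id`, `read_id`).
#' @param model A [gene_model()].
#' @param stranded Restrict to reads on the gene strand?
#' @return Named integer vector, one count per start exon.
#' @export
count_start_exon_reads <- function(alignments, model, stranded = FALSE) {
  ex <- model$start_exons
  counts <- stats::setNames(integer(nrow(ex)), ex$name)
  if (nrow(alignments) == 0) return(counts)
  a <- alignments[alignments$chrom == model$chrom, , drop = FALSE]
  if (stranded) a <- a[a$strand == model$strand, , drop = FALSE]
  if (nrow(a) == 0) return(counts)
  if (is.null(a$read_id)) a$read_id <- sprintf("r%d", seq_len(nrow(a)))
  for (i in seq_len(nrow(ex))) {
    hit <- a$start < ex$end[i] & ex$start[i] < a$end
    counts[i] <- length(unique(a$read_id[hit]))
  }
  counts
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `rpkm = count / (feature_length/1000) / (total_mapped_reads/1e6)`.
#'
#' @param count Raw read count(s).
#' @param feature_length Feature length in bp (> 0).
#' @param total_mapped_reads Genome-wide mapped reads of the dataset (> 0).
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(300, 600, 2e6)  # 250
#' @export
compute_rpkm <- function(count, feature_length, total_mapped_reads) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  count / (feature_length / 1000) / (total_mapped_reads / 1e6)
}

#' Per-sample, per-start-exon expression records from RNA-Seq alignments
#'
#' Counts reads per start exon for every sample in `meta` and converts
#' to RPKM using each sample's `total_mapped_reads`.
#'
#' @param alignments Alignment data frame covering all samples.
#' @param model A [gene_model()].
#' @param meta Sample sheet: `sample_id`, `condition`,
#'   `total_mapped_reads`.
#' @param stranded Passed to [count_start_exon_reads()].
#' @return Data frame with `sample_id`, `condition`, `unit_name`,
#'   `raw_count`, `feature_length`, `rpkm`.
#' @export
expression_records <- function(alignments, model, meta, stranded = FALSE) {
  ex <- model$start_exons
  out <- list()
  for (i in seq_len(nrow(meta))) {
    a <- alignments[alignments$sample_id == meta$sample_id[i], , drop = FALSE]
    cnt <- count_start_exon_reads(a, model, stranded = stranded)
    out[[i]] <- data.frame(
      sample_id = meta$sample_id[i], condition = meta$condition[i],
      unit_name = ex$name, raw_count = as.integer(cnt),
      feature_length = ex$end - ex$start,
      rpkm = compute_rpkm(cnt, ex$end - ex$start, meta$total_mapped_reads[i]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' TSS-proximal GRO-Seq quantification
#'
#' For each start exon's TSS, counts reads whose 5'-most aligned base
#' falls in the strand-oriented window covering 100 bp upstream through
#' 500 bp downstream of the TSS, and converts to RPKM with the feature
#' length fixed at the window size (600 bp, the fragment size).  GRO-Seq
#' is strand-specific nascent transcription, so only reads on the gene
#' strand are counted by default.
#'
#' @param alignments Alignment data frame covering all samples.
#' @param model A [gene_model()].
#' @param meta Sample sheet (`sample_id`, `condition`,
#'   `total_mapped_reads`).
#' @param upstream,downstream Window extent around the TSS in bp.
#' @param stranded Count only reads on the gene strand?
#' @param chrom_length Optional chromosome length; windows extending
#'   past the ends are clipped with a warning.
#' @return Expression record data frame as for [expression_records()].
#' @export
groseq_tss_rpkm <- function(alignments, model, meta, upstream = 100,
                            downstream = 500, stranded = TRUE,
                            chrom_length = NULL) {
  ex <- model$start_exons
  width <- upstream + downstream
  if (model$strand == "+") {
    ws <- ex$tss - upstream; we <- ex$tss + downstream
  } else {
    ws <- ex$tss - downstream + 1L; we <- ex$tss + upstream + 1L
  }
  if (any(ws < 0) || (!is.null(chrom_length) && any(we > chrom_length))) {
    warning("TSS window extends past chromosome bounds; clipped")
    ws <- pmax(ws, 0L)
    if (!is.null(chrom_length)) we <- pmin(we, chrom_length)
  }
  a <- alignments[alignments$chrom == model$chrom, , drop = FALSE]
  if (stranded) a <- a[a$strand == model$strand, , drop = FALSE]
  pos5 <- ifelse(a$strand == "-", a$end - 1L, a$start)
  out <- list()
  for (i in seq_len(nrow(meta))) {
    in_sample <- a$sample_id == meta$sample_id[i]
    cnt <- vapply(seq_len(nrow(ex)), function(j) {
      sum(in_sample & pos5 >= ws[j] & pos5 < we[j])
    }, numeric(1))
    out[[i]] <- data.frame(
      sample_id = meta$sample_id[i], condition = meta$condition[i],
      unit_name = ex$name, raw_count = as.integer(cnt),
      feature_length = width,
      rpkm = compute_rpkm(cnt, width, meta$total_mapped_reads[i]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups List of two or more numeric vectors, each with at least
#'   two finite values.
#' @return List with elements `F` and `p` (upper-tail).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least two values")
  v <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(v))) stop("values must be finite")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  Fv <- unname(ft$statistic); p <- unname(ft$p.value)
  if (is.nan(Fv)) {  # zero within- and between-group variance
    Fv <- 0; p <- 1
  }
  list(F = Fv, p = p)
}

#' Tukey-Kramer pairwise comparisons
#'
#' For each pair of groups computes the studentized-range statistic
#' `q = |mi - mj| / sqrt(MSW/2 * (1/ni + 1/nj))` (the Kramer standard
#' error accommodates unequal group sizes) and compares it with the
#' studentized-range distribution at (k groups, N-k df), controlling the
#' family-wise error at `alpha`.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param alpha Family-wise error rate.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `diff`, `q`, `p_adj`, `significant`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least two values")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  N <- sum(ni)
  msw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / (N - k)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- if (se == 0) { if (mi[i] == mi[j]) 0 else Inf } else abs(mi[i] - mi[j]) / se
    p <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      group_a = nm[i], group_b = nm[j], diff = mi[i] - mi[j],
      q = q, p_adj = p, significant = p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition fold changes per start exon
#'
#' For each quantified unit computes `fold = mean(rpkm | condition_a) /
#' mean(rpkm | condition_b)` (treated over control), attaches a one-way
#' ANOVA across all conditions present in `records`, and Tukey-Kramer
#' pairwise significance when three or more conditions are present or
#' the ANOVA is significant.  When the control mean is zero the fold
#' change is reported as `NA` with `fold_defined = FALSE` (no division).
#'
#' @param records Expression records (see [expression_records()]).
#' @param condition_a Treated condition label.
#' @param condition_b Control condition label.
#' @param alpha Significance level for the ANOVA / post-hoc flags.
#' @return Data frame with one row per unit: means, `fold_change`,
#'   `fold_defined`, `anova_F`, `anova_p`, `tukey_significant` (is the
#'   a-vs-b pair flagged?).  Full pairwise tables are attached as
#'   attribute `"tukey"` (a named list).
#' @export
condition_fold_changes <- function(records, condition_a, condition_b,
                                   alpha = 0.05) {
  units <- unique(records$unit_name)
  tuk_all <- list()
  rows <- list()
  for (u in units) {
    r <- records[records$unit_name == u, , drop = FALSE]
    conds <- unique(r$condition)
    groups <- lapply(conds, function(cc) r$rpkm[r$condition == cc])
    names(groups) <- conds
    an <- if (length(groups) >= 2 && all(lengths(groups) >= 2))
      one_way_anova(groups) else list(F = NA_real_, p = NA_real_)
    tk <- NULL
    if (length(groups) >= 2 && all(lengths(groups) >= 2) &&
        (length(groups) >= 3 || (!is.na(an$p) && an$p < alpha)))
      tk <- tukey_kramer(groups, alpha = alpha)
    tuk_all[[u]] <- tk
    ma <- mean(r$rpkm[r$condition == condition_a])
    mb <- mean(r$rpkm[r$condition == condition_b])
    defined <- is.finite(mb) && mb > 0
    pair_sig <- NA
    if (!is.null(tk)) {
      hit <- (tk$group_a == condition_a & tk$group_b == condition_b) |
        (tk$group_a == condition_b & tk$group_b == condition_a)
      if (any(hit)) pair_sig <- tk$significant[hit][1]
    }
    rows[[u]] <- data.frame(
      unit_name = u, condition_a = condition_a, condition_b = condition_b,
      mean_rpkm_a = ma, mean_rpkm_b = mb,
      fold_change = if (defined) ma / mb else NA_real_,
      fold_defined = defined,
      pct_of_control = if (defined) 100 * ma / mb else NA_real_,
      anova_F = an$F, anova_p = an$p, tukey_significant = pair_sig,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tukey") <- tuk_all
  out
}
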