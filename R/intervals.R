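# Genomic intervals are plain data frames with columns chrom, start, end and
# optionally strand / name.  Coordinates are 0-based half-open [start, end),
# the BED convention; 1-based formats (GTF, SAM) are converted at the
# reader/writer boundary and nowhere else.  Chromosome names are compared by
# exact string equality (no "chr" normalisation).

#' Construct a set of genomic intervals
#'
#' Builds the data frame representation used throughout the package:
#' 0-based half-open coordinates, one row per interval.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions (`end > start`).
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @param name Optional interval labels.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`
#'   and (if given) `name`.
#' @examples
#' genomic_intervals("chrS", c(100, 400), c(200, 450))
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NULL) {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = rep_len(as.integer(start), n),
                  end = rep_len(as.integer(end), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- rep_len(as.character(name), n)
  assert_intervals(x)
  x
}

#' Validate an interval data frame
#'
#' Checks the invariants every interval set must satisfy: non-empty
#' chromosome names, `start >= 0`, `end > start`, and a valid strand
#' column when present.
#'
#' @param x A data frame of intervals.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
assert_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("interval data frame lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) stop("interval end must be > start")
  if ("strand" %in% names(x) && any(!x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they are on the same chromosome and their
#' half-open ranges intersect by at least one base:
#' `a$start < b$end && b$start < a$end`.  Vectorised elementwise over the
#' rows of `a` and `b` (length-1 inputs recycle).
#'
#' @param a,b Interval data frames (see [genomic_intervals()]).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 150, 250)
#' overlaps(a, b)
#' @export
overlaps <- function(a, b) {
  assert_intervals(a); assert_intervals(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# For each row of `query`, TRUE iff it overlaps any row of `subject`.
#' Overlap of each query interval with any subject interval
#'
#' @param query,subject Interval data frames.
#' @return Logical vector, one entry per row of `query`.
#' @export
overlaps_any <- function(query, subject) {
  assert_intervals(query); assert_intervals(subject)
  if (nrow(subject) == 0 || nrow(query) == 0) return(rep(FALSE, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          query$start[i] < subject$end)
  }, logical(1))
}

#' Merge intervals, bridging small gaps
#'
#' Returns the minimal set of disjoint intervals covering the input,
#' joining intervals separated by at most `gap` bases.  Output is sorted
#' by chromosome then start.  Strand and names are dropped (the merge is
#' strand-blind, as for candidate-region definition).
#'
#' @param x Interval data frame.
#' @param gap Maximum gap (bp) bridged when joining; `gap = 0` joins only
#'   touching or overlapping intervals.
#' @return Interval data frame with columns `chrom`, `start`, `end`.
#' @examples
#' merge_intervals(genomic_intervals("chrS", c(0, 15), c(10, 20)), gap = 5)
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(gap >= 0)
  assert_intervals(x)
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  parts <- lapply(split(x, x$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                         min.gapwidth = as.integer(gap) + 1L)
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# distance between two intervals on the same chromosome: 0 when they
# overlap or touch, else the number of intervening bases
interval_distance <- function(a, b) {
  ifelse(a$chrom != b$chrom, NA_integer_,
         pmax(0L, pmax(a$start, b$start) - pmin(a$end, b$end)))
}
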