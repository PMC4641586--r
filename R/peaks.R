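# Window-based ChIP-Seq peak calling with an automatically derived
# Poisson minimum-read threshold, optional input-control correction, and
# replicate-based differential enrichment via a negative-binomial exact
# test.

#' Tile a chromosome and count read 5' ends per window
#'
#' Non-overlapping windows of `window_size` bp starting at 0; each read
#' is assigned to exactly one window by its 5'-most aligned base (the
#' start for + reads, `end - 1` for - reads).
#'
#' @param alignments Alignment data frame.
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window size in bp (default 50).
#' @param chrom Chromosome to count (default: the single chromosome
#'   present).
#' @return A `window_counts` object: list with `chrom`, `window_size`,
#'   `counts` (one integer per window), `chrom_length`.
#' @export
window_counts <- function(alignments, chrom_length, window_size = 50,
                          chrom = NULL) {
  stopifnot(window_size >= 1)
  if (is.null(chrom)) {
    chrom <- unique(alignments$chrom)
    if (length(chrom) == 0) chrom <- "chrS"
    if (length(chrom) > 1)
      stop("alignments span several chromosomes; give `chrom` explicitly")
  }
  a <- alignments[alignments$chrom == chrom, , drop = FALSE]
  n_win <- as.integer(ceiling(chrom_length / window_size))
  pos5 <- ifelse(a$strand == "-", a$end - 1L, a$start)
  pos5 <- pos5[pos5 >= 0 & pos5 < chrom_length]
  cnt <- tabulate(pos5 %/% window_size + 1L, nbins = n_win)
  structure(list(chrom = chrom, window_size = as.integer(window_size),
                 counts = as.integer(cnt),
                 chrom_length = as.integer(chrom_length)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %s, %d windows of %d bp, %d reads\n",
              x$chrom, length(x$counts), x$window_size, sum(x$counts)))
  invisible(x)
}

# build a window_counts object from a raw count vector (used by
# simulations and tests)
as_window_counts <- function(counts, chrom = "chrS", window_size = 50,
                             chrom_length = length(counts) * window_size) {
  structure(list(chrom = chrom, window_size = as.integer(window_size),
                 counts = as.integer(counts),
                 chrom_length = as.integer(chrom_length)),
            class = "window_counts")
}

#' Minimum reads per window under a Poisson background
#'
#' The smallest integer k such that the Poisson upper tail
#' `P(X >= k | lambda)` does not exceed `alpha / n_windows`
#' (Bonferroni correction across windows).  This formalises an
#' "automatically calculated" minimum-read threshold.
#'
#' @param background_rate Mean background reads per window (> 0).
#' @param n_windows Number of windows tested.
#' @param alpha Family-wise error rate.
#' @return Integer threshold k.
#' @examples
#' poisson_min_reads(1.0, 20000)  # 9
#' @export
poisson_min_reads <- function(background_rate, n_windows, alpha = 0.05) {
  stopifnot(background_rate > 0, n_windows >= 1)
  cut <- alpha / n_windows
  k <- stats::qpois(cut, background_rate, lower.tail = FALSE) + 1L
  # guard against quantile edge cases: enforce the defining inequality
  while (k > 1 && stats::ppois(k - 2, background_rate, lower.tail = FALSE) <= cut)
    k <- k - 1L
  while (stats::ppois(k - 1, background_rate, lower.tail = FALSE) > cut)
    k <- k + 1L
  as.integer(k)
}

#' Call enriched windows and merge them into peaks
#'
#' The per-window background mean is the global treatment mean when no
#' input control is given; with an input, it is the input's running
#' local mean (over `2 * local_halfwidth + 1` windows) scaled to the
#' treatment library size, floored at the scaled global input mean.
#' A window is significant when its count reaches
#' [poisson_min_reads()] for its background mean; adjacent significant
#' windows merge into one peak whose `read_count` is the sum and whose
#' `p_value` is the smallest member-window Poisson upper tail.
#'
#' @param treatment `window_counts` for the treatment sample.
#' @param input Optional `window_counts` for the input control (same
#'   grid).
#' @param alpha Family-wise error rate for the threshold.
#' @param local_halfwidth Half-width (in windows) of the input local
#'   mean.
#' @return Data frame of peaks: `chrom`, `start`, `end`, `read_count`,
#'   `expected`, `p_value`, `fold_over_input`.
#' @export
call_peaks <- function(treatment, input = NULL, alpha = 0.05,
                       local_halfwidth = 10) {
  stopifnot(inherits(treatment, "window_counts"))
  tc <- treatment$counts
  n <- length(tc)
  if (!is.null(input)) {
    stopifnot(inherits(input, "window_counts"))
    if (input$window_size != treatment$window_size ||
        length(input$counts) != n || input$chrom != treatment$chrom)
      stop("treatment and input window grids do not match")
    scale <- sum(tc) / max(sum(input$counts), 1)
    k2 <- 2 * local_halfwidth + 1
    kern <- rep(1 / k2, k2)
    local <- as.numeric(stats::filter(input$counts, kern, sides = 2))
    # edges: shrink to available windows
    na <- which(is.na(local))
    for (i in na) {
      lo <- max(1, i - local_halfwidth); hi <- min(n, i + local_halfwidth)
      local[i] <- mean(input$counts[lo:hi])
    }
    lambda <- pmax(local * scale, mean(input$counts) * scale)
  } else {
    lambda <- rep(max(mean(tc), 1e-9), n)
  }
  uk <- vapply(unique(lambda), function(l) poisson_min_reads(l, n, alpha),
               integer(1))
  kvec <- uk[match(lambda, unique(lambda))]
  sig <- tc >= kvec
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      read_count = integer(), expected = numeric(),
                      p_value = numeric(), fold_over_input = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(sig)) return(empty)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  ws <- treatment$window_size
  pw <- stats::ppois(tc - 1, lambda, lower.tail = FALSE)
  rows <- lapply(runs, function(i) {
    w <- starts[i]:ends[i]
    data.frame(chrom = treatment$chrom,
               start = (w[1] - 1L) * ws,
               end = min(w[length(w)] * ws, treatment$chrom_length),
               read_count = sum(tc[w]),
               expected = sum(lambda[w]),
               p_value = max(min(pw[w]), .Machine$double.xmin),
               fold_over_input = if (is.null(input)) NA_real_ else
                 sum(tc[w]) / sum(lambda[w]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Conditional two-sided exact test for a two-group count comparison.
# ya, yb: pooled (library-size normalised, rounded) counts; na, nb:
# numbers of replicates; phi: common NB dispersion (variance m + phi*m^2;
# phi = 0 degenerates to the Poisson / conditional-binomial case).
nb_exact_test <- function(ya, yb, na = 1, nb = 1, phi = 0) {
  n <- ya + yb
  if (n == 0) return(1)
  y <- 0:n
  if (phi <= 0) {
    w <- stats::dbinom(y, n, na / (na + nb))
  } else {
    mu_a <- n * na / (na + nb); mu_b <- n * nb / (na + nb)
    w <- stats::dnbinom(y, size = na / phi, mu = mu_a) *
      stats::dnbinom(n - y, size = nb / phi, mu = mu_b)
    w <- w / sum(w)
  }
  sum(w[w <= w[ya + 1] * (1 + 1e-10)])
}

#' Differential enrichment between two conditions
#'
#' Counts are scaled to a common library size; the log2 fold change uses
#' the normalised means (a 0.5 pseudocount per side is added only when a
#' mean is zero, to avoid infinities).  The p-value comes from an exact
#' conditional test on the pooled normalised counts under a
#' negative-binomial model with one common dispersion estimated across
#' regions by the method of moments (zero dispersion reduces to the
#' exact Poisson / conditional-binomial test).  Regions are classified
#' `enriched` iff `log2FC >= lfc` and `p < alpha`, `depleted` iff
#' `log2FC <= -lfc` and `p < alpha`, else `unchanged`.
#'
#' @param regions Interval data frame, one row per tested region.
#' @param counts_a,counts_b Matrices (regions x replicates) of raw
#'   counts for the two conditions; vectors are treated as one
#'   replicate.
#' @param lib_sizes List with numeric vectors `a` and `b` of per-replicate
#'   library sizes.
#' @param alpha Significance level.
#' @param lfc Absolute log2-fold-change threshold (default 1).
#' @param dispersion Common NB dispersion; `NULL` (default) estimates it
#'   from the data.
#' @return Data frame: region coordinates, per-side normalised means,
#'   `log2_fold_change`, `p_value`, `class`.
#' @export
differential_regions <- function(regions, counts_a, counts_b, lib_sizes,
                                 alpha = 0.05, lfc = 1, dispersion = NULL) {
  ca <- as.matrix(counts_a); cb <- as.matrix(counts_b)
  stopifnot(nrow(ca) == nrow(regions), nrow(cb) == nrow(regions))
  la <- lib_sizes$a; lb <- lib_sizes$b
  stopifnot(length(la) == ncol(ca), length(lb) == ncol(cb),
            all(la > 0), all(lb > 0))
  ref <- mean(c(la, lb))
  na <- sweep(ca, 2, ref / la, `*`)
  nb <- sweep(cb, 2, ref / lb, `*`)
  if (is.null(dispersion)) {
    mom <- function(m) {
      if (ncol(m) < 2) return(numeric(0))
      mu <- rowMeans(m); v <- apply(m, 1, stats::var)
      ok <- mu > 0
      ((v - mu) / mu^2)[ok]
    }
    ests <- c(mom(na), mom(nb))
    dispersion <- if (length(ests) > 0) max(0, mean(ests)) else 0
  }
  mean_a <- rowMeans(na); mean_b <- rowMeans(nb)
  ps_a <- ifelse(pmin(mean_a, mean_b) == 0, 0.5, 0)
  l2fc <- log2((mean_a + ps_a) / (mean_b + ps_a))
  l2fc[mean_a == 0 & mean_b == 0] <- 0
  pv <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ya <- round(sum(na[i, ])); yb <- round(sum(nb[i, ]))
    pv[i] <- if (ya + yb == 0) 1 else
      nb_exact_test(ya, yb, ncol(na), ncol(nb), dispersion)
  }
  cls <- ifelse(pv < alpha & l2fc >= lfc, "enriched",
                ifelse(pv < alpha & l2fc <= -lfc, "depleted", "unchanged"))
  cls[mean_a == 0 & mean_b == 0] <- "unchanged"
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, mean_norm_a = mean_a,
                    mean_norm_b = mean_b, log2_fold_change = l2fc,
                    p_value = pv, class = cls, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  out
}
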