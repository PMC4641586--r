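# Independent brute-force oracles and fixture builders.  These stay
# deliberately naive: per-base unions, all-position matchers, explicit
# enumeration — slow but obviously correct on small instances.

# per-base union with gap bridging, one chromosome at a time
bf_merge <- function(x, gap = 0) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    d <- x[x$chrom == ch, , drop = FALSE]
    covered <- rep(FALSE, max(d$end) + gap + 2)
    for (i in seq_len(nrow(d))) covered[(d$start[i] + 1):d$end[i]] <- TRUE
    # bridge gaps of <= gap uncovered bases between covered runs
    r <- rle(covered)
    pos <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1 && j < length(r$values) &&
          r$lengths[j] <= gap)
        covered[(pos[j] - r$lengths[j] + 1):pos[j]] <- TRUE
    }
    r <- rle(covered)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) > 0)
      out[[ch]] <- data.frame(chrom = ch, start = lo[keep] - 1L,
                              end = hi[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all-position IUPAC matcher with its own code table
bf_scan <- function(sequence, motifs) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s <- strsplit(toupper(sequence), "")[[1]]
  revcomp <- function(b) rev(unname(comp[b]))
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- strsplit(toupper(motifs$consensus[i]), "")[[1]]
    w <- length(pat)
    strands <- if (isTRUE(motifs$both_strands[i])) c("+", "-") else "+"
    for (p in seq_len(max(0, length(s) - w + 1))) {
      win <- s[p:(p + w - 1)]
      for (st in strands) {
        q <- if (st == "+") win else revcomp(win)
        if (all(mapply(function(b, cd) b %in% codes[[cd]], q, pat)))
          hits[[length(hits) + 1]] <- data.frame(
            motif = motifs$name[i], position = p - 1L, strand = st,
            matched_sequence = paste(win, collapse = ""),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(motif = character(), position = integer(),
                      strand = character(), matched_sequence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$position, out$motif, out$strand), , drop = FALSE]
}

# two-sided conditional binomial exact p (Poisson null, equal rates
# weighted by replicate numbers)
bf_cond_binom_p <- function(ya, yb, na = 1, nb = 1) {
  n <- ya + yb
  w <- dbinom(0:n, n, na / (na + nb))
  sum(w[w <= w[ya + 1] * (1 + 1e-10)])
}

# random interval set on one or two chromosomes, coordinates <= span
rand_intervals <- function(n, span = 5000, chroms = "chrS") {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(200, n, replace = TRUE)
  genomic_intervals(ch, st, st + w)
}

# uniform-quality reads data frame
make_reads <- function(seqs, q = 38) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs), function(n) {
               intToUtf8(rep(33L + q, n))
             }, character(1)), stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
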