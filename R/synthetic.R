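# Synthetic-data generators with planted ground truth.  Every generator
# is a pure function of (parameters, seed): it saves and restores the
# global RNG state, so identical calls give identical output and nothing
# leaks into the caller's randomness.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the caller's RNG
#' state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# NB draw under the mean/dispersion parameterisation used throughout:
# variance = m + phi * m^2; phi = 0 degenerates smoothly to Poisson(m).
rnbinom_disp <- function(n, mean, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = 1 / dispersion, mu = mean)
}

#' Generate a toy multi-start-exon gene on a synthetic chromosome
#'
#' Places `n_start_exons` non-identical start exons (80-300 bp) labelled
#' `1u`...`Nu` on one chromosome, designates a cancer-promoter exon (the
#' `5u` analogue: `"5u"` when it exists, else the middle exon) and a
#' muscle exon (the `9u` analogue: `"9u"` when it exists, else the last
#' exon), sets the promoter to 179 bp upstream through 25 bp downstream
#' of the cancer exon's first base, and draws a uniform-random A/C/G/T
#' genome sequence.
#'
#' @param genome_length Chromosome length in bp; must be at least 10x
#'   the gene span.
#' @param n_start_exons Number of alternative start exons (>= 3).
#' @param seed Mandatory RNG seed.
#' @param chrom Chromosome name (default `"chrS"`; use `"chr22"` for
#'   chromosome-filter scenarios).
#' @param gene_offset Fraction of the chromosome before the gene starts.
#' @return List with `model` (a [gene_model()]) and `sequence`
#'   (character scalar).
#' @export
make_toy_gene_model <- function(genome_length = 1e6, n_start_exons = 7, seed,
                                chrom = "chrS", gene_offset = 0.3) {
  stopifnot(n_start_exons >= 3)
  with_seed(seed, {
    lens <- sample(80:300, n_start_exons, replace = TRUE)
    gaps <- sample(500:3000, n_start_exons - 1, replace = TRUE)
    span <- sum(lens) + sum(gaps)
    if (genome_length < 10 * span)
      stop("genome too short: need at least 10x the gene span (",
           10 * span, " bp)")
    g0 <- round(genome_length * gene_offset)
    starts <- g0 + cumsum(c(0, lens[-n_start_exons] + gaps))
    ends <- starts + lens
    names <- paste0(seq_len(n_start_exons), "u")
    cancer <- if (n_start_exons >= 5) "5u" else
      names[ceiling(n_start_exons / 2)]
    muscle <- if (n_start_exons >= 9) "9u" else names[n_start_exons]
    exons <- data.frame(name = names, start = starts, end = ends,
                        tss = starts, stringsAsFactors = FALSE)
    ctss <- exons$tss[exons$name == cancer]
    model <- gene_model(
      gene_id = "MBtoy", chrom = chrom, strand = "+", start_exons = exons,
      promoter = promoter_interval(chrom, ctss, "+"),
      cancer_exon = cancer, muscle_exon = muscle)
    sequence <- paste(sample(c("A", "C", "G", "T"), genome_length,
                             replace = TRUE), collapse = "")
    list(model = model, sequence = sequence)
  })
}

#' Simulate start-exon RNA-Seq alignments with planted abundances
#'
#' Per replicate sample, draws a negative-binomial count for every start
#' exon (mean from `abundance[[condition]][exon]`, shared `dispersion`,
#' variance `m + dispersion * m^2`), places that many reads uniformly
#' within the exon on the gene strand, and adds Poisson background reads
#' genome-wide so that each sample's `total_mapped_reads` dominates the
#' gene signal (the RPKM denominator is genome-wide).
#'
#' @param model A [gene_model()].
#' @param meta Sample sheet: `sample_id`, `condition`.
#' @param abundance Named list: condition -> named vector of mean counts
#'   per start exon.
#' @param dispersion Shared NB dispersion (>= 0).
#' @param read_length Read length in bp (must not exceed the shortest
#'   exon).
#' @param background_mean Mean number of genome-wide background reads
#'   per sample.
#' @param genome_length Chromosome length for background placement.
#' @param seed Mandatory RNG seed.
#' @return List with `alignments` (data frame), `meta` (with
#'   `total_mapped_reads` filled in) and `truth` (planted expected
#'   counts).
#' @export
simulate_variant_reads <- function(model, meta, abundance, dispersion = 0.05,
                                   read_length = 50, background_mean = 5e4,
                                   genome_length = 1e6, seed) {
  stopifnot(dispersion >= 0)
  ex <- model$start_exons
  if (any(read_length > ex$end - ex$start))
    stop("read_length exceeds the length of exon(s): ",
         paste(ex$name[read_length > ex$end - ex$start], collapse = ", "))
  with_seed(seed, {
    aln <- list(); totals <- integer(nrow(meta))
    truth_counts <- list()
    for (i in seq_len(nrow(meta))) {
      cond <- meta$condition[i]
      means <- abundance[[cond]]
      if (is.null(means)) stop("no abundance for condition '", cond, "'")
      means <- means[ex$name]
      means[is.na(means)] <- 0
      cnt <- vapply(means, function(m)
        if (m <= 0) 0L else as.integer(rnbinom_disp(1, m, dispersion)),
        integer(1))
      starts <- integer(0); ids <- character(0)
      for (j in seq_len(nrow(ex))) {
        if (cnt[j] == 0) next
        s <- ex$start[j] +
          sample.int(ex$end[j] - ex$start[j] - read_length + 1L, cnt[j],
                     replace = TRUE) - 1L
        starts <- c(starts, s)
        ids <- c(ids, sprintf("%s_%s_%d", meta$sample_id[i], ex$name[j],
                              seq_len(cnt[j])))
      }
      n_bg <- stats::rpois(1, background_mean)
      if (n_bg > 0) {
        bs <- sample.int(genome_length - read_length, n_bg, replace = TRUE) - 1L
        starts <- c(starts, bs)
        ids <- c(ids, sprintf("%s_bg_%d", meta$sample_id[i], seq_len(n_bg)))
      }
      n <- length(starts)
      totals[i] <- n
      if (n > 0)
        aln[[i]] <- data.frame(chrom = model$chrom, start = starts,
                               end = starts + read_length,
                               strand = model$strand,
                               sample_id = meta$sample_id[i], read_id = ids,
                               stringsAsFactors = FALSE)
      truth_counts[[meta$sample_id[i]]] <- cnt
    }
    meta$total_mapped_reads <- totals
    alignments <- if (length(aln) > 0) do.call(rbind, aln) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), sample_id = character(),
                 read_id = character(), stringsAsFactors = FALSE)
    rownames(alignments) <- NULL
    list(alignments = alignments, meta = meta,
         truth = list(abundance = abundance, dispersion = dispersion,
                      sampled_counts = truth_counts))
  })
}

#' Simulate a ChIP experiment with planted enriched windows
#'
#' The input control is homogeneous Poisson at `input_rate` reads per
#' window; the treatment is Poisson at `background_rate`, multiplied by
#' each planted peak's enrichment factor inside the peak.  Reads are
#' placed uniformly within their window.
#'
#' @param genome_length Chromosome length (bp).
#' @param background_rate Treatment background reads per window (> 0).
#' @param peaks Data frame `start`, `end`, `enrichment` (factors > 1);
#'   may have zero rows.
#' @param input_rate Input reads per window (default: equal to
#'   `background_rate`).
#' @param window_size Window size in bp.
#' @param read_length Read length in bp.
#' @param seed Mandatory RNG seed.
#' @param chrom Chromosome name.
#' @return List with `treatment`, `input` (alignment data frames) and
#'   `truth` (the planted peaks).
#' @export
simulate_chip_experiment <- function(genome_length, background_rate = 2,
                                     peaks = NULL, input_rate = background_rate,
                                     window_size = 50, read_length = 36, seed,
                                     chrom = "chrS") {
  stopifnot(background_rate > 0)
  if (is.null(peaks))
    peaks <- data.frame(start = integer(), end = integer(),
                        enrichment = numeric())
  if (nrow(peaks) > 0) {
    if (any(peaks$enrichment <= 1)) stop("enrichment factors must be > 1")
    if (any(peaks$start < 0 | peaks$end > genome_length))
      stop("planted peak outside the genome")
  }
  n_win <- as.integer(ceiling(genome_length / window_size))
  rate <- rep(background_rate, n_win)
  for (i in seq_len(nrow(peaks))) {
    w <- (peaks$start[i] %/% window_size + 1L):((peaks$end[i] - 1L) %/% window_size + 1L)
    rate[w] <- background_rate * peaks$enrichment[i]
  }
  draw <- function(lambda, label) {
    cnt <- stats::rpois(n_win, lambda)
    tot <- sum(cnt)
    if (tot == 0)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        sample_id = character(), read_id = character(),
                        stringsAsFactors = FALSE))
    win <- rep(seq_len(n_win) - 1L, cnt)
    offs <- sample.int(window_size, tot, replace = TRUE) - 1L
    starts <- pmin(win * window_size + offs, genome_length - read_length)
    data.frame(chrom = chrom, start = starts, end = starts + read_length,
               strand = sample(c("+", "-"), tot, replace = TRUE),
               sample_id = label, read_id = sprintf("%s_%d", label, seq_len(tot)),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    treatment <- draw(rate, "treatment")
    input <- draw(rep(input_rate, n_win), "input")
    list(treatment = treatment, input = input,
         truth = list(peaks = peaks, background_rate = background_rate,
                      window_size = window_size,
                      genome_length = genome_length))
  })
}

#' Simulate promoter-anchored ChIA-PET pairs plus noise
#'
#' True pairs get one anchor overlapping the promoter and one inside a
#' distal region (anchor widths 100-500 bp, jittered placement); noise
#' pairs get both anchors uniform on the genome.  The truth flag is
#' carried in the `is_true` column and in the returned truth list.
#'
#' @param promoter One-row interval data frame.
#' @param distal_regions Interval data frame of true interacting
#'   regions (disjoint from the promoter).
#' @param n_true_per_region True pairs per distal region.
#' @param n_noise Number of noise pairs.
#' @param genome_length Chromosome length for noise placement.
#' @param seed Mandatory RNG seed.
#' @param factor,dataset_id Labels stored on every pair.
#' @return List with `pets` (pair data frame with `is_true`) and
#'   `truth` (the distal regions).
#' @export
simulate_pets <- function(promoter, distal_regions, n_true_per_region = 3,
                          n_noise = 20, genome_length = 1e6, seed,
                          factor = "PolII", dataset_id = "sim") {
  assert_intervals(promoter); assert_intervals(distal_regions)
  if (any(overlaps_any(distal_regions, promoter)))
    stop("distal regions must be disjoint from the promoter")
  with_seed(seed, {
    rows <- list()
    anchor_in <- function(iv) {
      w <- min(sample(100:500, 1), iv$end - iv$start)  # contained anchor
      s <- iv$start + sample.int(iv$end - iv$start - w + 1L, 1) - 1L
      c(s, s + w)
    }
    for (i in seq_len(nrow(distal_regions))) {
      for (j in seq_len(n_true_per_region)) {
        a <- anchor_in(promoter[1, ])
        b <- anchor_in(distal_regions[i, ])
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = promoter$chrom, start1 = a[1], end1 = a[2],
          chrom2 = distal_regions$chrom[i], start2 = b[1], end2 = b[2],
          pet_count = sample(1:5, 1), factor = factor,
          dataset_id = dataset_id, is_true = TRUE, stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(n_noise)) {
      w1 <- sample(100:500, 1); w2 <- sample(100:500, 1)
      s1 <- sample.int(genome_length - w1, 1) - 1L
      s2 <- sample.int(genome_length - w2, 1) - 1L
      rows[[length(rows) + 1]] <- data.frame(
        chrom1 = promoter$chrom, start1 = s1, end1 = s1 + w1,
        chrom2 = promoter$chrom, start2 = s2, end2 = s2 + w2,
        pet_count = sample(1:3, 1), factor = factor,
        dataset_id = dataset_id, is_true = FALSE, stringsAsFactors = FALSE)
    }
    pets <- do.call(rbind, rows)
    rownames(pets) <- NULL
    list(pets = pets, truth = list(distal_regions = distal_regions,
                                   n_true = nrow(distal_regions) * n_true_per_region,
                                   n_noise = n_noise))
  })
}

#' Plant concrete motif instances into a sequence
#'
#' Overwrites the sequence at each instance position with a concrete
#' realisation of the IUPAC consensus (ambiguity codes resolved
#' uniformly at random under the seed); minus-strand instances are
#' written as the reverse complement of the realisation, so scanning
#' recovers them on the minus strand.
#'
#' @param sequence Character scalar.
#' @param instances Data frame `name`, `consensus`, `position` (0-based),
#'   `strand`; instances must lie within the sequence and not overlap.
#' @param seed Mandatory RNG seed.
#' @return The modified sequence.
#' @export
plant_motifs <- function(sequence, instances, seed) {
  if (nrow(instances) == 0) return(sequence)
  len <- nchar(instances$consensus)
  if (any(instances$position < 0 |
            instances$position + len > nchar(sequence)))
    stop("motif instance outside the sequence")
  ord <- order(instances$position)
  pos <- instances$position[ord]; l <- len[ord]
  if (any(pos[-1] < (pos + l)[-length(pos)]))
    stop("overlapping motif instances")
  with_seed(seed, {
    for (i in seq_len(nrow(instances))) {
      cons <- .check_consensus(instances$consensus[i])
      bases <- vapply(strsplit(cons, "")[[1]], function(code) {
        opts <- strsplit(.IUPAC[[code]], "")[[1]]
        if (length(opts) == 1) opts else sample(opts, 1)
      }, character(1))
      real <- paste(bases, collapse = "")
      if (instances$strand[i] == "-")
        real <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(real)))
      substr(sequence, instances$position[i] + 1L,
             instances$position[i] + nchar(real)) <- real
    }
    sequence
  })
}

#' Simulate per-CpG bisulfite counts with imperfect conversion
#'
#' Per CpG, the site survives dropout with probability `1 - dropout`
#' (emulating uneven sequencing depth), coverage is Poisson(`coverage`),
#' and each read reports the planted state with probability
#' `conversion_rate` (so unmethylated sites show spurious methylated
#' reads at rate `1 - conversion_rate`, and vice versa).
#'
#' @param cpg_positions Integer vector of CpG positions (0-based C).
#' @param states Character vector (`"methylated"`/`"unmethylated"`),
#'   recycled along positions.
#' @param coverage Mean read coverage.
#' @param conversion_rate Bisulfite conversion probability (0 < c <= 1).
#' @param dropout Probability a site yields no data.
#' @param seed Mandatory RNG seed.
#' @param chrom Chromosome name.
#' @return List with `records` (CpG count data frame) and `truth`
#'   (position -> planted state, dropout flags).
#' @export
simulate_methylation <- function(cpg_positions, states, coverage = 20,
                                 conversion_rate = 0.99, dropout = 0.1,
                                 seed, chrom = "chrS") {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  states <- rep_len(states, length(cpg_positions))
  with_seed(seed, {
    kept <- stats::runif(length(cpg_positions)) >= dropout
    cov <- stats::rpois(length(cpg_positions), coverage)
    cov[!kept] <- 0L
    meth <- integer(length(cpg_positions))
    for (i in seq_along(cpg_positions)) {
      if (cov[i] == 0) next
      p_meth <- if (states[i] == "methylated") conversion_rate else
        1 - conversion_rate
      meth[i] <- stats::rbinom(1, cov[i], p_meth)
    }
    records <- data.frame(chrom = chrom, pos = as.integer(cpg_positions),
                          methylated = meth,
                          unmethylated = as.integer(cov - meth),
                          stringsAsFactors = FALSE)
    records <- records[cov > 0, , drop = FALSE]
    rownames(records) <- NULL
    list(records = records,
         truth = list(positions = as.integer(cpg_positions), states = states,
                      dropped = !kept))
  })
}

#' Serialise a truth bundle to JSON
#'
#' @param truth A (possibly nested) list of planted ground truth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bundle <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a truth bundle written by [write_truth_bundle()]
#' @param path JSON path.
#' @return The truth list.
#' @export
read_truth_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
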