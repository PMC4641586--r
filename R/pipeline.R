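# End-to-end orchestration: one config drives simulation of every input,
# all analysis stages, and a reproducible report bundle.  All randomness
# derives from config$seed via fixed per-stage offsets, so a rerun with
# an identical config is byte-identical.

#' Build a pipeline configuration
#'
#' The defaults define the reference synthetic scenario: a gene with 7
#' alternative start exons on a 1 Mb chromosome whose cancer-promoter
#' exon (`5u`) dominates expression and whose muscle exon is
#' near-silent; hypoxia raises `5u` transcription 4.3-fold (and `4u`
#' 1.2-fold), estrogen lowers `5u` to 40% of control (`4u` to 55%),
#' androgen lowers `5u` to 64% (`4u` to 82%); three negative-binomially
#' dispersed replicates per condition; Poisson ChIP background with
#' 8-fold planted peaks and an input control; promoter-anchored PET
#' pairs to five downstream and two upstream distal regions plus
#' uniform noise pairs; planted response-element motifs; and per-CpG
#' bisulfite counts at 99% conversion with 10% depth dropout.
#'
#' @param seed Master seed (mandatory; validation fails without it).
#' @param outdir Output directory.
#' @param genome_length,chrom,n_start_exons Genome/gene geometry.
#' @param base_means Named mean counts per start exon under control.
#' @param effects Named list: condition -> named multipliers applied to
#'   `base_means` (exons not named keep the control mean).
#' @param n_replicates,dispersion,read_length,background_mean RNA-Seq
#'   simulation parameters.
#' @param groseq_replicates,groseq_background_mean GRO-Seq parameters.
#' @param window_size,chip_background_rate,chip_enrichment,peak_alpha
#'   ChIP simulation and peak-calling parameters.
#' @param diff_replicates Replicates per condition for the differential
#'   stage.
#' @param pets_per_region,noise_pets,merge_gap,min_support ChIA-PET
#'   parameters.
#' @param distal_offsets Distal-region starts relative to the promoter
#'   start (bp; negative = upstream).
#' @param distal_width Width of each distal region (bp).
#' @param hypoxia_enhancer,hormone_enhancer Offsets (elements of
#'   `distal_offsets`) of the hypoxia-responsive and
#'   androgen-responsive planted enhancers.
#' @param methylation_coverage,conversion_rate,methylation_dropout
#'   Bisulfite parameters.
#' @param annotation_pad Neighbourhood (bp) added around each candidate
#'   region when annotating motifs and CpGs; response elements sit near,
#'   not exactly under, the PET ligation anchors.
#' @param n_preprocess_reads Raw reads simulated for the preprocessing
#'   stage.
#' @param write_alignments Also write the (large) per-read alignment
#'   tables?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = NULL,
                            outdir = tempfile("promloop_run_"),
                            genome_length = 1e6, chrom = "chrS",
                            n_start_exons = 7,
                            base_means = c("1u" = 30, "2u" = 20, "3u" = 10,
                                           "4u" = 466, "5u" = 500, "6u" = 25,
                                           "7u" = 2.5),
                            effects = list(
                              hypoxia = c("5u" = 4.3, "4u" = 1.2),
                              estrogen = c("5u" = 0.40, "4u" = 0.55),
                              androgen = c("5u" = 0.64, "4u" = 0.82)),
                            n_replicates = 3, dispersion = 0.05,
                            read_length = 50, background_mean = 5e4,
                            groseq_replicates = 2,
                            groseq_background_mean = 2e4,
                            window_size = 50, chip_background_rate = 2,
                            chip_enrichment = 8, peak_alpha = 0.05,
                            diff_replicates = 2,
                            pets_per_region = 3, noise_pets = 20,
                            merge_gap = 1000, min_support = 1,
                            distal_offsets = c(-80000, -40000, 30000, 80000,
                                               130000, 190000, 250000),
                            distal_width = 1500,
                            hypoxia_enhancer = 250000,
                            hormone_enhancer = 130000,
                            methylation_coverage = 20,
                            conversion_rate = 0.99,
                            methylation_dropout = 0.1,
                            annotation_pad = 1500,
                            n_preprocess_reads = 2000,
                            write_alignments = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that a seed is present, the scenario is internally consistent
#' (designated enhancers among the distal offsets, exon means named for
#' every exon) before any computation runs.
#'
#' @param config A [pipeline_config()].
#' @return `config`, invisibly, or an error.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed))
    stop("config validation: a seed is required (config$seed is NULL)")
  if (length(config$base_means) != config$n_start_exons)
    stop("config validation: base_means must name all ", config$n_start_exons,
         " start exons")
  for (off in c(config$hypoxia_enhancer, config$hormone_enhancer))
    if (!off %in% config$distal_offsets)
      stop("config validation: enhancer offset ", off,
           " is not among distal_offsets")
  if (any(abs(config$distal_offsets) + config$distal_width > config$genome_length))
    stop("config validation: distal regions exceed the genome")
  invisible(config)
}

# count read 5' ends per region (vector over regions)
count_reads_in_regions <- function(alignments, regions) {
  if (nrow(alignments) == 0) return(integer(nrow(regions)))
  pos5 <- ifelse(alignments$strand == "-", alignments$end - 1L,
                 alignments$start)
  vapply(seq_len(nrow(regions)), function(i) {
    sum(alignments$chrom == regions$chrom[i] & pos5 >= regions$start[i] &
          pos5 < regions$end[i])
  }, integer(1))
}

# the (assay, condition) -> planted-peak-location plan for the ChIP stage
.chip_plan <- function(cfg) {
  open_off <- setdiff(cfg$distal_offsets, cfg$hormone_enhancer)
  plan <- list(
    list(assay = "DNase", condition = "control", offsets = open_off, promoter = TRUE),
    list(assay = "DNase", condition = "hypoxia", offsets = open_off, promoter = TRUE),
    list(assay = "DNase", condition = "estrogen", offsets = open_off, promoter = TRUE),
    list(assay = "DNase", condition = "androgen", offsets = cfg$distal_offsets, promoter = TRUE),
    list(assay = "FAIRE", condition = "control", offsets = open_off, promoter = TRUE),
    list(assay = "FAIRE", condition = "hypoxia", offsets = open_off, promoter = TRUE),
    list(assay = "HIF1a", condition = "control", offsets = numeric(0), promoter = FALSE),
    list(assay = "HIF1a", condition = "hypoxia", offsets = cfg$hypoxia_enhancer, promoter = FALSE),
    list(assay = "ERa", condition = "control", offsets = numeric(0), promoter = FALSE),
    list(assay = "ERa", condition = "estrogen", offsets = cfg$hypoxia_enhancer, promoter = FALSE),
    list(assay = "p300", condition = "control", offsets = numeric(0), promoter = FALSE),
    list(assay = "p300", condition = "estrogen", offsets = cfg$hypoxia_enhancer, promoter = FALSE),
    list(assay = "AR", condition = "control", offsets = numeric(0), promoter = FALSE),
    list(assay = "AR", condition = "androgen", offsets = cfg$hormone_enhancer, promoter = FALSE),
    list(assay = "PolII", condition = "control", offsets = numeric(0), promoter = TRUE),
    list(assay = "PolII", condition = "estrogen", offsets = cfg$hypoxia_enhancer, promoter = TRUE))
  plan
}

#' Run the full synthetic pipeline
#'
#' Executes: simulate -> preprocess -> quantify/groseq -> foldchange ->
#' callpeaks/diffpeaks -> chiapet -> evidence -> motifs/methylation ->
#' annotate, writing every result table plus a manifest and the
#' effective parameters to `config$outdir`.  A stage failure aborts
#' with the failing stage named; outputs written so far stay on disk
#' next to a `FAILED` marker file.
#'
#' @param config A validated [pipeline_config()].
#' @return A report bundle (list of all result tables and paths),
#'   invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = cfg, outdir = cfg$outdir)
  manifest <- list()
  timings <- list()
  emit <- function(obj, file, stage, writer = NULL) {
    path <- file.path(cfg$outdir, file)
    if (is.null(writer)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      n <- nrow(obj)
    } else {
      writer(obj, path)
      n <- if (is.data.frame(obj)) nrow(obj) else NA_integer_
    }
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = file, stage = stage, rows = n, stringsAsFactors = FALSE)
    path
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      writeLines(paste("stage:", name, "-", conditionMessage(e)),
                 file.path(cfg$outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  ## -- simulate: gene model, genome, planted features ----------------------
  sim <- stage("simulate_gene", {
    gm <- make_toy_gene_model(cfg$genome_length, cfg$n_start_exons,
                              seed = cfg$seed + 1L, chrom = cfg$chrom)
    prom <- gm$model$promoter
    distal <- genomic_intervals(
      cfg$chrom,
      pmax(0, prom$start + cfg$distal_offsets),
      pmax(0, prom$start + cfg$distal_offsets) + cfg$distal_width)
    star <- distal[match(cfg$hypoxia_enhancer, cfg$distal_offsets), ]
    horm <- distal[match(cfg$hormone_enhancer, cfg$distal_offsets), ]
    inst <- rbind(
      data.frame(name = "HRE", consensus = "RCGTG",
                 position = star$start + 200, strand = "+"),
      data.frame(name = "ERE_half", consensus = "RGGTCA",
                 position = star$start + c(400, 430, 460, 490), strand = "+"),
      data.frame(name = "RUNX1", consensus = "TGTGGT",
                 position = star$start + c(600, 630), strand = "+"),
      data.frame(name = "SP1", consensus = "GGGCGG",
                 position = star$start + 700, strand = "+"),
      data.frame(name = "ARE", consensus = "GGWACANNNTGTTCT",
                 position = horm$start + c(300, 340, 380), strand = "+"),
      data.frame(name = "SP1", consensus = "GGGCGG",
                 position = prom$start + 50, strand = "+"))
    sequence <- plant_motifs(gm$sequence, inst, seed = cfg$seed + 2L)
    list(model = gm$model, sequence = sequence, promoter = prom,
         distal = distal, star = star, horm = horm, planted_motifs = inst)
  })
  emit(sim$model, "gene_model.gtf", "simulate", function(o, p) write_gene_model(o, p))
  emit(sim$sequence, "genome.fa", "simulate",
       function(o, p) write_fasta(stats::setNames(o, cfg$chrom), p))

  ## -- preprocess: raw read QC ---------------------------------------------
  prep <- stage("preprocess", {
    raw <- with_seed(cfg$seed + 3L, {
      n <- cfg$n_preprocess_reads
      starts <- sample.int(nchar(sim$sequence) - 100L, n, replace = TRUE)
      seqs <- substring(sim$sequence, starts, starts + 99L)
      quals <- vapply(seq_len(n), function(i)
        intToUtf8(33L + pmin(40L, pmax(2L, round(stats::rnorm(100, 34, 6))))),
        character(1))
      data.frame(id = sprintf("raw%d", seq_len(n)), seq = seqs, qual = quals,
                 stringsAsFactors = FALSE)
    })
    trimmed <- trim_and_filter(raw, preprocess_profile("rnaseq"))
    masked <- phred_filter_and_mask(raw)
    rbind(
      data.frame(step = names(attr(trimmed, "stats")),
                 profile = "rnaseq", count = attr(trimmed, "stats"),
                 stringsAsFactors = FALSE),
      data.frame(step = names(attr(masked, "stats")),
                 profile = "chip_bisulfite", count = attr(masked, "stats"),
                 stringsAsFactors = FALSE))
  })
  emit(prep, "preprocess_stats.tsv", "preprocess")

  ## -- quantify: RNA-Seq start-exon expression -----------------------------
  abundance <- lapply(stats::setNames(nm = c("control", names(cfg$effects))),
                      function(cond) {
    m <- cfg$base_means
    if (cond != "control") {
      eff <- cfg$effects[[cond]]
      m[names(eff)] <- m[names(eff)] * eff
    }
    m
  })
  rna <- stage("quantify", {
    meta <- data.frame(
      sample_id = paste0(rep(names(abundance), each = cfg$n_replicates), "_r",
                         seq_len(cfg$n_replicates)),
      condition = rep(names(abundance), each = cfg$n_replicates),
      stringsAsFactors = FALSE)
    sim_rna <- simulate_variant_reads(
      sim$model, meta, abundance, dispersion = cfg$dispersion,
      read_length = cfg$read_length, background_mean = cfg$background_mean,
      genome_length = cfg$genome_length, seed = cfg$seed + 4L)
    records <- expression_records(sim_rna$alignments, sim$model, sim_rna$meta)
    list(meta = sim_rna$meta, records = records,
         alignments = sim_rna$alignments)
  })
  emit(rna$meta, "sample_sheet.tsv", "quantify")
  emit(rna$records, "expression_records.tsv", "quantify")
  if (cfg$write_alignments)
    emit(rna$alignments, "alignments_rnaseq.tsv", "quantify",
         function(o, p) write_alignments_tsv(o, p))

  ## -- groseq: nascent transcription at TSSs -------------------------------
  gro <- stage("groseq", {
    meta <- data.frame(
      sample_id = paste0(rep(c("control", "estrogen"),
                             each = cfg$groseq_replicates), "_gro_r",
                         seq_len(cfg$groseq_replicates)),
      condition = rep(c("control", "estrogen"), each = cfg$groseq_replicates),
      stringsAsFactors = FALSE)
    sim_gro <- simulate_variant_reads(
      sim$model, meta, abundance[c("control", "estrogen")],
      dispersion = cfg$dispersion, read_length = cfg$read_length,
      background_mean = cfg$groseq_background_mean,
      genome_length = cfg$genome_length, seed = cfg$seed + 5L)
    groseq_tss_rpkm(sim_gro$alignments, sim$model, sim_gro$meta,
                    chrom_length = cfg$genome_length)
  })
  emit(gro, "groseq_records.tsv", "groseq")

  ## -- foldchange ----------------------------------------------------------
  folds <- stage("foldchange", {
    out <- do.call(rbind, lapply(names(cfg$effects), function(cond)
      condition_fold_changes(rna$records, cond, "control")))
    rownames(out) <- NULL
    out
  })
  emit(folds, "fold_changes.tsv", "foldchange")
  gro_folds <- stage("foldchange_groseq",
                     condition_fold_changes(gro, "estrogen", "control"))
  emit(gro_folds, "groseq_fold_changes.tsv", "foldchange")

  ## -- callpeaks: ChIP simulation and peak calling -------------------------
  chip <- stage("callpeaks", {
    plan <- .chip_plan(cfg)
    prom <- sim$promoter
    tracks <- list(); peak_tables <- list()
    for (i in seq_along(plan)) {
      p <- plan[[i]]
      planted <- data.frame(start = numeric(0), end = numeric(0),
                            enrichment = numeric(0))
      for (off in p$offsets) {
        rs <- sim$distal$start[match(off, cfg$distal_offsets)]
        s <- ((rs + 500) %/% cfg$window_size) * cfg$window_size
        planted <- rbind(planted, data.frame(start = s, end = s + 500,
                                             enrichment = cfg$chip_enrichment))
      }
      if (p$promoter) {
        s <- (prom$start %/% cfg$window_size) * cfg$window_size
        planted <- rbind(planted, data.frame(start = s, end = s + 250,
                                             enrichment = cfg$chip_enrichment))
      }
      ce <- simulate_chip_experiment(
        cfg$genome_length, cfg$chip_background_rate, planted,
        window_size = cfg$window_size, seed = cfg$seed + 10L + i,
        chrom = cfg$chrom)
      tw <- window_counts(ce$treatment, cfg$genome_length, cfg$window_size,
                          chrom = cfg$chrom)
      iw <- window_counts(ce$input, cfg$genome_length, cfg$window_size,
                          chrom = cfg$chrom)
      called <- call_peaks(tw, iw, alpha = cfg$peak_alpha)
      key <- paste(p$assay, p$condition, sep = "_")
      tracks[[key]] <- assay_track(p$assay, p$condition,
                                   called[, c("chrom", "start", "end")],
                                   dataset_id = paste0("sim_", key))
      if (nrow(called) > 0)
        peak_tables[[key]] <- cbind(assay = p$assay, condition = p$condition,
                                    called, stringsAsFactors = FALSE)
    }
    peaks_all <- if (length(peak_tables) > 0) do.call(rbind, peak_tables) else
      data.frame()
    rownames(peaks_all) <- NULL
    list(tracks = tracks, peaks = peaks_all)
  })
  emit(chip$peaks, "chip_peaks.tsv", "callpeaks")

  ## -- chiapet: candidate regions from PET pairs ---------------------------
  loops <- stage("chiapet", {
    sp <- simulate_pets(sim$promoter, sim$distal,
                        n_true_per_region = cfg$pets_per_region,
                        n_noise = cfg$noise_pets,
                        genome_length = cfg$genome_length,
                        seed = cfg$seed + 30L)
    anchored <- promoter_anchored_pets(sp$pets, sim$promoter)
    regions <- define_candidate_regions(anchored, sim$promoter,
                                        merge_gap = cfg$merge_gap,
                                        min_support = cfg$min_support)
    list(pets = sp$pets, anchored = anchored, regions = regions,
         truth = sp$truth)
  })
  emit(loops$pets[, setdiff(names(loops$pets), "is_true")], "pets.bedpe",
       "chiapet", function(o, p) write_bedpe(o, p))
  emit(loops$regions, "candidate_regions.tsv", "chiapet")
  emit(genomic_intervals(loops$regions$chrom, loops$regions$start,
                         loops$regions$end, name = loops$regions$region_id),
       "candidate_regions.bed", "chiapet",
       function(o, p) write_custom_track(o, "candidate_regions", p))

  ## -- diffpeaks: differential enrichment at candidate regions -------------
  diffs <- stage("diffpeaks", {
    star_peak <- data.frame(
      start = ((sim$star$start + 500) %/% cfg$window_size) * cfg$window_size,
      end = ((sim$star$start + 500) %/% cfg$window_size) * cfg$window_size + 500,
      enrichment = cfg$chip_enrichment)
    reg <- loops$regions
    sims <- lapply(seq_len(2 * cfg$diff_replicates), function(r) {
      planted <- if (r <= cfg$diff_replicates)
        star_peak else star_peak[0, ]
      simulate_chip_experiment(cfg$genome_length, cfg$chip_background_rate,
                               planted, window_size = cfg$window_size,
                               seed = cfg$seed + 50L + r, chrom = cfg$chrom)
    })
    ca <- sapply(sims[seq_len(cfg$diff_replicates)],
                 function(s) count_reads_in_regions(s$treatment, reg))
    cb <- sapply(sims[cfg$diff_replicates + seq_len(cfg$diff_replicates)],
                 function(s) count_reads_in_regions(s$treatment, reg))
    lib_a <- vapply(sims[seq_len(cfg$diff_replicates)],
                    function(s) nrow(s$treatment), numeric(1))
    lib_b <- vapply(sims[cfg$diff_replicates + seq_len(cfg$diff_replicates)],
                    function(s) nrow(s$treatment), numeric(1))
    dr <- differential_regions(reg, matrix(ca, nrow = nrow(reg)),
                               matrix(cb, nrow = nrow(reg)),
                               list(a = lib_a, b = lib_b))
    cbind(region_id = reg$region_id, dr, stringsAsFactors = FALSE)
  })
  emit(diffs, "differential_hif1a.tsv", "diffpeaks")

  ## -- evidence matrix and condition-response classification ---------------
  evidence <- stage("evidence", {
    em <- build_evidence_matrix(loops$regions, sim$promoter, chip$tracks)
    labels <- rbind(
      cbind(assay = "HIF1a", contrast = "hypoxia_vs_control",
            classify_condition_response(em, "HIF1a", "control", "hypoxia")),
      cbind(assay = "DNase", contrast = "androgen_vs_control",
            classify_condition_response(em, "DNase", "control", "androgen")),
      cbind(assay = "ERa", contrast = "estrogen_vs_control",
            classify_condition_response(em, "ERa", "control", "estrogen")))
    rownames(labels) <- NULL
    list(matrix = em, crossmark = crossmark_table(em), labels = labels)
  })
  emit(as.data.frame(evidence$matrix), "evidence_matrix.tsv", "evidence")
  emit(evidence$crossmark, "crossmark_table.tsv", "evidence")
  emit(evidence$labels, "response_labels.tsv", "evidence")

  ## -- motifs and methylation within candidate regions ---------------------
  feats <- stage("motifs_methylation", {
    # candidate regions are PET-anchor unions; motif/CpG annotation uses a
    # padded neighbourhood, since response elements sit near, not exactly
    # under, the ligation anchors
    cand <- loops$regions[, c("region_id", "chrom", "start", "end")]
    cand$start <- pmax(0L, cand$start - cfg$annotation_pad)
    cand$end <- pmin(cfg$genome_length, cand$end + cfg$annotation_pad)
    reg_all <- rbind(
      data.frame(region_id = "promoter", chrom = sim$promoter$chrom,
                 start = sim$promoter$start, end = sim$promoter$end,
                 stringsAsFactors = FALSE),
      cand)
    hits <- do.call(rbind, lapply(seq_len(nrow(reg_all)), function(i) {
      s <- substr(sim$sequence, reg_all$start[i] + 1L, reg_all$end[i])
      scan_motifs(s, offset = reg_all$start[i], chrom = reg_all$chrom[i])
    }))
    rownames(hits) <- NULL
    cpg_pos <- c(sim$star$start + c(150, 180, 230, 260),
                 sim$promoter$start + c(20, 60, 100),
                 sim$distal$start[1] + c(300, 350, 400))
    cpg_states <- c(rep("unmethylated", 4), rep("unmethylated", 3),
                    rep("methylated", 3))
    sm <- simulate_methylation(cpg_pos, cpg_states,
                               coverage = cfg$methylation_coverage,
                               conversion_rate = cfg$conversion_rate,
                               dropout = cfg$methylation_dropout,
                               seed = cfg$seed + 60L, chrom = cfg$chrom)
    calls <- methylation_fraction_and_call(
      filter_chromosome(sm$records, cfg$chrom))
    annot <- annotate_regions(reg_all, hits, calls)
    list(motif_hits = hits, methylation = calls, annotation = annot,
         meth_truth = sm$truth)
  })
  emit(feats$motif_hits, "motif_hits.tsv", "motifs")
  emit(feats$methylation, "methylation_calls.tsv", "methylation")
  emit(feats$annotation, "region_annotation.tsv", "annotate")

  ## -- bundle, truth, manifest ---------------------------------------------
  truth <- list(
    abundance = abundance, planted_motifs = sim$planted_motifs,
    distal_regions = sim$distal,
    hypoxia_enhancer = as.list(sim$star), hormone_enhancer = as.list(sim$horm),
    methylation = feats$meth_truth)
  write_truth_bundle(truth, file.path(cfg$outdir, "truth.json"))
  jsonlite::write_json(cfg[setdiff(names(cfg), "outdir")],
                       file.path(cfg$outdir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  bundle$model <- sim$model
  bundle$promoter <- sim$promoter
  bundle$distal <- sim$distal
  bundle$expression <- rna$records
  bundle$meta <- rna$meta
  bundle$groseq <- gro
  bundle$fold_changes <- folds
  bundle$groseq_fold_changes <- gro_folds
  bundle$peaks <- chip$peaks
  bundle$tracks <- chip$tracks
  bundle$pets <- loops$pets
  bundle$regions <- loops$regions
  bundle$differential <- diffs
  bundle$evidence <- evidence$matrix
  bundle$crossmark <- evidence$crossmark
  bundle$response_labels <- evidence$labels
  bundle$motif_hits <- feats$motif_hits
  bundle$methylation <- feats$methylation
  bundle$annotation <- feats$annotation
  bundle$preprocess_stats <- prep
  bundle$truth <- truth
  bundle$timings <- unlist(timings)
  mf <- do.call(rbind, manifest)
  utils::write.table(mf, file.path(cfg$outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bundle$manifest <- mf
  class(bundle) <- "promloop_bundle"
  invisible(bundle)
}

#' @export
print.promloop_bundle <- function(x, ...) {
  cat("promloop report bundle in", x$outdir, "\n")
  cat(sprintf("  %d start exons, %d candidate regions, %d peak calls\n",
              nrow(x$model$start_exons), nrow(x$regions), nrow(x$peaks)))
  invisible(x)
}

#' Summarise a report bundle
#'
#' Produces the analysis surfaces as plain tables: per-start-exon fold
#' changes with significance flags, the candidate-region crossmark
#' table, condition-response labels, and per-region motif/CpG
#' annotations.  Every number is taken from the persisted stage tables;
#' nothing is recomputed.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param path Optional path for a markdown summary file.
#' @return Named list of the summary tables.
#' @export
summarize_report <- function(bundle, path = NULL) {
  need <- c("fold_changes", "crossmark", "response_labels", "annotation")
  miss <- setdiff(need, names(bundle))
  if (length(miss) > 0)
    stop("incomplete bundle; missing stage output(s): ",
         paste(miss, collapse = ", "))
  out <- list(fold_changes = bundle$fold_changes,
              groseq_fold_changes = bundle$groseq_fold_changes,
              crossmark = bundle$crossmark,
              response_labels = bundle$response_labels,
              annotation = bundle$annotation)
  if (!is.null(path)) {
    con <- file(path, "w"); on.exit(close(con))
    wt <- function(title, df) {
      writeLines(c(paste("##", title), ""), con)
      writeLines(paste(names(df), collapse = "\t"), con)
      if (nrow(df) > 0)
        writeLines(do.call(paste, c(lapply(df, format), sep = "\t")), con)
      writeLines("", con)
    }
    writeLines(c("# Pipeline summary", ""), con)
    wt("Start-exon fold changes (RNA-Seq)", out$fold_changes)
    wt("Start-exon fold changes (GRO-Seq TSS windows)",
       out$groseq_fold_changes)
    wt("Evidence crossmark table", out$crossmark)
    wt("Condition-response labels", out$response_labels)
    wt("Region annotation (motifs and CpGs)", out$annotation)
  }
  out
}
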