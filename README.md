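# promloop

Integrative analysis of genes driven by multiple alternative promoters:
start-exon-specific expression, enhancer looping, chromatin state and
CpG methylation, with a synthetic-data generator that plants known
regulatory structure for end-to-end validation.

## The problem

Genes such as human myoglobin (*MB*) are transcribed from several
mutually exclusive first exons (`1u`, `2u`, ..., `10u`), each marking its
own promoter. In breast and prostate cancer cells, transcription runs
mainly from a cancer-associated promoter (exon `5u`, promoter defined as
179 bp upstream to 25 bp downstream of its TSS) rather than the muscle
promoter, and responds to hypoxia (up) and to estrogen/androgen (down).
Resolving *which* promoter is used, *how strongly*, and *which distal
elements control it* requires integrating RNA-Seq, GRO-Seq,
ChIP/FAIRE/DNase peaks, ChIA-PET interaction pairs and bisulfite
methylation data. `promloop` is aimed at computational biologists who
want that integration as composable, deterministic, tested R functions
rather than a chain of browser sessions and one-off scripts.

## What it computes

* **Start-exon quantification** —
  `RPKM = count / (len/10^3) / (total mapped/10^6)` per exon and sample;
  GRO-Seq nascent signal in strand-oriented −100/+500 bp TSS windows
  (0.6 kb feature length). Fold changes as treated/control mean RPKM,
  with one-way ANOVA and Tukey-Kramer post-hoc tests (studentized-range
  statistic with the Kramer SE for unequal group sizes).
* **Peak calling** — 50 bp windows, each read assigned by its 5' base;
  a window is enriched when its count reaches the smallest *k* with
  `P(X ≥ k | λ) ≤ α/n_windows` (Poisson tail, Bonferroni across
  windows); input-control correction via a scaled local mean; adjacent
  enriched windows merge into peaks.
* **Differential enrichment** — exact conditional negative-binomial
  test on library-normalised replicate counts (method-of-moments common
  dispersion; dispersion 0 reduces to the conditional-binomial test);
  classified at |log2FC| ≥ 1, p < 0.05.
* **Loop integration** — ChIA-PET pairs with exactly one anchor on the
  promoter define distal candidate regions (anchors merged within 1 kb,
  lettered in genomic order), then a region × (assay, condition)
  evidence matrix with `present`/`absent`/`no_data` cells and
  condition-response labels (`treatment-gained`, `constitutive`, ...).
* **Sequence features** — IUPAC consensus scanning for HRE/ERE/ARE/
  RUNX1/SP1 motifs on both strands; per-CpG methylation fractions and
  calls (thresholds 0.2/0.8, minimum coverage 4).
* **Synthetic data** — generators for every input with planted truth:
  NB-dispersed start-exon reads, Poisson ChIP background with enriched
  windows, promoter-anchored PETs plus noise, planted motifs,
  imperfect-conversion bisulfite counts.

## Worked example

One call simulates the full scenario (1 Mb genome, 7 start exons,
hypoxia/estrogen/androgen conditions, ChIP tracks, PET pairs, bisulfite
counts) and runs every analysis stage; it takes a few seconds:

```r
library(promloop)
b <- run_pipeline(pipeline_config(seed = 1, outdir = "promloop_run"))

subset(b$fold_changes, unit_name %in% c("4u", "5u"),
       select = c(unit_name, condition_a, fold_change, pct_of_control,
                  anova_p, tukey_significant))
#>  unit_name condition_a fold_change pct_of_control  anova_p tukey_significant
#>         4u     hypoxia       1.465          146.5 0.042347             FALSE
#>         5u     hypoxia       3.637          363.7 0.000062              TRUE
#>         4u    estrogen       0.775           77.5 0.042347             FALSE
#>         5u    estrogen       0.371           37.1 0.000062             FALSE
#>         4u    androgen       1.226          122.6 0.042347             FALSE
#>         5u    androgen       0.558           55.8 0.000062             FALSE
```

The planted effects were 4.3× (hypoxia), 40% (estrogen) and 64%
(androgen) on exon `5u`: a single 3-replicate run recovers them with the
sampling scatter a dispersion-0.05 design implies (the log fold change
carries an ~18% CV floor; see the vignette). The ChIA-PET stage recovers
the seven planted distal regions and letters them in genomic order:

```r
b$regions[, c("region_id", "start", "end", "n_pets", "distance_to_promoter")]
#>  region_id  start    end n_pets distance_to_promoter
#>          A 229151 229871      3                78807
#>          B 268844 269740      3                38938
#>          C 339338 339915      3                30456
#>          D 388753 389680      3                79871
#>          E 439030 440077      3               130148
#>          F 498935 499912      3               190053
#>          G 559308 559943      3               250426
```

and the evidence matrix classifies the enhancer 250 kb downstream
(region `G`, which carries the planted HRE and unmethylated CpGs) as
gaining HIF1a binding under hypoxia:

```r
subset(b$response_labels, assay == "HIF1a")
#>  assay           contrast region_id            label
#>  HIF1a hypoxia_vs_control         G treatment-gained   # all others: closed
```

`summarize_report(b, "summary.md")` writes the crossmark table, fold
changes, response labels and per-region motif/CpG annotations as one
readable file; all tables are also persisted as TSV in `outdir` with a
manifest.

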