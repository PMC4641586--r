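---
title: "Dissecting alternative-promoter regulation with promloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting alternative-promoter regulation with promloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promloop)
```

## The biological question

Some genes are transcribed from several mutually exclusive first exons,
each marking its own promoter. The human myoglobin (*MB*) gene is the
motivating case: its muscle promoter (exon `9u`) drives the classic
high-level expression in myocytes, while a distinct cancer-associated
promoter (exon `5u`) drives low-level expression in breast and prostate
tumour cells, where it responds to hypoxia (up) and to estrogen or
androgen exposure (down). Which promoter is active, how strongly, and
which distal DNA elements regulate it are questions that can be answered
by integrating several sequencing assays:

* **RNA-Seq** read counts over each alternative start exon quantify
  promoter usage per condition.
* **GRO-Seq** (nascent transcription) signal in a window around each
  TSS confirms that changes are transcriptional.
* **ChIP-Seq / FAIRE-Seq / DNase** peaks describe the chromatin state of
  candidate regulatory regions per condition.
* **ChIA-PET** pairs identify distal regions that physically loop back
  to the promoter.
* **Bisulfite sequencing** gives the methylation state of CpGs inside
  those regions.

`promloop` implements this integration as a set of composable, tested R
functions, and ships a synthetic-data generator that plants known
regulatory structure so that every stage can be validated end to end
against ground truth.

## Quantification model

**Start-exon counting.** A read is assigned to a start exon when any of
its aligned blocks overlaps the exon by at least 1 bp; a read
overlapping k exons contributes to all k. Counting is unstranded by
default (typical unstranded RNA-Seq libraries); a stranded switch
exists. Counts are normalised to

$$\mathrm{RPKM} = \frac{\text{count}}{(\text{exon length}/10^3)\,
(\text{total mapped reads}/10^6)},$$

with the *genome-wide* mapped-read total in the denominator. "Total
mapped" rather than "total processed" is used because the quantity is a
mapping-derived library size.

**GRO-Seq TSS windows.** Nascent transcription is counted in a
strand-oriented window from 100 bp upstream to 500 bp downstream of each
TSS; the RPKM feature length is fixed at the 600 bp window (0.6 kb
fragment). A read falls in the window when its 5'-most aligned base does
— polymerase position is marked by the 5' end of a run-on read. Only
reads on the gene strand count, because GRO-Seq is strand-specific.

**Fold changes and tests.** Condition effects are summarised as
`mean RPKM(treated) / mean RPKM(control)`; decreases are also reported
as percentages of control. A classical one-way fixed-effects ANOVA runs
across all conditions per exon, followed by Tukey-Kramer pairwise
comparisons (studentized-range statistic with the Kramer standard error
for unequal group sizes; critical values from `ptukey`). When the
control mean is zero the fold change is flagged undefined rather than
divided.

Note a practical limit of a 3-replicate design: with negative-binomial
counts of dispersion $\varphi$ (variance $m + \varphi m^2$), the log
fold-change estimate carries a standard-deviation floor of
$\sqrt{2\varphi/n}$ regardless of how deep the counts are — about 0.18
(an 18% coefficient of variation) at $\varphi = 0.05,\ n = 3$. Individual
run estimates of a 4.3-fold effect therefore scatter roughly between 3
and 6; only the replicate-averaged ANOVA, not the point fold change,
should be over-interpreted.

## Peak calling

Chromosomes are tiled with non-overlapping 50 bp windows (the step
equals the window size; a sliding mode is configurable) and each read is
assigned to one window by its 5'-most base. The minimum read count that
makes a window significant is derived automatically from a Poisson
background: the smallest $k$ with

$$P(X \ge k \mid \lambda) \le \alpha / n_\text{windows},$$

a Bonferroni correction over windows at $\alpha = 0.05$. For
$\lambda = 1$ and 20000 windows this gives $k = 9$. With an input
control, $\lambda$ per window is the input's running local mean (21
windows) scaled to the treatment library size and floored at the scaled
global mean, which absorbs coverage bumps shared by treatment and input.
Adjacent significant windows merge into one peak that reports the
summed count, summed expectation, and the smallest member-window tail
probability.

**Differential enrichment.** Regions are compared between conditions on
library-size-normalised replicate counts. The p-value is an exact
conditional test on the pooled normalised counts under a
negative-binomial model with a single common dispersion estimated across
regions by the method of moments; at dispersion zero this reduces to the
conditional-binomial (Poisson) exact test. The implementation is
self-contained and is cross-checked in the tests against both a
brute-force enumeration oracle and an independent package
implementation of the same conditional test. Classification uses
|log2 fold change| ≥ 1 with p < 0.05. The 0.5 pseudocount per side is
applied only when one side's mean is zero: its purpose is to avoid
infinite ratios, and adding it unconditionally would bias every finite
log fold change (e.g. the (100,120) vs (25,30) example would report 1.98
instead of the exact 2.0).

## Loop integration

ChIA-PET pairs qualify as promoter-anchored when exactly one anchor
overlaps the promoter by ≥ 1 bp; pairs with both anchors on the
promoter are self-loops and are excluded (but counted). The distal
anchors are merged into candidate regions when within 1 kb of each other
(in practice such regions are often delimited by visual inspection
across browser tracks; 1 kb is an explicit, configurable rule instead).
Regions are named `A`, `B`, ... in genomic order. Supporting-pair and
supporting-dataset counts are reported per region rather than used as a
hard filter (`min_support` defaults to 1).

The evidence matrix crosses every region (plus the promoter) with every
(assay, condition) combination spanned by the supplied tracks: `present`
iff any matching peak overlaps the region, `absent` iff at least one
matching track exists without overlap, `no_data` otherwise — a cell is
never guessed. When datasets disagree, `present` wins and every present
cell stays traceable to a concrete (dataset, peak) pair through the
audit attribute. Condition-response labels per assay follow directly:
`treatment-gained`, `treatment-lost`, `constitutive`, `closed`, or
`no_data`.

## Sequence features

Motif scanning is exact IUPAC consensus matching (both strands by
default; minus-strand hits are reported at plus-strand coordinates). The
shipped consensus set uses literature-standard cores — HRE `RCGTG`, ERE
half site `RGGTCA`, full ARE `GGWACANNNTGTTCT`, ARE half site `AGAACA`,
RUNX1 `TGTGGT`, SP1 `GGGCGG` — as declared substitutes for commercial
motif predictors whose underlying models are unpublished; they are
user-overridable. Binary present/absent matching (not position-weight
scoring) reflects how such annotations are reported.

Methylation calls per CpG use fraction thresholds 0.2 / 0.8 and a
minimum coverage of 4 reads; sites below coverage are `no_call`, mirrors
of the "insufficient depth" gaps in real bisulfite tables. These
thresholds are conventions: published tables report binary states
without stating cutoffs.

When candidate regions are annotated inside the pipeline, each region is
padded by ±1.5 kb (`annotation_pad`): a candidate region is the union of
PET ligation anchors, and the response elements of an enhancer sit near,
not necessarily under, those anchors.

## Read preprocessing

Three named profiles reproduce the stated QC parameter sets:
`rnaseq` (trim 12 bp 5' / 5 bp 3', quality limit 0.05, minimum length
15 nt, ≤ 2 ambiguous bases), `groseq` (trim 12 bp 5', limit 0.01,
minimum 10 nt) and `chip_bisulfite` (reject mean Phred < 30, then mask
15 bp 5' and 5 bp 3' with N). Two interpretation choices are documented
rather than hidden:

* "quality limit" trimming is implemented as modified-Mott trimming —
  keep the contiguous segment maximising $\sum(\text{limit} - p_i)$
  with $p_i$ the per-base error probability — which mimics the
  documented behaviour of the commercial trimmer that defines only the
  limit;
* the Phred-30 rejection is read as *mean* Phred over the read, the
  simplest defensible reading of an underspecified rule (minimum- or
  windowed-score readings would be stricter).

## The synthetic generator

`pipeline_config()` defaults define the reference scenario: a 1 Mb
chromosome carrying a 7-start-exon gene whose cancer exon `5u` dominates
(control mean 500 counts) while the muscle exon is near-silent
(mean 2.5, several hundred-fold below `5u`); hypoxia multiplies `5u` by
4.3 and `4u` by 1.2; estrogen lowers `5u` to 40% and `4u` to 55% of
control; androgen lowers them to 64% / 82%; three replicates per
condition with NB dispersion 0.05 (variance $m + 0.05 m^2$; replicate
dispersions are a calibration choice — public datasets rarely state
them);
~50000 genome-wide background reads per sample so the RPKM denominator
is genome-wide as in real libraries. ChIP data are Poisson with rate 2
per 50 bp window, planted peaks at 8× enrichment, and a matched input.
Five downstream and two upstream distal regions (up to 250 kb from the
promoter, an A–G-style geometry of promoter-interacting regions as
described around the *MB* locus) receive three true PET pairs each, plus
20 uniform noise pairs. Planted motifs place an HRE,
four ERE half sites, two RUNX1 sites and an SP1 box in the
hypoxia/estrogen enhancer 250 kb downstream, three AREs in the
androgen-responsive region, and an SP1 box in the promoter. Bisulfite
counts use mean coverage 20, conversion 0.99 and 10% site dropout, with
the four CpGs around the HRE planted unmethylated.

Every generator is a pure function of (parameters, seed): reruns are
byte-identical, and the global RNG stream of the caller is left
untouched. What the generator does **not** emulate — sequencing errors,
adapter contamination, PCR duplicates, fragment-length structure,
spliced reads across start exons, mappability biases — bounds what
passing tests prove: they validate the statistical machinery and the
integration logic, not robustness to artefacts of real libraries.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; GTF and SAM
  are converted at the file boundary. Chromosome names match by exact
  string equality.
* The Bonferroni-corrected Poisson threshold is a reproducible,
  documented formalisation of the "automatically calculated" minimum
  read counts of commercial peak callers.
* Library-size normalisation in the differential test is total-count
  scaling; normalised pooled counts are rounded for the exact test.
* Ties in Mott trimming resolve to the leftmost maximal segment; an
  all-bad read trims to length zero and is then length-filtered.
* The studentized-range p-values come from `ptukey`; a Monte-Carlo null
  would be the fallback only where that quantile function is
  unavailable.
* Problem sizes in the test-suite calibrations (2000-window null
  backgrounds, 100 kb recovery genomes, 200–1000 replicate seeds,
  reduced 400 kb pipeline configs) are chosen to keep the full suite
  around a minute while leaving the binomial noise on estimated rates
  well inside the asserted margins; the full-scale 1 Mb default run
  takes under ten seconds.

## Limitations

* The NB exact test assumes a common dispersion across regions;
  region-specific dispersion (as tagwise empirical-Bayes estimators
  provide) is out of scope.
* Candidate-region boundaries depend on the anchor merge gap; region
  boundaries drawn by eye in browser-based analyses are not exactly
  reproducible by any fixed rule.
* Motif hits are binary consensus matches; affinity differences between
  sites are invisible.
* The pipeline consumes alignments; mapping itself (including bisulfite
  genome conversion) is outside the package.
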