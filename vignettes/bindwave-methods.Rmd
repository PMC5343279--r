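---
title: "Methods: consensus binding sites, regulatory-element context, and SOCE quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus binding sites, regulatory-element context, and SOCE quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindwave)
```

`bindwave` covers the downstream half of a transcription-factor ChIP-Seq
study: what happens after peaks have been called. This vignette documents
the models and conventions each stage uses, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices made where more than one reasonable definition exists.

## Coordinates and formats

All intervals are 0-based half-open internally (the BED convention).
Browser-style printed positions (1-based, closed) are produced only by
`to_browser_coords()`; nothing else touches that convention. Chromosome
names are matched as exact strings — no `chr` aliasing — because silent
aliasing hides input mix-ups. Peak scores follow the MACS convention
`score = -10 log10(p)`; `score_to_pvalue()` and `pvalue_to_score()` are
the only converters. narrowPeak input takes its score from the
signalValue column by default; a switch selects the `-log10(p)` column
instead, since peak callers differ in which column they populate
meaningfully.

## Consensus peaks

A consensus peak is a maximal region of pooled replicate coverage that
contains at least `min_overlap` (default 1) bp shared by *every*
replicate. Three definitions were open:

* **Overlap criterion.** "Called in all replicates" is interpreted as at
  least one shared base pair; the threshold is exposed as `min_overlap`
  for sensitivity analysis.
* **Reported interval.** The base-wise intersection (default) is the
  region every antibody supports; the pooled union is available via
  `coords = "union"`. The exact intersection segments are kept in the
  `core` list-column, which is also what the test-suite oracle compares
  against a per-base boolean-AND reference.
* **Consensus score.** The minimum across replicates of each replicate's
  best overlapping peak score — deliberately conservative: a consensus
  region is only as credible as its weakest supporting experiment.
  Recomputing per-region p-values from read pileups is out of scope;
  combining replicate p-values (Fisher, Stouffer, ...) was considered and
  rejected because no single convention is standard for dependent
  replicate ChIP experiments.

Where one replicate contributes two adjacent peaks inside one pooled
region, a single consensus peak is emitted (the maximal-region rule);
ties and ordering are resolved by (chrom, start).

## Midpoint annotation

Peaks are represented by their midpoint, `floor((start + end) / 2)`.
Categories are assigned with priority promoter > exonic > intronic >
intergenic. The promoter window is ±`promoter_halfwidth` (default
1000 bp, the conventional TSS-proximal window) around *any* transcript's
strand-aware TSS, and it is closed at the edges: `|d| = 1000` is still a
promoter call. The priority order means a midpoint inside a first exon
but near the TSS is a promoter call — the promoter definition overrides
gene-body status, and exon beats intron wherever transcripts disagree.
TSS distances are signed relative to the gene's strand (downstream
positive); ties in absolute distance break toward the lexicographically
smaller `gene_id`, making results order-independent. Peaks on
chromosomes without gene models are classified intergenic with a warning
by default (an error is available), and their TSS distance is `NA`.
Because the four categories form a strict partition, counts always sum to
the number of peaks.

## Chromatin context

Each peak gets one score per signal track: the **maximum** value among
overlapping segments (default). The rationale: these tracks are
peak-call-like (a called histone region with a score), and "the histone
peak this binding site falls in" is its score; a coverage-weighted mean
(uncovered bases contributing 0) is available via `aggregate = "mean"`
for dense signal. The genome baseline is the expected score of a
uniformly random base, `sum(value × length) / genome_size` — independent
of the peak set — with a mean-over-covered-segments alternative. Empty
categories yield `NA` cells, never 0, to keep "no peaks" distinct from
"no signal".

## E-box clusters and conservation profiles

E-boxes (CANNTG) are scanned on the forward strand only: the pattern
class is its own reverse complement, so double-strand scanning would
double-count every site. Overlapping matches are counted by default (the
honest enumeration; `overlapping = FALSE` gives greedy left-to-right
counting), and an `N` in the sequence never matches. Background density
is pooled hits over pooled length; cluster enrichment is the density
ratio `(k / L) / background`, so four E-boxes in 130 bp against a 1/180
bp background is ≈5.5-fold.

Sliding-window profiles use window 50 bp and step 1 bp by default; the
step is configurable since only the window and span are conventionally
reported. Signal tracks are expanded to per-base values first, with
uncovered bases contributing 0 (set `uncovered = NA` plus `na_rm = TRUE`
to skip gaps instead — relevant for conservation tracks with unscored
bases). Window means are computed by cumulative sums and verified against
a naive moving average to 1e-9. Concordance between two profiles on the
same grid is Spearman rank correlation, robust to the very different
scales of conservation scores and binding scores.

## ChIP-qPCR and RT-qPCR

The input aliquot adjustment subtracts `log2(1 / input_fraction)` cycles
(3.32 for 10%); the full-precision logarithm is used internally, 3.32
being its display rounding. Percent input is
`100 × 2^(adjusted input Ct − ChIP Ct)`; fold enrichment divides the
target antibody's mean percent input by the control antibody's at the
same amplicon. Replicates are aggregated by arithmetic mean of percent
inputs before the ratio (the order matters only at second order; a
geometric-mean option is provided, which is unbiased in log space). Fold
enrichment is invariant to any constant shift applied to all Ct values.
RT-qPCR relative expression is standard ΔΔCt.

## SOCE trace quantification

Traces are normalized as ΔF/F₀ with F₀ the background-subtracted
minimum, so every valid normalized trace has minimum exactly 1; a
background at or above the raw minimum is an error, not a silent clamp.
The record is segmented at the thapsigargin time (default 100 s) and the
Ca²⁺ re-addition time (default 400 s) into baseline, ER-release (wave 1)
and SOCE (wave 2) phases. Two definitions were open and are switches:

* **Peak reference.** Peak height defaults to the maximum above the mean
  of the pre-stimulus window (`baseline = "pre"`), not above the
  normalization floor of 1: the pre-window mean is the cell's own resting
  level, and the floor may be reached elsewhere in the record. The floor
  is available via `baseline = "floor"`.
* **Areas.** AUCs are trapezoidal integrals of the baseline-subtracted
  trace clipped at 0, keeping areas non-negative under noise. The SOCE
  area splits at `early_s` (default 50 s) after Ca²⁺ re-addition; the
  split point is inserted into the integration grid by linear
  interpolation, so early + late equals the total to numerical precision
  even off-grid.

`cohort_summary()` reports median/quartiles/range per condition (the
box-plot numbers) and leaves hypothesis testing to standard routines
(`kruskal.test`, `t.test`) on the tidy per-cell table.

## The synthetic-data generator

The generator's defaults are the study conditions the package is tested
under, chosen once:

* Genome: 2 chromosomes × 100 kb — large enough for dozens of
  well-separated genes, small enough that every test runs in seconds.
* Genes: 24 three-exon genes (600 bp exons, 800 bp introns), placed with
  ≥2.6 kb intergenic gaps and 3 kb chromosome margins so that planted
  site categories are geometrically unambiguous (every planted midpoint
  is >1 kb from any boundary that could flip its category). Exons are
  600 bp so 550 bp profile spans fit inside single exons.
* Binding sites: 60 truth sites of 300 bp (15 per category), observed by
  3 replicates with 10 bp Gaussian boundary jitter, 5% per-replicate
  miss rate, and 30 decoy peaks per replicate drawn mutually disjoint
  across replicates and from the truth — so decoys can never form a
  consensus, and with the miss rate at 0 the consensus count equals the
  planted count exactly.
* Marks: each mark's enriched segments sit on the truth sites of its
  characteristic category (H3K4me3/H3K27ac promoters, H3K36me3 exons,
  H3K4me1 introns, H3K9me3/H3K27me3/CTCF intergenic), 10× over sparse
  background segments.
* Element: the first intronic truth site carries a planted 4-E-box /
  130 bp cluster (window re-sampled until the count is exact) and a
  Gaussian conservation/binding bump (σ = 150 bp) shared by both tracks,
  so their 50 bp window profiles co-vary; exons are globally elevated in
  conservation relative to introns. The empirical ~1/180 bp intronic
  E-box density is a configuration value used for enrichment arithmetic;
  uniform random sequence has its own density (~1/256 bp), which the
  pipeline reports alongside as the measured background.
* qPCR: planted folds {1, 1.4, 35, 100} — a null, a subtle change, and
  the two landmark target enrichments — with 0.2-cycle Ct noise and 3
  technical replicates.
* Traces: 30 cells per condition, 6 s frames for 600 s, α-function waves
  `(t/τ) e^{1−t/τ}` (τ = 20 s) at 100 s and 400 s; the paper-shaped
  protocol fixes the timings, and the α-function is a generic wave shape
  — only relative amplitudes and areas are asserted anywhere, never the
  shape itself. SOCE scale 1.0 vs 1.4 between conditions, 5% per-cell
  amplitude CV, 0.02 ΔF/F₀ frame noise.

One master seed drives everything through deterministic per-artifact
sub-streams, so regenerating any one artifact never perturbs the others
and the whole dataset is byte-reproducible.

What the generator does **not** emulate: read-level data (FASTQ,
alignment, peak calling), realistic nucleotide composition or motif
clustering beyond the planted element, overlapping transcript isoforms,
copy-number or mappability artifacts in signal tracks, qPCR efficiency
deviations from 2.0, photobleaching and drift in imaging, or cell
segmentation. Passing the recovery tests therefore demonstrates that the
arithmetic and interval logic are correct under controlled conditions —
not that the defaults capture the noise structure of any real
experiment.

## Problem sizes and numerical tolerances

The test suite verifies the consensus implementation against a per-base
boolean-AND oracle on 200 random 100 kb genomes, window means against a
naive moving average at 1e-9, AUC additivity at 1e-9, planted qPCR folds
exactly at zero noise and within 15% (as the geometric mean over 12
independent noisy tables at 3 replicates, which tests the estimator's
accuracy rather than a single noisy draw), and planted SOCE ratios
within 10% on 30-cell cohorts. The end-to-end demo
(`run_pipeline()`) runs all stages through the on-disk formats in a few
seconds at the default sizes.

## Known limitations

* Consensus scores are not recomputed p-values; min-score is a
  conservative stand-in.
* Annotation offers no UTR/ncRNA subcategories, and nearest-gene
  assignment is by TSS distance only.
* bigWig is not parsed; signal tracks are bedGraph text.
* Background estimation for imaging is out of scope: the background is
  an input (scalar per field or per-frame series).
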