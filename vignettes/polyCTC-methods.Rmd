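---
title: "Methods: detecting and characterizing polyploid circulating tumor cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing polyploid circulating tumor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

polyCTC models one question end to end: do large polyploid tumor cells —
circulating tumor cells with *increased genomic content* (CTC-IGC) — appear
in liquid biopsies, are they clonally related to typical CTCs, which genes
do chemotherapy-surviving polyploid cells turn on, and does their presence
track progression-free survival? Because raw patient slides and sequencing
runs cannot be redistributed, the package pairs every analysis stage with a
synthetic-data generator that plants known ground truth with the same
statistical structure the stage assumes. Passing tests therefore demonstrate
*method correctness on data with the assumed structure*; they do not by
themselves validate performance on real slides or real sequencing libraries
(see Limitations).

# Slide imaging and morphometry

A slide is a set of co-registered intensity channels: DAPI (nuclei), a
pooled pan-cytokeratin/EpCAM "EPI" epithelial cocktail, CD45 (leukocyte
exclusion), and a variable marker channel. Segmentation is per channel:
a pixel is foreground when it exceeds the local arithmetic mean over a
`blockSize` window by more than `offset`, followed by morphological opening
(disk, radius 2 px) and small-component removal. Channel masks are unioned
into the cell mask; the DAPI mask intersected with each cell component is
its nuclear region; the nuclear equivalent diameter is
`pixelSize * sqrt(4 * area / pi)`.

Parameter notes:

* `blockSize` (default 51 px) must exceed the largest object so local means
  stay anchored to background; with 10x scanning at ~1 µm/px this covers
  cells up to ~40 µm.
* `offset` (default 10 intensity units) suits near-noiseless images. For
  the shipped presets (background 500, signals ~8000–9000, noise SD 50) the
  preset carries `segmentOffset = 2600`, about one third of the
  signal-to-background contrast. Because rendered disks are blurred
  (sigma = 1 px), a threshold near half-contrast crosses the edge profile
  within ±0.5 px of the true radius, which keeps measured equivalent
  diameters within 1 px of truth; thresholds close to background
  systematically inflate small nuclei.
* Border-touching components are retained but flagged, so synthetic
  size statistics are not biased by dropping them; anucleate components are
  kept with diameter 0 and flagged.

# Rare-cell classification and the IGC rule

Calls are exhaustive and mutually exclusive, in order: DAPI− → OTHER;
CD45+ → WBC (the exclusion marker dominates); EPI+ & CD45− → CTC;
EPI− & CD45− & marker+ → MARKER_ONLY; else OTHER. Positivity is
background-relative — mean intensity above background mean + 5 SD, estimated
from pixels outside the dilated cell mask — because absolute cutoffs do not
transfer across stain batches or scanners.

The IGC rule flags a CTC whose nuclear diameter is at least twice the
"average" of the sample's CTC population. We implement the reference as the
**median** of all CTC-class cells in the sample: the arithmetic mean is
inflated by the very IGC cells being detected, making the rule circular,
while the median is stable whenever IGC cells are a minority. A 20%
trimmed-mean dialect is available. The reference is computed per sample
(one patient compartment), not per cohort. MARKER_ONLY cells meeting the
rule are flagged but never count toward sample positivity, since without
epithelial positivity their tumor origin is unconfirmed. The rule is
scale-invariant: units (µm vs px) cannot change the flags.

# Copy-number ratios, segmentation, concordance

Per-cell bin counts are divided by bin width, optionally GC-corrected by a
median-per-GC-decile curve, and scaled so the genome-wide median ratio is 1.
Ratio 1 is copy-number neutral *relative to that cell's genome*; uniform
whole-genome doubling and sequencing depth cancel exactly, which is what
makes IGC profiles comparable with typical CTC profiles.

Segmentation is recursive binary splitting per chromosome on
`log2(ratio + 0.01)` (the pseudo-ratio keeps zero-count bins finite): the
candidate breakpoint maximizes the pooled two-sample t statistic; it is
accepted when its within-chromosome permutation p (1000 permutations by
default) is below `alpha = 0.01` and both sides keep `minBins = 5` bins.
Noise-free steps are recovered exactly because the t statistic is maximized
at the true changepoint.

Concordance between two cells is the Pearson correlation of per-bin log2
segmented ratios (Spearman dialect available); the group comparison tests
within-A, within-B and cross-group off-diagonal entries pairwise by Wilcoxon
rank-sum with Holm correction over the three tests. Zero-variance (flat)
profiles have undefined concordance and return a flagged `NA`.

# Differential expression and the survivor intersection

The DE test is deliberately simple and fully self-contained: per gene, a
tie-corrected Wilcoxon rank-sum on log2 CPM within each sequencing batch
that contains both groups, combined across batches by Stouffer weighting
with sqrt(n); BH correction across tested genes. LFC is the difference in
group means of `log2(CPM + 1)`. Genes detected in fewer than 10% of cells
in both groups are excluded — a standard sparsity guard. The quasi-likelihood
count-model pipeline used in the field would gain power on borderline
effects; the shipped preset plants 8-fold shifts precisely so that recovery
does not hinge on that choice.

"LFC > 1.5" is interpreted on the log2 scale (~2.8-fold); a linear
fold-change dialect is provided. Up-sets are intersected per line across its
two drugs, then across lines; the intersection is monotone in both
thresholds. Over-representation uses the one-sided Fisher exact test against
a user-supplied GMT library. The per-cell signature score follows the
rank-based JASMINE structure: mean rank of expressed signature genes among a
cell's expressed genes divided by the number of expressed genes, averaged
with the expression odds ratio of signature vs non-signature genes after
min–max scaling each component across cells; constant components (e.g. a
single cell) are defined as 0.5 with a warning.

# Survival

Kaplan–Meier product-limit estimation with Greenwood variance and the
standard two-group log-rank test are implemented directly (the `survival`
package serves as an independent oracle in the test suite, never as the
implementation). Ties at an event time use the simultaneous-death
convention; censorings tied with an event are placed after it. A median
split utility supports marker-expression grouping.

# The synthetic generators: what they emulate, and what not

**Slides.** Cells are hard disks (whole cell in cytoplasmic channels, a
concentric nuclear disk in DAPI) blurred with sigma = 1 px plus Gaussian
noise — enough structure to exercise thresholding and morphometry
deterministically. No point-spread optics, no overlapping or touching cells
(placement is rejection sampling with a 10,000-attempt cap), no uneven
illumination, no staining artifacts. Real slides violate all four, so
imaging performance here is an upper bound.

**Cohort preset.** 31 matched blood/marrow patients plus 13 marrow-only
patients; 3 blood slides and 25 marrow slides of the matched set carry
planted IGC (3/31 = 9.7%, 25/31 = 80.6%). The paper-facing counts fix only
the matched set; the 13 marrow-only patients get 10 positives, matching the
~80% marrow rate — needed for the 44-sample survival stage. Each slide
carries 500 white blood cells (an arbitrary but realistic plating density —
the source protocol does not state one), 8 typical CTCs (nuclear diameter
12 ± 0.5 µm) and, on positive slides, 2 CTC-IGC (28 ± 1 µm, i.e. ≥2× with
clear separation). PFS is exponential (hazard 0.25/month for positive
patients vs 1/12 for negative, i.e. median ~2.8 vs ~8.3 months) with
independent uniform censoring at rate 0.2 — the simplest model exposing the
KM/log-rank contract, not a calibrated clinical model.

**Copy number.** A ~5,000-bin grid over 22 autosomes with hg38-proportional
lengths. The PC3-like preset plants state 3 on chromosome 1 and state 1 on
chromosome 10 (the line's known centromere ploidies) on a diploid baseline,
so median-normalized ratios are 1.5 and 0.5. GC bias is off by default; an
optional monotone quadratic curve exists to test the correction. Reads are
multinomial over bins given a Poisson total (~500k), i.e. no alignment or
duplication artifacts.

**RNA.** 20,000 genes — a realistic transcriptome scale chosen so the
planted programs stay a small share of each cell's library; with a small
gene universe the 8-fold program shifts inflate treated-cell library sizes
enough to compress CPM fold changes below threshold (composition bias),
which is a property of CPM normalization, not of the planted biology.
Program genes get uniform baseline mean counts in [1, 2] (never
sub-detection); other baselines are log-normal. Counts are negative binomial
(dispersion 0.1) with Gaussian library-size factors (1e5 ± 2e4), condition
sizes matching the profiled 10-days-post-treatment populations
(MDA 43/62/62, PC3 129/68/118), two batches per condition. Planted programs:
309 shared across all four treated conditions, 1282 MDA-only, 869 PC3-only,
all at log2 fold change 3, so the line-shared sets are 1591 and 1178 and
their intersection 309. Biotypes assign 238/53/12/6 of the shared program to
protein coding / lncRNA / pseudogene / TEC (77% / 17% / 4% / 2%).

# Numerical choices and degenerate inputs

* Fixed seeds make every generator byte-reproducible; derived seeds stay
  below 2^31.
* Rank-sum p-values: exact enumeration of assignments for combined n ≤ 20
  in `compareMorphometry` (ties handled by enumerating tied ranks), normal
  approximation with tie correction otherwise and in `deTest`.
* `log2(ratio + 0.01)` before segmentation/concordance; zero-variance
  profiles return flagged `NA` concordance.
* Empty inputs return empty typed tables (records, breakdowns) rather than
  errors; impossible inputs (all-zero counts, even block sizes, missing
  channels, empty groups) raise named errors.
* Set intersection sizes and positivity percentages are reported rounded as
  in the source figures (one decimal for percentages of 31; integer biotype
  percentages).

# Problem sizes

Default test and acceptance runs use the full 31 + 13-patient cohort at
800 × 800 px slides, 20,000-gene counts for ~685 cells, 2,000–5,000-bin
copy-number grids with 100–1,000 segmentation permutations, 500 null
cohorts for calibration and 20 null DE replicates. These sizes were chosen
as the smallest at which each statistical claim is sharp (e.g. exact
set-size recovery, KS uniformity).

# Known limitations

* No overlapping-cell splitting (watershed) — the generator guarantees
  separation; real slides do not.
* CPM-mean LFC carries composition bias under very large planted programs;
  the preset design keeps it second-order rather than removing it.
* The copy-number segmentation is a defined stand-in for the original
  low-pass WGS pipeline; acceptance is planted-truth recovery, not
  replication of patient profiles.
* Survival modelling is exponential with uniform censoring; no Cox
  regression or covariate adjustment.
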