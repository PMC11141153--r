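---
title: "Methods: endolysosomal multi-omics statistics for AF models"
author: "atriomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endolysosomal multi-omics statistics for AF models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriomics)
```

# Scope and design

`atriomics` re-implements, as tested and reusable components, the
computational stages of an endolysosomal multi-omics analysis of a
large-animal (goat) atrial-fibrillation model: differential label-free
proteomics per sub-cellular fraction, an integrated proteome–transcriptome
pathway analysis, automated glycogen-granule counting on electron
micrographs, and the enzyme-assay / Western-blot summary statistics. A
synthetic-data generator with known ground truth stands in for the deposited
raw data, so every stage is testable end to end.

The package follows Bioconductor conventions: the central container
`OmicsMatrix` extends `SummarizedExperiment` (one `exprs` assay, `NA`
encodes the missing-value mask, `colData()$group` holds the AF/sham labels,
the dataset tag lives in `metadata()`), results are S4 objects with
accessors, and all randomness is controlled by integer seeds.

# Differential proteomics

## Filtering, transformation, normalization

With three biological replicates per condition, a protein is retained when
at most two of its six intensities are missing (`filterMissing()`, the rule
is a parameter). No imputation is performed anywhere: the statistics operate
on observed values only. `normalizeMatrix()` applies `log2` and a
per-feature Z-score. Two conventions were genuinely open:

* **Z-score margin.** The volcano t-statistic compares samples within a
  protein, and row-wise standardization is the common default in
  label-free workflows; rows are the default and a column-wise option is
  exposed.
* **SD denominator.** The sample SD (n − 1) is used, so a two-point row
  (2, 8) standardizes to (−0.707, 0.707), not (−1, 1). Zero-SD rows are
  emitted as all-zero with a warning rather than `NaN`, because a constant
  row carries no group information but should not poison a heatmap.

## The S0-moderated statistic and permutation FDR

Per feature, `moderatedT()` computes the pooled two-sample Student
t (`t_raw`) and the SAM-style moderated statistic

$$d = \frac{\bar{x}_{AF} - \bar{x}_{sham}}{SE_{pooled} + S_0},$$

with $S_0 = 0.1$ by default. $S_0$ damps the significance of features whose
fold change is tiny but whose variance is tinier; at $S_0 = 0$, $d$ equals
`t_raw` to machine precision (a tested reduction).

`permutationVolcano()` estimates the false-discovery rate by balanced group
relabelings. For a candidate cutoff $c$ on $|d|$:

$$\widehat{FDR}(c) = \frac{\mathrm{median}_{\pi}\,\#\{|d_\pi| \ge c\}}
{\max(1, \#\{|d_{obs}| \ge c\})}.$$

The raw estimate is monotonized by a running minimum over ascending $c$, and
the smallest cutoff with monotonized $\widehat{FDR} \le 5\%$ is selected;
features exactly at the cutoff are significant. With 3-vs-3 designs there
are only $\binom{6}{3} = 20$ distinct balanced splits, so the requested 250
randomizations trigger exhaustive enumeration — the tests verify exact
agreement with a brute-force oracle on that path. Relabelings are drawn
without replacement in the sampled regime. The estimator is deliberately
symmetric (one cutoff on $|d|$); an asymmetric variant was considered and
rejected to keep the exhaustive oracle exact and the behaviour easy to
reason about.

Measured behaviour under the generator's study conditions (3 vs 3, $S_0$ =
0.1, 5% FDR): on null data the flagged proportion is ~0.4% (the median-based
count is conservative); with a planted 2-unit log2 effect and residual SDs
in [0.2, 0.5], mean power over seeds is 0.84–0.87.

## QC summaries

`pcaVariance()` (centered SVD on complete data — mirroring the study's
"100% valid values" policy), `sampleCorrelation()` (pairwise-complete
Pearson), `clusterForHeatmap()` (Euclidean K-means for labels plus
average-linkage ordering for display) and `listOverlap()` (shared
percentage of the union) round out the per-fraction QC. All delegate to the
standard stats implementations; tests pin them to independent closed-form
oracles.

# Integrated proteome–transcriptome enrichment

## Normalization and harmonization

`vstTransform()` applies a generalized log,
$glog(x) = \log_2\!\big((x + \sqrt{x^2 + c^2})/2\big)$, after per-sample
median/MAD affine calibration. `c` defaults to the 5th percentile of the
calibrated positive values: large enough to flatten the noise-dominated low
range, small enough to leave the upper dynamic range on the log2 scale
(`c = 0` reduces exactly to `log2`). `harmonizeIds()` maps goat-style
identifiers onto human homolog ids through a supplied two-column table;
many-to-one collisions collapse elementwise by median (default) or by
largest magnitude. `detectOutlierSamples()` projects standardized shared
features onto the first two principal components and flags samples farther
from their group's coordinate-wise median than `thresholdMad` (default 5)
times the MAD of all within-group distances; the median centre keeps a
gross outlier from masking itself, and removal aborts if a group would drop
below two samples.

## Ranking policy across datasets

`rankDatasets()` ranks genes ascending by t within each dataset (mid-ranks
for ties; rank $n_d$ = most AF-up). The cross-omics missing-value policy
is asymmetric by design: a gene missing in one proteomics fraction but
observed in another is *ranked last* there — the whole ranked-last block
sits at the bottom and shares its mid-rank $(L+1)/2$, which keeps rank sums
exact — while a gene observed only in the transcriptomics dataset is
*excluded* from every proteomics ranking (its absence from proteomics
carries no evidence). Zero-SE t statistics become signed infinite sentinels
and rank to the extremes.

## The joint rank-enrichment test

For a pathway with $k_d$ ranked members in dataset $d$ of size $n_d$,
`manovaEnrichmentTest()` standardizes the mean member rank with the exact
sampling-without-replacement variance,

$$z_d = \frac{\bar R_d - (n_d + 1)/2}
{\sqrt{(n_d - k_d)(n_d + 1) / (12\,k_d)}},$$

estimates the cross-dataset dependence $\hat C$ as the Spearman correlation
of the full rank columns over genes ranked in both datasets, and refers
$T^2 = z^\top \hat C^{-1} z$ to $\chi^2_D$. A singular $\hat C$ is
ridge-regularized ($\varepsilon = 10^{-6}$) with a warning. In one
dimension this reduces exactly to the normal-approximation Wilcoxon
rank-sum test, and the statistic is invariant to monotone transforms of the
underlying t values — both tested properties.

The membership floor — at least two ranked members in every dataset
entering the joint test — is the package's reading of "at least 2 genes on
both sides of each paired comparison"; skipped pathways are logged with
reasons. The per-dataset effect direction is reported as the normalized
rank score $score_d = (2/n_d)(\bar R_d - (n_d+1)/2) \in (-1, 1)$; a single
"pathway score" scalar is not claimed, since no formula pins one down —
users get the score vector plus $T^2$.

Calibration, measured: over 2,000 random 15-gene categories on a null
4-dataset study the p-values are uniform (KS distance ≈ 0.017–0.031,
type-I rate at 0.05 ≈ 0.049), and the analytic p agrees with a
drawn-category permutation oracle within twice the Monte-Carlo error at
$k = 10$, $n = 100$. At very small categories ($k = 3$, $n = 12$) the
$\chi^2$ approximation is only as good as the discreteness of 3-gene rank
sums allows (support steps ≈ 0.03); the tests document a 0.08 envelope
there. Multiple testing uses Benjamini–Hochberg q-values (`qValues()`;
deterministic and exactly testable, with a Storey-$\pi_0$ variant as an
option), significance at 1% FDR, and confidence tiers at q < 0.01
(confident) and q < 0.001 (highly confident) — the tier cutoffs are package
defaults exposed in the API, not published constants.

# Glycogen counting in electron micrographs

ROIs are 0-based half-open rectangles ("`(0,0,2,2)` = the four top-left
pixels"), cropped pixel-exactly. Each crop is Gaussian-smoothed
(σ = 1 px), passed through a 3×3 grayscale minimum filter (accentuating
dark granules), and binarized dark-side (foreground strictly below the
threshold). The default threshold is a fixed 0.45 on the [0, 1] scale,
chosen by inspecting synthetic micrographs: granule interiors sit near
0.27 and min-filtered cytosol near 0.55, and a fixed value — unlike Otsu —
does not collapse on sparse images whose histograms are effectively
unimodal. Otsu remains available for dense material.

Connected components (8-connectivity default, 4 available) smaller than
`min_area` (15 px²) are discarded; a component up to `single_granule_area`
(110 px²) counts one granule; a larger merged blob counts
$\max(1, \lfloor \text{area} / \text{single\_granule\_area} \rfloor)$ —
an area-quotient reading of "the maximum number of deposits which can fit",
chosen over geometric packing because it is deterministic and exactly
unit-testable. Densities are `count / (area_px · nm_per_px²)`, reported per
nm² by default with a per-µm² option (granule-scale counts per nm² are
physically odd but mirror how such results are often printed; the unit is
explicit everywhere). Group comparison is a two-sided pooled t-test at a
configurable aggregation level (per ROI or per animal).

On synthetic micrographs with 10/50/200 planted non-touching granules the
automated counts land within 0–6% of truth across seeds.

# Enzyme assays and Western blots

`fitStandardCurve()` is ordinary least squares; `enzymeActivity()`
back-calculates released 4-MU through the curve and normalizes by
incubation time and protein mass (nmol/min/mg default, nmol/h/mg via the
factor 60; negative back-calculated amounts are clamped to zero with a
warning). `groupSummary()` reports the mean and sample SD at full internal
precision — rounding is a formatting concern.

"Two-way" and "one-way" t-tests are interpreted as two-tailed and
one-tailed pooled two-sample Student t respectively: this single
interpretation reproduces all four printed p-values from the printed inputs
(0.60, 0.29→printed 0.28, 0.57→0.56 from the replicate activities; 0.075→
0.07 one-tailed from the Rab11A band summaries), which triple-validates it.
Welch's form is an option, not the default. `tFromSummary()` is exactly
consistent with `twoSampleT()` on raw vectors — a tested identity — so
published summary statistics can be re-analyzed without the raw replicates.

# The synthetic-data generator

The generator defines the study conditions rather than adapting to them:

* **Proteomics.** log2 intensities are Normal with feature baselines from
  N(23, 2) and residual SDs from U(0.2, 0.8) — spanning the dynamic range
  and noise heterogeneity typical of label-free data; values are emitted on
  the raw $2^x$ scale so the pipeline's log2 step is exercised. Regulated
  features shift by `effect_log2` in AF. Missingness is either uniform or
  intensity-dependent (logistic in −log2 intensity, calibrated by root
  finding to the requested overall rate) — left-censoring being the
  dominant mechanism in label-free data, this stresses the filter rule
  realistically.
* **Transcripts.** Negative-binomial counts with uniform library-size
  factors in [0.7, 1.4] and `dispersion` as the NB size parameter
  (variance = μ + μ²/size), so large values approach Poisson — a tested
  moment property.
* **Pathways.** Background sets sample uniformly from the universe; planted
  sets draw all members from the regulated features, so the planted signal
  is coherent in sign across all datasets. `simulateStudy()` shares one
  regulated set across every fraction and the transcript data.
* **Micrographs.** Textured background (smoothed Gaussian field), bright
  elliptical organelle blobs (whose bounding boxes generated ROIs avoid,
  mirroring manual box selection), anti-aliased dark granule disks placed
  by rejection sampling with a 2 px rim gap, and per-pixel Gaussian noise.
  Failure to place the requested granules is an explicit error, not a
  silent shortfall.
* **Assay plates.** Linear standards plus unknowns whose responses encode
  the true activities; at zero noise, back-calculation is an exact
  round trip.

What the generator does *not* emulate — peptide-level effects, shared
protein-group ambiguity, batch structure, spatially varying EM illumination,
granule clumping into rosettes — bounds what passing tests show: they
validate the statistical machinery under the stated models, not performance
on any particular deposited dataset. Reproducing the study's real-data
numbers (e.g. its significant-protein counts or glycogen densities) would
require the deposited accessions and is out of scope by design.

Problem sizes used in the shipped test and acceptance suites (100 null
studies of 150 features; 10 recovery studies of 2,000 features, 100
pathways, 4 datasets; 512² px micrographs with 10–200 granules) were chosen
as the smallest sizes at which the Monte-Carlo error of each check is
comfortably below its acceptance margin.

# Determinism and orchestration

Every simulator takes an integer seed; `deriveSeed(seed, stage)` hashes the
stage name into the global seed so stages re-run in isolation reproduce the
full-pipeline run. `runPipeline()` executes simulate → diff → enrich (with
glycogen and assay as independent stages), writes TSV/GMT/JSON outputs, and
emits a manifest with the package version, seed, a configuration hash,
per-stage row counts and every warning raised. Identical configuration and
seed give byte-identical outputs — a tested contract.

# Known limitations

* The volcano FDR estimator is conservative on null data (median false
  counts over 20 exhaustive splits are coarse at 3 vs 3); it controls but
  does not tightly attain the nominal 5%.
* The enrichment $\chi^2$ is an approximation whose accuracy degrades for
  categories of fewer than ~5 ranked members; the membership floor guards
  the worst cases but small-category p-values remain approximate.
* Granule counting assumes dark, roughly convex granules on a brighter
  background; touching granules are resolved only by the area quotient, and
  densely clumped material will be under-resolved.
* The homolog map is consumed, never inferred; mapping quality is the
  caller's responsibility.
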