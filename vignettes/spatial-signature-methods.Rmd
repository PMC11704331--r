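---
title: "Methods: spatial hotspot statistics and repression-signature survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial hotspot statistics and repression-signature survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

Pancreatic tumors (and many other carcinomas) are not transcriptionally
uniform: two antagonistic transcription-factor (TF) programs can occupy
different regions of the same tumor, and immune cells — macrophages in
particular — distribute unevenly around those regions. `spatsig` packages
the quantitative core of that kind of study:

1. **Spatial statistics on cell detections.** Whole-slide image analysis
   yields tables of cell centroids (micrometers) with marker classes. The
   package turns marker-positive detections into kernel density surfaces,
   segments "hotspots" (connected regions of high positive-cell density),
   and measures per-cell distances to competing hotspot classes.
2. **A TF repression signature.** Genes that a repressive TF binds, that
   rise when the TF is silenced, and that anti-correlate with the TF across
   an independent cell-line panel form a signature of lost repression.
   Samples are scored with a single-sample (GSVA-style) enrichment
   statistic and stratified for survival analysis.
3. **Virtual microdissection.** Xenograft bulk RNA-seq mixes graft (human
   tumor) and host (mouse stroma) reads; comparing each read's alignment
   scores against the two genomes separates compartment-specific
   transcriptomes.

Because the original slide coordinates and patient cohorts are not
redistributable, every input class has a seeded synthetic generator with
known ground truth; all quantitative claims in the test suite are made
against that ground truth or against independent oracle implementations.

# Spatial model

## Density maps

For marker-positive cells at positions $x_i$ the density surface at a pixel
center $p$ is the truncated Gaussian kernel sum

$$\hat\lambda(p) = \sum_i \frac{1}{2\pi h^2}
  \exp\!\left(-\frac{\lVert p - x_i\rVert^2}{2h^2}\right),$$

evaluated on a regular grid and truncated at $6h$ (discarded mass
$< 10^{-8}$ per cell). Coordinates are continuous micrometers, origin
top-left, y increasing downward — the convention of common whole-slide
exports. When sources sit at least $3h$ from the window edge,
$\sum \hat\lambda \cdot s^2$ recovers the source count within 2% (a test
enforces this over 100 random configurations).

**Defaults: bandwidth 50 µm, pixel 10 µm.** Imaging studies of this kind
rarely report their density-map parameters. For millimeter-scale tumor
sections, 50 µm smooths over a few cell diameters without erasing regional
structure, and a 10 µm pixel keeps the grid a factor of five below the
bandwidth so discretization error is negligible. Both are plain arguments.

## Hotspots

Pixels at or above a threshold (closed comparison) form a mask; 8-connected
components are regions; components below `min_area_um2` (default
10\,000 µm², roughly a 100 µm square — smaller islands are staining noise
at this scale) are dropped. The default threshold is the 0.90 quantile of
*positive-density* pixels: taking the quantile over all pixels would let
large empty slide areas drag the threshold toward zero.

Each region is stored both as a pixel set and as closed polygon rings
traced along the pixel boundary. Diagonally touching pixels belong to one
8-connected region whose rings meet at a pinch vertex; the tracer takes
the sharpest right turn there so rings touch but never cross. A test
confirms the shoelace area of the rings equals the pixel area exactly.

## Distances

The distance of a cell to a hotspot set is the Euclidean distance to the
nearest point of the nearest region boundary, 0 inside a region — the
"distance to annotation" behavior of slide-analysis tools, not distance to
a centroid. Point-in-region decisions treat the boundary as inside. The
implementation computes exact point-to-segment distances over the boundary
edge list; an oracle that densely samples the boundary at 0.01 µm agrees
within 0.05 µm on 50-cell instances (acceptance test). Serial-section
"transfer" of hotspots is modeled as the identity transform on shared
coordinates; no image registration is attempted.

For two competing hotspot classes the package reports per-cell distance
pairs and the fraction of cells strictly closer to each class; exact ties
count in neither side and are reported separately.

## Group comparison

Distance distributions are compared with the unpaired t-test with Welch's
correction, the convention in this literature. Degenerate inputs are
explicit: two constant samples with equal means give $t = 0, p = 1$;
constant samples with different means report the smallest representable
p-value with a `degenerate` flag rather than a silent zero.

# Signature model

## Peak-to-gene annotation

Binding peaks are assigned to genes with the basal-plus-extension rule of
GREAT-style annotation: a strand-aware basal domain (default 5 kb upstream,
1 kb downstream of the TSS) extended up to 1 Mb per side but never into a
neighboring gene's basal domain. Coordinates are 0-based half-open
throughout; overlap is computed with `GenomicRanges`. Curated regulatory
domains are out of scope.

## Derivation

The signature is a pure intersection filter:
bound genes ∩ genes up-regulated on TF silencing
(`p_adj <= 0.05`, `log2fc >= 0` by default — the study tradition reports
"significantly upregulated" without a fold-change floor, so the floor
defaults to 0 and both thresholds are recorded in the provenance) ∩ genes
with negative Spearman correlation to the TF across the cell-line panel.
Provenance records every intermediate set size, so a derived signature is
auditable and re-derivation is bit-identical.

## Single-sample scores

The scoring statistic follows the published GSVA construction: per gene a
kernel CDF across cohort samples (Gaussian kernel, bandwidth $\mathrm{sd}/4$;
an empirical-CDF option for counts), per sample a ranking of genes by that
statistic, symmetric rank weights $|N/2 - \mathrm{rank}|^{\tau}$ (default
$\tau = 1$), and a weighted random walk that steps up at signature genes
and down elsewhere; the score is the maximum positive plus maximum negative
walk deviation (max-diff scoring). These defaults mirror the cited
package's published defaults for continuous expression data. Two
consequences matter in practice:

* Scores are **relative within a cohort** — the kernel CDF is estimated
  across the supplied samples — so cohorts must be scored individually and
  never on a merged matrix. `gsva_scores` takes one cohort at a time by
  construction.
* Ties in the per-sample ranking are broken by gene order
  (deterministically), which only matters for degenerate constant genes.

The implementation is checked against a separately written, loop-based
oracle on small matrices (to $10^{-12}$) and against planted cohorts, where
the Spearman correlation between scores and the generating latent activity
is ≥ 0.8 at 200 samples (≈ 0.98 observed by the acceptance script).

## Preranked GSEA

For a gene list ranked by a score (e.g. correlation of every gene to the
TF), the running sum increments by $|s|^p$ (normalized within the set,
$p = 1$) at set genes and decrements by $1/(N - N_\mathrm{set})$ otherwise;
ES is the signed maximum deviation. The null shuffles gene labels — the
input is a correlation-ranked list, not a sample-label design, so sample
permutation is not applicable — with the seed an explicit argument. NES
divides ES by the mean |null ES| of matching sign, and the p-value is the
fraction of null ES at least as extreme. Calibration is tested: over 200
random sets the rejection rate at $\alpha = 0.05$ stays within
$[0.02, 0.09]$.

# Cohort statistics

* **Stratification.** Quartile groups use $k = \lceil n/4 \rceil$ lowest /
  highest scores with stable input-order tie breaking; this reproduces the
  155/309/155 split of a 619-patient merged cohort and never leaves an
  unassigned sample. Tertiles use the same rule with $\lceil n/3 \rceil$.
* **Kaplan–Meier / log-rank / Cox** are delegated to the `survival`
  package (`survfit`, `survdiff`, `coxph` with Breslow tie handling —
  documented; at the tie rates the generator produces, the
  Breslow–Efron difference is negligible). The median-survival convention
  is the smallest $t$ with $S(t) \le 0.5$, undefined (flagged) when the
  curve never reaches 0.5. Cox fits that run into monotone likelihood or
  non-convergence fail loudly with a diagnostic rather than returning a
  meaningless interval. Tests verify the partial-likelihood maximum
  against a grid-search oracle, type-I error calibration of the log-rank
  test, and CI coverage for a planted hazard ratio of 2.
* **Marker-mean scores and harmonization.** Population abundance proxies
  are arithmetic means of log-expression over curated marker genes.
  Cross-cohort harmonization min-max normalizes per cohort and population,
  pools, and divides by the reference-group mean so the reference group
  sits at 1 ("standardized to the mean" is read as division, matching a
  relative-score axis; a subtraction mode is available behind a flag).
  Min-max is affine-invariant, which a test exploits directly.

# Virtual microdissection

The full logic of xenograft read-filtering tools (mate-pair aware
edit-distance re-examination) is reduced to a documented score-margin
classifier: a read goes to the genome with the strictly higher alignment
score by more than `margin` (default 0), ties and sub-margin differences
stay unassigned (conservative), single-genome reads go to that genome.
Read conservation (graft + host + unassigned = input) is exact and tested,
as are label-swap symmetry and monotonicity of the unassigned count in the
margin. With a divergence penalty ten times the score noise, assignment
accuracy against generator ground truth exceeds 0.99 on 10\,000 reads.
Alignment itself and SAM/BAM parsing are out of scope: the input is a
per-read score table.

# Synthetic-data generator

The generator exists so every stage is testable against known truth:

* **Tissue** (`simulate_tissue`): a Thomas cluster process per TF class
  (parents Poisson at $5 \times 10^{-6}$/µm² in a 2 × 2 mm window ≈ 20
  clusters per class; 50 offspring per parent, displacement σ = 40 µm),
  cross-class parent exclusion of 300 µm enforced by rejection sampling
  with a 1000-attempt cap that fails loudly — silently relaxing the
  exclusion would corrupt the ground truth. Immune cells come from an
  inhomogeneous Poisson process, implemented by thinning a homogeneous
  proposal at `base + amplitude` (exact because the target intensity
  $\lambda(x) = \mathrm{base} + \mathrm{amplitude}\,e^{-d(x)/\rho}$ is
  bounded by the proposal rate). These sizes give a few thousand tumor
  cells and hotspots a few hundred micrometers across — the scale of the
  published whole-slide figures — while keeping a full spatial run in
  seconds.
* **Expression cohorts** (`simulate_expression_cohort`): a latent
  per-sample activity $u \sim N(0,1)$ shifts the 37 signature genes (the
  published signature size) by `effect_size`·u and drives exponential
  event times with hazard $h_0 e^{\gamma u}$ ($h_0 = 0.02$/month,
  $\gamma = \log 2$, uniform censoring to 120 months — realistic
  resected-cohort scales).
* **Cell-line panels** (`simulate_cellline_panel`): 46 lines (the panel
  size of the cited resource), genes constructed as
  $\mp c \cdot \mathrm{anchor} + \sqrt{1 - c^2}\,\varepsilon$ with
  $c = 0.7$, so sample correlations concentrate near $\mp c$ and are
  exactly $\mp 1$ at $c = 1$.
* **Read scores** (`simulate_dual_species_reads`): own-genome score
  $N(100, 2)$, wrong-genome deficit $N(20, 5)$ clamped at 0, 5% of reads
  unmapped on the wrong genome, 90% graft fraction — a typical xenograft
  mix.

All randomness flows through one seeded generator per call (the caller's
RNG state is saved and restored), so a config is a complete recipe:
identical seed and config give byte-identical output, which the pipeline
runner exploits to make run directories self-reproducing via stored
provenance (config + global seed + derived per-stage seeds).

**What the generator does not emulate:** nucleus-level image content,
stain variation, segmentation errors, batch effects across cohorts,
non-proportional hazards, mate-pair structure in reads. Passing tests
therefore demonstrate correctness of the statistics on idealized data with
the stated structure, not robustness to those real-data artifacts.

# Numerical choices and degenerate inputs

* Closed thresholding (`>=`) for hotspot masks; 8-connectivity.
* Point-in-region boundary-inclusive; distances exactly 0 inside.
* Quantile thresholds are taken over strictly positive density pixels.
* Empty marker classes yield an empty density map with a warning, not an
  error; an all-sub-threshold grid yields a valid empty hotspot set; an
  empty hotspot set makes *distance* computations fail loudly.
* Stable-order tie handling in stratification (documented; makes the
  all-ties case deterministic).
* Spearman p-values use the t-approximation with $n - 2$ df; zero rank
  variance is flagged, not silently 0.
* Cox Newton iterations run to a $10^{-10}$ tolerance with a 100-iteration
  cap inside `coxph`.

# Problem sizes used in the checks

The acceptance script and test suite run at the scales the analyses are
designed for: 619-sample stratification; ~1\,300–5\,000 immune cells on a
2 × 2 mm window for the distance contrast; 200-sample cohorts (1\,000
genes, 37 signature genes) for scoring fidelity; 5\,000-subject KM
calibration; 1\,000 null replicates for log-rank type-I error; 100
replicates at n = 2\,000 for Cox coverage; 10\,000 reads for assignment
accuracy. These sizes were chosen to make the Monte-Carlo bounds in the
tests tight while a full run stays in the low minutes on a laptop.

# Known limitations

* Hotspot polygons touching at pinch vertices are technically non-simple
  at that single point; downstream geometry treats regions as pixel sets,
  so this only affects exported GeoJSON aesthetics.
* The GREAT-style annotation implements the basal-plus-extension rule
  only, without curated domain exceptions.
* Multivariable Cox models, proportional-hazards diagnostics and interval
  censoring are out of scope, as is any normalization of microdissected
  counts.
* The published density-map parameters, hotspot threshold, and the exact
  cohort curation behind the printed survival numbers are not reported in
  the source literature; those numbers are therefore targets of structural
  (synthetic-analogue) reproduction, not exact numeric reproduction.
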