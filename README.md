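# spatsig

Spatial hotspot and repression-signature analysis for tumor tissue.

Carcinomas such as pancreatic ductal adenocarcinoma carry regionally
heterogeneous transcription-factor (TF) programs: mutually exclusive
TF-high tumor regions coexist within one tumor, and immune cells —
macrophages in particular — distribute unevenly around them, with
consequences for subtype identity and patient outcome. `spatsig` is an R
package for the quantitative backbone of such studies, aimed at
computational biologists working with whole-slide cell detections,
expression cohorts with survival data, and xenograft RNA-seq.

## What it computes

**Spatial statistics on cell detections.** From a table of cell centroids
(µm) with marker classes:

- Gaussian kernel density maps of marker-positive cells,
  $\hat\lambda(p) = \sum_i (2\pi h^2)^{-1} e^{-\lVert p-x_i\rVert^2/(2h^2)}$
  (default bandwidth $h$ = 50 µm, pixel 10 µm);
- hotspot segmentation: pixels at or above a density threshold (default
  0.90 quantile of positive pixels), 8-connected components, minimum-area
  filter, polygon contours;
- positive-cell fractions inside hotspots, and per-cell Euclidean
  distances to the nearest hotspot boundary (0 inside), including paired
  distances to two competing hotspot classes with tie-aware
  "closer-to-A" fractions;
- Welch two-sample t-tests for distance contrasts.

**Repression-signature derivation and scoring.** Genes that are TF-bound
(GREAT-style basal-plus-extension peak annotation: 5 kb/1 kb basal domain,
up to 1 Mb extension truncated at neighboring basal domains), up-regulated
on TF silencing (adjusted p ≤ 0.05), and Spearman-anti-correlated with the
TF across a cell-line panel form the signature. Samples are scored with a
GSVA-style single-sample statistic (Gaussian kernel CDF, symmetric rank
weights, max-diff random-walk score) and gene lists are tested with
preranked GSEA (weighted running sum, seeded gene-label permutation null).

**Cohort survival statistics.** Rank-based quartile/tertile stratification
(k = ⌈n/4⌉ per extreme group, stable tie order — a 619-patient cohort
splits 155/309/155), Kaplan–Meier curves with median survival
(smallest t with S(t) ≤ 0.5), log-rank tests, Cox proportional-hazards
ratios with 95% Wald intervals (Breslow ties), marker-mean immune
population scores, and min-max cross-cohort harmonization standardized to
a reference group.

**Virtual microdissection.** Per-read graft/host assignment from
dual-genome alignment scores by a conservative score-margin rule, with
exactly conservative compartment count matrices.

**Synthetic-data generation.** Seeded generators for every input class —
clustered two-class TF tissue with immune attraction (Thomas cluster
process + inhomogeneous Poisson thinning), expression cohorts with a
planted signature driving a proportional-hazards survival model,
anchor-correlated cell-line panels, and dual-species read scores — so the
full pipeline is testable without external data.

## Worked example

Simulate a tumor with immune cells attracted to the TF_A regions, segment
hotspots of both TF classes, and measure the immune-distance contrast:

```r
library(spatsig)

sim <- simulate_tissue(tissue_sim_config(seed = 42,
  immune_baseline_intensity = 5e-5, immune_attraction_amplitude = 1.5e-3))
win <- c(0, 0, 2000, 2000)

hs_a <- derive_hotspots(
  compute_density_map(sim$cells, "TF_A", bandwidth = 50, pixel_size = 10,
                      window = win),
  "quantile", 0.9, min_area_um2 = 10000, class_label = "TF_A")
hs_b <- derive_hotspots(
  compute_density_map(sim$cells, "TF_B", 50, 10, window = win),
  "quantile", 0.9, 10000, class_label = "TF_B")

d_a <- distance_to_hotspots(sim$cells, "IMMUNE_1", hs_a)
d_b <- distance_to_hotspots(sim$cells, "IMMUNE_1", hs_b)
d_a; d_b
#> Distances of 1395 cells to hotspots: mean 114.8 um, sd 132.1 um
#> Distances of 1395 cells to hotspots: mean 352.0 um, sd 206.4 um
welch_test(d_a$per_cell$distance_um, d_b$per_cell$distance_um)
#> Welch t-test: t = -36.15, df = 2372.68, p = 2.216e-228
shortest_distance_pairs(sim$cells, "IMMUNE_1", hs_a, hs_b)
#> Distance pairs over 1395 cells: 81.4% closer to A, 18.6% closer to B, 0 ties
```

The immune population sits on average 114.8 µm from the attracted-class
hotspots but 352.0 µm from the other class — the synthetic analogue of a
macrophage-to-hotspot distance contrast — and >80% of individual immune
cells are strictly closer to the attracted class.

Score a survival cohort with a planted prognostic signature, stratify into
quartiles, and estimate the upper-vs-lower hazard ratio:

```r
cohort <- simulate_expression_cohort(cohort_sim_config(seed = 42,
  n_samples = 1000, n_genes = 500, signature_size = 37,
  log_hr_per_score = log(2)))
sc <- gsva_scores(cohort$expr, cohort$signature_genes)
strat <- stratify_quartiles(sc)
strat
#> Stratified cohort of 1000 samples:
#> group
#> lower   mid upper
#>   250   500   250
grp <- strat$assignment$group[match(cohort$survival$sample_id,
                                    strat$assignment$sample_id)]
keep <- grp %in% c("lower", "upper")
cox_hr(cohort$survival[keep, ], droplevels(grp[keep]), reference = "lower")
#> Cox proportional hazards (Breslow ties): HR = 5.057 (95% CI 3.900-6.557), p = 2.21e-34
km_estimate(cohort$survival[grp == "upper", ])
#> Kaplan-Meier curve: 250 subjects, 199 events; median survival 15.86
km_estimate(cohort$survival[grp == "lower", ])
#> Kaplan-Meier curve: 250 subjects, 94 events; median survival 75.2
```

High signature scores mark markedly shorter survival (median 15.9 vs 75.2
months; HR 5.06 with the CI far from 1) — the generator plants a log(2)
hazard increase per unit latent score, and the score → quartile → Cox
chain recovers a strong, correctly signed effect.

A thin command-line wrapper over the same functions ships at
`inst/cli/spatsig.R` (subcommands `run`, `density`, `hotspots`,
`distances`, `stratify`, `microdissect`), and `run_pipeline()` executes
multi-stage runs from a JSON config with full provenance.

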