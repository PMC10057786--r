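---
title: "Methods: coupling peat organic geochemistry with NBR time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling peat organic geochemistry with NBR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatsense)
```

This vignette is the package's account of its science: the measurement
models it implements, the assumptions behind the synthetic-data generator,
and the numerical and design choices made where the methodology is
genuinely open. Nothing stated here as a result is asserted anywhere except
where the test suite or the acceptance script computes it.

## 1. The measurement chain

The workflow joins three measurement systems at the level of a *site*:

1. **Rock-Eval (6) pyrolysis** of peat sub-samples taken down a core.
   The instrument program is a 3-minute isothermal hold at 200 °C (free
   hydrocarbons, S1), a pyrolysis ramp at 25 °C min⁻¹ to 650 °C (bound
   hydrocarbons cracking, S2, with FID detection), then an oxidation ramp
   300→850 °C at 20 °C min⁻¹ (residual carbon released as CO and CO₂,
   infrared detection). `temp_program()` encodes this program and is
   configurable.
2. **Carbon accounting** per core: bulk density from segment dry mass over
   the corer chamber volume, carbon density per segment, summed stocks.
3. **Optical remote sensing**: per-year NBR from NIR and SWIR-2 surface
   reflectance, and per-pixel mean / temporal standard deviation over the
   multi-year stack.

Rank statistics (Spearman, rank-sum, Kruskal–Wallis, pairwise Wilcoxon
with Bonferroni) relate the per-site summaries because n is small (11
sites) and none of the quantities can be assumed Gaussian.

### Thermal-stability indices

The S2 pyrogram is partitioned into four windows: A1 = 200–340 °C,
A2 = 340–400 °C, A3 = 400–460 °C, A4 > 460 °C, each reported as a
percentage of the total S2 area. The refractory index is
R = (A3 + A4)/100 and the immature index is I = log₁₀((A1 + A2)/A3).
The literature sometimes prints the R formula with ambiguous
parenthesisation; this package reads it as (A3 + A4)/100, the only reading
consistent with the percentage convention shared by the I-index and with R
values reported around 0.5–0.65 for tropical peat. Windows are half-open
[lo, hi) with A4 unbounded above; the boundary assignment of mass exactly
on a node edge is not specified by the method's sources, and with
continuous signals it carries zero area, so the choice is inconsequential.

The I-index is undefined when A3 = 0 or A1 + A2 = 0. Such samples are
returned as `NA` with a warning and excluded (with a count) from layer
summaries — flagged, never silently dropped.

### TOC, HI, OI

TOC (wt %) is assembled from the three carbon pools:
`TOC = 0.083·(S1 + S2) + (12/280)·S3_CO + (12/440)·S3_CO₂`, the standard
Rock-Eval 6 stoichiometry (0.083 wt % C per mg g⁻¹ of hydrocarbons; carbon
mass ratios for CO and CO₂ with the factor 10 mg g⁻¹ → wt % folded in).
The factors are configurable via `toc_factors()`. HI = 100·S2/TOC and
OI = 100·S3_CO₂/TOC. The oxidation-phase integration windows for S3 CO and
S3 CO₂ are configurable and default to the full provided curves, because
the instrument software's exact windows are not published; narrowing them
only rescales S3 and OI and does not touch the S2-based indices the
analysis rests on.

### Depth layers

Segments are stratified as: `upper50` (bottom within 50 cm of the
surface), `below_water_table` (segment within 50 cm below the water
table), `deep` (within 50 cm of the underlying clay), else `other`. A
segment matching several rules takes the shallowest applicable label, so
every sample sits in exactly one bucket. Litter samples carry their own
`litter` label and never enter stocks. The water table default is 0.4 m
below the surface — a dry-season value (sampling campaigns for this kind
of study run in the dry season; in the wet season the table is near the
surface) — and is configurable per scenario.

### Carbon stocks

Bulk density uses the half-cylinder Russian-corer chamber,
π·2.5²·10/2 = 98.17 cm³ per 10 cm increment, as a configurable constant
(other corers differ). Carbon density is bd × (TOC/100) × thickness in
g cm⁻², and the whole unit chain is kept in one place:
1 g cm⁻² = 10⁴ g m⁻² = 10⁸ g ha⁻¹ = 100 Mg ha⁻¹. Rock-Eval is run on
selected sub-samples rather than every segment, so unmeasured segments
take linearly depth-interpolated TOC between measured neighbours
(constant-extrapolated at the core ends); the interpolation rule is a
package choice — the field literature does not state one — and splitting
segments at constant bd and TOC provably leaves stocks unchanged (tested
as an additivity property). Vegetation carbon applies the conventional
0.47 carbon fraction to above-ground biomass.

### Remote sensing

NBR = (NIR − SWIR2)/(NIR + SWIR2) ∈ [−1, 1], undefined (nodata) where
both bands are zero. Stack statistics use the *sample* (n−1) standard
deviation, matching the default of the R raster tooling this kind of
analysis is normally run with; pixels with fewer than two valid years get
nodata sd, and a pixel's statistics use its valid years only. Site
extraction takes the nearest pixel (the containing cell) with no
interpolation or neighbourhood averaging — the simplest defensible rule
when the source analysis does not state one. Distances to the river and
canal networks are planar point-to-segment minima and therefore require
projected metre coordinates; geographic (degree) input is rejected with an
instruction to project rather than silently producing meaningless numbers.
Normality screening of pixel series (`normality_check()`) applies
Shapiro–Wilk to a seeded random sample of pixels rather than to every
pixel; constant series are flagged undefined.

Because no raster I/O stack is assumed, rasters live in a lightweight
matrix container (`scene_stack`) with a north-up metre geotransform, and
persistence uses the plain-text ESRI ASCII grid format; polylines use
GeoJSON with an explicit units marker.

### Rank statistics

`spearman_rank()` reports S = Σ(rank differences)² alongside rho; without
ties rho = 1 − 6S/(n(n²−1)), with ties it is the Pearson correlation of
mid-ranks. `rank_sum_w()` follows the `wilcox.test` convention in which W
is the Mann–Whitney U of the first group (range [0, n_a·n_b]; complete
separation of 11 vs 11 gives W = 121); p-values are exact for tie-free
samples with n_a·n_b ≤ 400, otherwise normal approximation with
continuity correction. All tests are two-sided. Pairwise comparisons use
the Bonferroni cap p_adj = min(1, p·m). Reported W values in the source
literature occasionally carry a "d.f. = 1" annotation; a rank-sum test has
no degrees of freedom and the package does not reproduce that notation.

## 2. What the synthetic generator emulates

The generator is first-class, tested code. It encodes the study *design*
— not any dataset — so the pipeline's behaviour can be validated against
constructed truth.

**Decomposition with depth.** Each segment's S2 mass is spread over four
Gaussian thermal components centred at 310/370/430/500 °C (σ = 15 °C):
mid-window placements for A1–A3 and a representative >460 °C centre for
the char pool, since the method's sources give only window bounds. Pool
fractions follow a linear depth trend (labile declining, refractory
rising) placed so a pristine profile drifts from R ≈ 0.50, I ≈ +0.19 near
the surface to R ≈ 0.64, I ≈ 0 at depth — inside the ranges reported for
intact tropical peat — with Gaussian jitter (σ = 0.012) per segment.

**Disturbance.** A scenario's `upper_labile_depletion` removes that
fraction of the labile (A1 + A2) mass from segments in the upper 50 cm.
Removal, not renormalisation: S2 and TOC fall with it, which is what
couples thermal stabilisation to a lower upper-50 cm carbon stock. The
oxidation-phase pools are depleted at half that rate, so HI also falls
with disturbance. Class defaults order depletion by disturbance severity —
CentralForest 0, ManagedRecovery 0.30, DisturbedForest 0.40, FireAffected
0.50 — consistent with the class descriptions (fire-affected scrub the
most degraded), and NBR parameters follow the same ordering (baselines
0.55/0.48/0.38/0.25; temporal sd 0.03/0.07/0.10/0.14).

**Scale anchors.** Segment dry masses are drawn so bulk density centres
on 0.10 g cm⁻³ (sd 0.008). The undepleted S2 base of 220 mg HC g⁻¹, with
the default TOC factors and oxidation pools at 0.32× and 5.6× S2, puts
TOC near 55 wt % and HI near 400 mg HC g⁻¹ TOC — inside the 300–475 band
reported for intact profiles — and makes per-core stocks land at the
10³ Mg ha⁻¹ order. Peat depths are uniform on 0.5–3.5 m (the reported
range); within-class depth variability is a free parameter nowhere
published, and depth is drawn independently of class, which keeps
whole-profile stock essentially uncorrelated with the remotely sensed
covariates — the null result expected for the full profile.

**Rasters.** Every pixel takes the class of its nearest site (a Voronoi
partition), a spatial baseline jitter (σ = 0.02), and i.i.d. Gaussian
year-to-year anomalies with the class temporal sd. Bands are backed out
from NBR at a fixed NIR + SWIR2 total of 0.5, which keeps reflectances in
[0, 1] for any NBR in [−1, 1].

**What it does not emulate** — and what passing tests therefore do not
show about real data: no spatial autocorrelation beyond the class
partition, no cloud or atmospheric artefacts, no mixed pixels at class
boundaries, no vegetation regrowth dynamics or fire-event timing, no peat
hydrology (the water table is a constant), no clay banding or marine
intrusions in deep peat, and no measurement error model for the corer
(compaction, gaps). The directional acceptance simulations show the
pipeline recovers a disturbance signal *of the constructed kind*; they
are not evidence about effect sizes in any real peatland.

**Determinism.** All randomness flows from one integer seed
(`withr::with_seed`); a fixed seed reproduces cores, rasters and written
CSVs byte-for-byte. Paired-seed scenarios share their base draws, so
depletion is the only difference within a pair.

## 3. Sub-sampling and orchestration

`generate_core(measure = "stratified")` analyses every upper-50 cm
segment, every second deeper segment and the basal one, exercising the
TOC-interpolation path by default; `measure = "all"` analyses everything.
`run_analysis()` chains generation → Rock-Eval → stocks → NBR →
correlations and returns a tidy `peat_analysis` object (with `tidy()`,
`glance()`, `autoplot()`, `write_report()`). The correlation screen
computes the two upper-50 cm relationships (stock vs NBR sd, HI vs NBR
mean) plus a whole-profile screen of five variables (stock, HI, OI, R, I
core means) against all four covariates (NBR mean, NBR sd, river and
canal distances) — exactly the covariates the pipeline computes, no more.
Layer summaries report medians and IQRs with linear-interpolation
(type 7) quartiles, both per class and for the pooled disturbed grouping
(DisturbedForest + FireAffected + ManagedRecovery).

## 4. Numerical choices

- Temperature grid: 1 °C steps along the pyrolysis ramp (2.4 s at
  25 °C min⁻¹); the hold phase contributes plateau samples on the same
  time step. Halving the step changes S2 by < 0.1 % (tested).
- The FID curve is per-second on a time axis, since the hold phase sits at
  constant temperature; S1 and S2 are trapezoid integrals over time, and
  node windows select ramp samples by temperature with linear
  interpolation of the integrand at window edges, making node areas
  insensitive to grid placement.
- Gaussian components are truncated by the finite ramp; with the default
  centres and widths the lost mass is far below the 0.5 % integration
  tolerance. Components ≥ 3σ inside their windows are recovered to within
  1 % absolute node area (closed-form normal-CDF oracle in the tests).
- Ties: mid-ranks everywhere; Spearman falls back to Pearson-on-ranks,
  Kruskal–Wallis applies the standard tie correction.
- Degenerate inputs error distinctly: zero total S2 area, TOC = 0,
  all-identical Kruskal–Wallis input, constant Spearman vectors, ramps
  not reaching 460 °C, sites outside the raster, inverted depth
  intervals, geographic-degree geometry.

## 5. Problem sizes

The replicate simulations in the tests and the acceptance script use the
full study design (11 cores, 5 years) on a 12 × 12 pixel grid with
stratified sub-sampling — about 150 pyrograms per run — and 100 replicate
runs per condition, with 100 paired-seed core comparisons for the
depletion contrast. These sizes give stable directional rates (binomial
standard error ≈ 2–5 percentage points) while keeping a full suite run in
minutes on one CPU.

## 6. Known limitations

- The generator's class parameters are plausible defaults, not fitted
  values; only orderings and broad ranges are anchored to published
  numbers.
- OI values produced by the default oxidation pools are much larger than
  typical instrument OI, because the full oxidation curves (which carry
  the residual carbon needed for a realistic TOC) are integrated as
  S3 CO₂; OI enters the analysis only through rank correlations, which
  are invariant to that scaling.
- Nearest-pixel extraction ignores sub-pixel position and neighbourhood
  averaging; with 30 m pixels and point cores this is a real but
  unquantified source of noise.
- The Spearman screen treats sites as independent; there is no spatial
  autocorrelation correction (out of scope).
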