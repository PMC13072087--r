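---
title: "Decomposing climatic niche breadth: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing climatic niche breadth: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebreadth)
```

## The scientific problem

A species' climatic niche breadth — the span of temperature or
precipitation conditions across its occupied localities — can arise in
two very different ways. It can be generated *within* localities, by
seasonal variation that every population experiences in place, or
*among* localities, by spatial climate differences across the
geographic range. Distinguishing the two matters: a breadth generated
by seasonality implies broad tolerance in every population, while a
breadth generated by geography is compatible with locally narrow,
spatially turned-over tolerances.

`nichebreadth` implements the full analysis chain used to ask this
question for a clade of terrestrial ectotherms: occurrence-record
quality control, species-level niche statistics from six bioclimatic
variables (Bio1, Bio5, Bio6 in °C; Bio12, Bio16, Bio17 in mm), a
within- vs among-locality decomposition, and phylogenetic regressions
that account for shared ancestry. Because real occurrence compilations
of this kind are not redistributable, the package also ships a
synthetic-data generator with recorded ground truth, so every estimator
can be validated by recovery experiments rather than by eyeballing.

## Niche statistics

Each georeferenced occurrence point is treated as one "locality" (one
~1 km² climate cell). For the records of one species (or one
species-by-region group):

* **Positions**: mean Bio1 (temperature position) and mean Bio12
  (precipitation position).
* **TNB** = max Bio5 − min Bio6: temperature niche breadth.
* **PNB** comes in two variants: the range of Bio12 (`pnb_annual`,
  spatial heterogeneity only) and max Bio16 − min Bio17
  (`pnb_wetdry`, spatial *and* seasonal variability).
* **Within-locality breadths** TNB~WL~ = mean(Bio5 − Bio6) and
  PNB~WL~ = mean(Bio16 − Bio17): the average seasonal span at a single
  locality.
* **Breadth ratios** TNBR~WL-S~ = TNB~WL~ / TNB per region, averaged
  (unweighted) over a species' occupied regions; likewise for
  precipitation with PNB~wetdry~ in the denominator. A ratio near 1
  means seasonality, not geography, generates the species' breadth.
* **Position variances** TNPV and PNPV: sample variances (n − 1) of
  the per-locality midpoints (Bio5 + Bio6)/2 and (Bio16 + Bio17)/2 —
  a direct among-locality variability measure; defined as 0 for a
  single locality.

Three choices here were genuinely open and deserve a word:

* **Ratio denominators are regional.** For a multi-region species, the
  ratio is formed inside each region and the per-region ratios are then
  averaged, rather than dividing by the cross-region breadth. This is
  the reading consistent with computing "the ratio for each region,
  then the mean ratio per species"; `ratio_denominator = "species"`
  switches to the pooled denominator for sensitivity analysis.
* **Midpoint variances are across localities by default.** The
  alternative reading — variance of per-region mean midpoints — is
  degenerate (exactly 0) for every single-region species, which in a
  typical compilation is almost all of them, so it cannot produce the
  reported region-level regressions; it remains available via
  `midpoint_variance = "region"`.
* **Which PNB feeds the regressions.** Because PNB~WL~ is defined from
  Bio16 − Bio17, the wet/dry index is the denominator-consistent
  choice and the default (`pnb_index = "wetdry"`); the annual index is
  computed and reported alongside, and can be selected instead.

Zero breadths (a species known from a single, climatically uniform
locality) would make the ratio 0/0; it is pinned to 1 with a warning,
since such a species' breadth *is* its within-locality breadth.

## Occurrence quality control

Records duplicated within a species at the same coordinates (snapped to
a 10^−4^-degree grid, ~11 m) are collapsed to the first occurrence.
Climatic outliers are then screened per species (per species × region
when regions are in play) and per variable, with the method chosen by
sample size, mirroring common GIS practice:

* **n < 20**: the 1.5 × IQR rule. Quartiles use linear interpolation
  between order statistics (`stats::quantile` type 7); legacy GIS
  tools do not document their convention, so it is configurable.
* **n ≥ 20**: a reverse-jackknife gap test. Values are sorted; the gap
  between consecutive order statistics is compared with
  C = (0.95·√n + 0.2)·range/50. Walking inward from each end over the
  outer decile of the sorted vector, the innermost gap exceeding C cuts
  off everything outside it. Two aspects of the walk are deliberate.
  "Innermost gap wins" makes a *cluster* of aberrant records separated
  from the body by one large gap flag as a whole, where a walk stopping
  at the first subcritical gap would miss it entirely. And the walk
  depth is capped at the outer decile because an outlier screen
  presumes outliers are a minority: at a few dozen observations C is
  small enough (≈ 0.1 × range) that gaps near the median of continuous
  data are routinely supercritical, and an uncapped walk can amputate —
  in the worst case eliminate — a perfectly clean sample.

A record flagged on any of the six variables is removed, and every
decision (method, variable, offending value, threshold) is written to
the QC report.

The critical value's √n·range scaling gives the jackknife a bounded
operating regime worth knowing about: for very large samples
(n ≳ 700 for a 10-SD displacement; C exceeds the whole range near
n ≈ 2700) no single point can open a supercritical gap, and the screen
goes inert; just above the n = 20 switch it is at its most
trigger-happy. The package's QC recovery experiment (in the test suite
and the acceptance script) therefore draws locality counts log-uniform
on [60, 250] — squarely inside the regime where the method is
informative — and there recovers ≥ 90% of injected 10-SD outliers with
≲ 1% false positives. Outside that regime the numbers degrade for the
reasons above, which is a property of the published screen, not of this
implementation.

## Phylogenetic regression

All cross-species regressions are generalized least squares with error
covariance σ²·V~λ~, where V is the phylogenetic variance–covariance
matrix (V[i,j] = root-to-MRCA depth of tips i, j) and V~λ~ multiplies
the off-diagonal entries by Pagel's λ ∈ [0, 1]. λ is estimated by
maximum likelihood; the branch-length power transforms κ and δ are left
at 1. Numerical choices:

* Everything runs through the Cholesky factor of V~λ~ (whitening); V is
  never inverted explicitly. An explicit-inverse textbook oracle is used
  in the tests, never in the fit.
* The λ profile is maximized by bounded scalar search (tolerance 10^−6^)
  restarted on [0, 0.5], [0.25, 0.75], [0.5, 1], with both endpoints
  evaluated explicitly — a flat or bimodal profile cannot trap the
  optimizer, and the reported optimum dominates λ = 0 and λ = 1 by
  construction. The test suite additionally checks it against a 10^−4^
  grid.
* λ is bounded to [0, 1]: values above 1 can break positive
  definiteness, and the estimates this analysis produces never call for
  them.
* σ̂² is the ML estimate (n denominator); the slope test uses the
  unbiased whitened residual variance RSS/(n − 2) and a t reference
  with n − 2 df, matching the conventional PGLS summary. r² is
  1 − RSS/TSS in the whitened space, with TSS from the GLS
  intercept-only fit under the same V~λ~.
* Perfect fits floor σ̂² at 10^−12^ and flag the fit degenerate rather
  than returning an infinite likelihood.
* Missing data are dropped pairwise per regression and the tree is
  re-pruned per model.

Trees need not be ultrametric (the fit only needs V), polytomies are
accepted as-is, and zero-length terminal branches only warn — they
break the fit only when two tips become identical covariance rows, and
that is caught at Cholesky time with an informative error.

On a star phylogeny, or with λ fixed at 0 on an ultrametric tree, the
whole machinery collapses to OLS; the acceptance checks verify this to
10^−8^, and verify the independent `nlme::gls` + `ape::corPagel` ML fit
is matched on interior-λ problems.

## The synthetic generator: what it emulates, and what it does not

`simulate_occurrences()` builds an occurrence table whose variance
structure is controlled, so the decomposition has known truth:

* **Within-locality component**: each species draws a baseline seasonal
  half-amplitude from `seasonal_amplitude_range` (default 5–18 °C); each
  locality's amplitude adds `amplitude_lat_gradient` × |latitude|
  (default 0.15 °C per degree — seasonality grows toward the poles, the
  coupling that produces the familiar negative breadth–position
  relationship in ectotherm compilations) and a ±2–10% jitter. Bio5 =
  T + a, Bio6 = T − a, and Bio1 falls inside that interval.
* **Among-locality component**: the locality mean T follows a
  latitudinal gradient (`spatial_gradient_temp`, default 0.6 °C per
  degree — the magnitude of the real-world decline of mean annual
  temperature with latitude), localities scatter around a species
  range centre (SD 3°), and annual precipitation is a per-species
  level (log-uniform 150–2500 mm) times a log-normal spatial field.
* **Internal consistency**: every record satisfies Bio6 ≤ Bio1 ≤ Bio5
  and 0 ≤ Bio17 ≤ Bio16 ≤ Bio12, plus Bio16 + Bio17 ≤ Bio12 (the
  wettest and driest quarters cannot jointly exceed the annual total —
  real bioclim layers obey this even though it is rarely stated).
* **Locality counts** are log-uniform on [2, 3082] by default,
  matching the span of a real compilation of this type; the analytic
  mean of that distribution is ≈ 420 localities per species — the same
  order as, though above, the empirical ~243 of the motivating
  compilation, whose counts are more bottom-heavy than log-uniform.
* **Regions** are three contiguous longitude bands standing in for an
  Africa/Asia/Oceania partition, with range centres sampled
  0.17/0.52/0.31 — species near band edges naturally spill across and
  become multi-region.
* Optional injected exact duplicates and 10-SD climatic outliers
  (temperature shifted additively, precipitation scaled
  multiplicatively, so all record-level orderings survive) carry
  ground-truth labels for QC testing.

Two preset configurations pin down the decomposition's directionality.
`high_seasonality_params()` (amplitudes 12–18 °C, gradient 0.05 °C/deg,
amplitude jitter 2%) makes breadth within-generated: the mean breadth
ratio exceeds 0.95. Note the jitter matters — variation of seasonal
amplitude *across* localities is itself an among-locality component and
caps the ratio at 1/(1 + jitter), which is why the preset nearly
switches it off. `high_gradient_params()` (amplitudes 1–6 °C, gradient
1.2 °C/deg, range SD 6°) makes breadth spatially generated (mean ratio
≈ 0.2) while keeping amplitude variation across species wide enough
that the positive within-breadth → breadth relationship stays
statistically detectable. The directionality experiments draw locality
counts on [50, 200] so realized spatial extents are comparable across
species.

What the generator does **not** emulate: spatial autocorrelation of
residual climate noise, coastlines and real geography, sampling bias
toward accessible localities, taxonomic error, or any covariance
between a species' niche traits and its position in the phylogeny
(climate fields and the simulated tree are independent unless traits
are simulated on the tree explicitly). Passing recovery tests therefore
demonstrate that the estimators compute what they claim on data with
known structure — not that any particular empirical compilation is
clean or that its regressions are causal.

## Problem sizes used by the validation suite

The recovery experiments fit 200-tip trees with 200 replicates per
(λ, slope) cell over λ ∈ {0, 0.5, 1} × slope ∈ {−0.6, 0, 0.75}; the
λ-grid cross-check uses 20 random 50-tip problems at a 10^−4^ grid; the
metric-identity sweep uses 1000 synthetic species under default
generator settings; the end-to-end example runs 100 species with up to
500 localities each. At these sizes the whole suite completes in a few
minutes on one core, and mean λ̂ lands within 0.1 of truth with slope
bias indistinguishable from zero at Monte-Carlo resolution.

## Known limitations

* Single-predictor PGLS only — no multiple regression, model
  selection, OU or Blomberg-K alternatives, and no confidence interval
  on λ̂.
* The λ profile is maximized per model; uncertainty in λ̂ is not
  propagated into the slope test (standard practice, but worth
  remembering at small n).
* The jackknife screen inherits the operating-regime caveats above;
  for samples of thousands of records per species it will flag
  nothing, and the IQR rule should be forced if screening is still
  wanted (`method = "iqr"`).
* Region assignment is by longitude band; real regional boundaries
  (and species that straddle them) need region labels supplied in the
  input table.
* `pnb_annual`-based ratios are not defined (the within-locality
  numerator Bio16 − Bio17 does not correspond to a Bio12 range); the
  annual index participates only as a breadth response.
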