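# nichebreadth

Macroecological analysis of species climatic niche breadth from
georeferenced occurrence records, for comparative biologists asking
*where a species' climatic tolerance comes from*: is the span of
conditions it occupies generated **within** localities, by seasonal
variation every population experiences in place, or **among**
localities, by spatial climate differences across its geographic
range? The package provides the full chain — occurrence quality
control, niche statistics, a within/among-locality decomposition, and
phylogenetic regressions — together with a synthetic-data generator
with recorded ground truth, so every estimator is validated by
recovery experiments.

## What it computes

From an occurrence table (one row per point: species, lon, lat,
optional region, and the bioclim values Bio1/Bio5/Bio6 in °C and
Bio12/Bio16/Bio17 in mm) and a rooted Newick phylogeny:

* **QC** (`deduplicate_occurrences`, `apply_qc`): coordinate
  deduplication on a 10⁻⁴-degree grid, then per-species climatic
  outlier screening — 1.5 × IQR for small samples (n < 20), a
  reverse-jackknife gap test with critical value
  C = (0.95·√n + 0.2)·range/50 for larger ones — with every decision
  recorded in a QC report.
* **Niche statistics** (`summarize_niches`): temperature niche breadth
  TNB = max Bio5 − min Bio6; precipitation breadth as the Bio12 range
  and as max Bio16 − min Bio17; niche positions (mean Bio1, mean
  Bio12); mean within-locality breadths TNB_WL = mean(Bio5 − Bio6) and
  PNB_WL = mean(Bio16 − Bio17); the breadth ratios TNBR_WL-S =
  TNB_WL/TNB and PNBR_WL-S (per region, averaged over a species'
  regions); and the midpoint position variances TNPV, PNPV — all per
  species × region and per species.
* **PGLS** (`fit_pgls_lambda`): generalized least squares with error
  covariance σ²·V_λ, where V is the phylogenetic variance–covariance
  matrix and Pagel's λ ∈ [0, 1] rescales its off-diagonal entries; λ is
  estimated by maximum likelihood (κ = δ = 1), everything runs through
  Cholesky factors, and the fit reports λ̂, coefficients, r², and a
  two-sided t test on the slope (n − 2 df).
* **Suites** (`run_breadth_position_suite`, `run_ratio_summary`,
  `run_decomposition_suite`, `run_all`): breadth-vs-position and
  breadth-vs-decomposition regression tables per region and globally,
  ratio summaries, and a one-call pipeline with manifest, logging and
  fixed seeds.

## Worked example

Simulate a 60-species compilation with known structure, clean it,
summarize it, and fit the breadth–position regressions:

```r
library(nichebreadth)

tree <- simulate_yule_tree(60, seed = 7)
sim  <- simulate_occurrences(climate_field_params(n_species = 60,
                                                  locality_range = c(10, 300),
                                                  seed = 7))
qc <- apply_qc(deduplicate_occurrences(sim$records)$kept)
s  <- summarize_niches(qc$kept)
head(s[s$region == "global",
       c("species", "n_localities", "temp_position", "tnb", "tnb_wl",
         "tnbr_wl_s")], 4)
#>   species n_localities temp_position   tnb tnb_wl tnbr_wl_s
#> 2  sp0001          289         6.389 35.16  22.27    0.6335
#> 4  sp0002           37        18.100 25.10  18.66    0.7436
#> 6  sp0003           10        15.989 45.17  40.41    0.8946
#> 8  sp0004           12         7.061 43.30  39.18    0.9049

fits <- run_breadth_position_suite(s, tree)
subset(fits, region == "Global")
#>                    model region  n lambda       r2         p     slope intercept
#> 4    TNB ~ temp_position Global 60      0 0.120593 6.558e-03 -0.450446     44.40
#> 8  PNB ~ precip_position Global 60      0 0.813841 7.728e-23  0.710677     81.23
#> 12             TNB ~ PNB Global 60      0 0.004665 6.041e-01  0.001113     36.36
```

The fitted global slopes have the structure the generator builds in:
temperature breadth *declines* with temperature position (−0.45 °C per
°C; cool-position, high-latitude species are more seasonal, hence
broader), precipitation breadth *rises* with precipitation position,
and λ̂ = 0 because the simulated climate field is independent of the
simulated phylogeny. The ratio summary shows where breadth comes from:

```r
run_ratio_summary(s)
#>    region  n tnbr_mean tnbr_min tnbr_max pnbr_mean pnbr_min pnbr_max
#> 1  Africa  8    0.8053   0.6978   0.8714    0.4286   0.2989   0.5090
#> 2    Asia 33    0.7676   0.6134   0.9494    0.3924   0.2417   0.5662
#> 3 Oceania 24    0.8035   0.6548   1.0000    0.4309   0.3054   1.0000
#> 4  Global 60    0.7798   0.6134   0.9102    0.4022   0.2417   0.6665
```

Under default settings, within-locality (seasonal) variation accounts
for ~78% of species-level temperature breadth but only ~40% of
precipitation breadth — seasonality dominates the thermal niche while
geography dominates the precipitation niche.

The whole pipeline, from simulation (or CSV + Newick inputs) to the
three result tables plus QC report and manifest, is one call:

```r
cfg <- read_config(system.file("extdata", "example-config.json",
                               package = "nichebreadth"),
                   outdir = "niche_run")
run_all(cfg)
```

See `vignettes/niche-breadth-methods.Rmd` for the statistical details,
the generator's assumptions, and the design decisions.

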