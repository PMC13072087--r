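# File formats

## Occurrence CSV (input and `inputs/occurrences.csv`, `occurrences_clean.csv`)

Header + one row per occurrence point. Columns:

| column  | type   | units | meaning                                   |
|---------|--------|-------|-------------------------------------------|
| species | string |       | species identifier (spaces become `_`)    |
| lon     | number | °     | longitude, [−180, 180]                    |
| lat     | number | °     | latitude, [−90, 90]                       |
| region  | string |       | region label (optional; default `all`)    |
| bio1    | number | °C    | annual mean temperature                   |
| bio5    | number | °C    | max temperature of warmest month          |
| bio6    | number | °C    | min temperature of coldest month          |
| bio12   | number | mm    | annual precipitation                      |
| bio16   | number | mm    | precipitation of wettest quarter          |
| bio17   | number | mm    | precipitation of driest quarter           |

Invariants enforced on read: `bio6 ≤ bio1 ≤ bio5`,
`0 ≤ bio17 ≤ bio16 ≤ bio12`. WorldClim-v1-style °C×10 temperatures are
accepted with `temp_scale = 10`.

## Tree (input and `inputs/tree.nwk`)

Newick, rooted, branch lengths required on every edge, ≥ 2 uniquely
labelled tips. Tip labels must match `species` after whitespace
trimming and space→underscore normalisation.

## QC report (`qc_report.csv`)

One row per input record, plus one extra row per additional flagged
variable. Columns: `row` (1-based index into the input table),
`status` (`kept` | `duplicate` | `outlier`), `method`
(`dedup` | `iqr` | `jackknife`), `variable` (bioclim column that
flagged), `value`, `threshold` (violated IQR fence, or the jackknife
critical value C), `species`, `region`.

## Niche summaries (`niche_summaries.csv`)

One row per species × region plus one per species with
`region = "global"` (all points pooled; ratio columns there hold the
cross-region mean ratio). Columns: `species, region, n_localities,
temp_position, precip_position, tnb, pnb_annual, pnb_wetdry, tnb_wl,
pnb_wl, tnbr_wl_s, pnbr_wl_s, tnpv, pnpv` (°C, mm, °C², mm²).

## Regression tables (`table1_breadth_position.csv`, `table3_decomposition.csv`)

One row per model × stratum: `model, region, n, lambda, r2, p, slope,
intercept, degenerate, pnb_index`. `region` is a region label or
`Global`; `n` is the number of species rows entering the fit;
`degenerate` marks zero-variance predictors or zero-residual fits;
`pnb_index` records which precipitation breadth (`wetdry`/`annual`)
fed the suite.

## Ratio summary (`table2_ratio_summary.csv`)

`region, n, tnbr_mean, tnbr_min, tnbr_max, pnbr_mean, pnbr_min,
pnbr_max`. Regional rows count every species occurring in the region;
`Global` counts each species once.

## Manifest (`manifest.json`)

`seed`, `simulated_inputs`, `r_version`, `package_version`, the full
configuration echo, record/species/table row counts, and all warnings
raised during the run.

## Simulation truth sidecar (`inputs/sim_truth.json`)

Per-species generating values (range centre, locality count, seasonal
amplitude, precipitation level, realized mean amplitude and
among-locality temperature variance), the generator's gradients, and
the row indices of injected outliers and duplicates.

## Analysis config (JSON, see `inst/extdata/example-config.json`)

Fields mirror `analysis_config()`: `occurrences`, `tree` (paths; omit
to simulate), `sim_params` (overrides for `climate_field_params()`),
`outdir`, `seed`, `force`, `temp_scale`, `qc`, `metrics`,
`min_stratum_n`.
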