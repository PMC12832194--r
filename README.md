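# droughtGreen

Quantifying how vegetation greenness responds to meteorological drought
in monsoon karst landscapes.

Drought impact studies in regions like the karst plateau of southwest
China follow a common chain: compute a standardized drought index from
station climate, extract drought events, measure greenness (NDVI)
anomalies against drought-free baselines, and stratify the response by
vegetation type and bedrock. `droughtGreen` implements that chain as a
tested R package for drought ecohydrologists and remote-sensing
analysts, together with fully seeded synthetic data generators so every
stage runs and is verifiable without access to restricted station or
satellite archives.

## The method in brief

* **SPEI-6** — the climatic water balance `D = P − PET` (Thornthwaite
  PET from monthly temperature and latitude), aggregated over k = 6
  months, fitted per calendar month with a 3-parameter log-logistic
  distribution by unbiased probability-weighted moments
  (`β = (b₀ − 2b₁)/(6b₁ − b₀ − 6b₂)`, etc.), and mapped through
  `Φ⁻¹(F(D₆))` to standard-normal deviates. Self-calibration (per-month
  mean ≈ 0, sd ≈ 1 over the calibration period) is enforced by tests.
* **Run theory** — drought months are `SPEI-6 ≤ −1.0`; maximal runs
  separated by ≤ 1 non-drought month merge into one event; events
  shorter than 2 months are discarded; severity classes follow the
  standard rating (moderate −1.5 < SPEI ≤ −1.0, severe −2.0 < SPEI ≤
  −1.5, extreme ≤ −2.0).
* **Greenness anomalies** — 16-day composites → monthly maximum value
  composites → per-calendar-month baselines computed with drought months
  *excluded* → absolute (`obs − baseline`) and percent anomalies, plus
  the signed lag of the annual greenness minimum.
* **Stratification** — zonal statistics by vegetation class (BDF, NDF,
  SCR, MDW, GRA; OTH excluded by default) and karst / non-karst
  landform, including the cross-classification.
* **Interpolation** — ordinary kriging (exponential variogram, WLS fit,
  optionally pooled across monthly fields) or IDW from stations to the
  analysis grid.

## Worked example

Run the default synthetic scenario — 60 × 60 grid of 250 m cells,
12 stations, 21 years, one planted 8-month drought (May–December of
year 11, precipitation halved) — and look at what the pipeline finds:

```r
library(droughtGreen)

scn <- simulateScenario(scenarioConfig(seed = 42))
scn$regionalSpei
#> SpeiSeries (k = 6): 252 months, 247 defined
#>   range [-2.44, 2.43] | calibration 2001-01 .. 2021-12

scn$events[, c("onset_label", "termination_label", "duration_months",
               "peak_spei", "event_class")]
#>  onset_label termination_label duration_months peak_spei event_class
#>      2011-05           2012-02              10 -2.443343     extreme
#>      2019-04           2019-12               9 -1.236311    moderate
#>      2020-03           2020-11               9 -2.203371     extreme
#>      2021-05           2021-08               4 -1.376994    moderate
```

The first event is the planted drought: the forcing ran May–December
2011, and the 6-month index — which integrates the deficit — stays below
threshold through February 2012, exactly the window the generator's
ground truth predicts (`scn$climate$groundTruth$expectedWindow`,
2011-05 … 2012-02). The later events are natural variability: a
21-year monsoon record contains real droughts beyond the planted one.

Per-class mean NDVI anomalies over the detected drought months recover
the planted sensitivity ordering (meadows most suppressed, needleleaf
forests least), and karst cells respond more strongly than non-karst:

```r
scn$droughtWindowSummary[, c("stratum", "n", "mean")]
#>  stratum    n    mean
#>      BDF   90 -0.0554
#>      NDF  407 -0.0259
#>      SCR 1211 -0.0710
#>      MDW   66 -0.0974
#>      GRA  556 -0.0491

scn$karstSummary[, c("stratum", "n", "mean")]
#>  stratum    n    mean
#>        K 2685 -0.0571
#>       NK  915 -0.0391
```

A mean anomaly of −0.097 for meadows says meadow NDVI during the
drought sat about 0.10 below its drought-free same-calendar-month
baseline; the K/NK contrast (−0.057 vs −0.039) is the karst
amplification the generator plants and the pipeline measures.

File-based use goes through `readStationCsv()` (which enforces the 5 %
missing-data station exclusion), `runPipeline()` with a YAML config, and
the CLI wrapper `inst/scripts/drought-greenness.R`
(`simulate | spei | events | run`). Grids are written as plain-text ESRI
ASCII rasters, tables as CSV/JSON.

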