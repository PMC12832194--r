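---
title: "Methods: drought events and vegetation greenness response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought events and vegetation greenness response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtGreen)
```

# The problem

Subtropical monsoon karst landscapes concentrate most of their annual
precipitation in April–October; a failed monsoon or a dry winter produces
meteorological droughts whose vegetation impact differs sharply between
vegetation types (meadows, scrublands, forests, grasslands) and between
karst bedrock (thin soils, rapid seepage) and non-karst terrain.
`droughtGreen` implements the full analysis chain used to quantify these
responses: a standardized drought index from monthly station climate,
run-theory event extraction, greenness (NDVI) anomaly analysis against
drought-free baselines, and stratified summaries — plus seeded synthetic
generators so the whole chain is testable without restricted data
archives.

# The drought index

The index standardizes the climatic water balance $D = P - \mathrm{PET}$
aggregated over $k$ months (the package default is $k = 6$, the timescale
that tracks vegetation best in this setting).

**Potential evapotranspiration.** Station inputs are monthly mean
temperature and precipitation only, so PET uses Thornthwaite's
temperature-and-day-length method: the annual heat index
$I = \sum_m (t_m/5)^{1.514}$ over positive monthly means, exponent
$a(I) = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 + 0.01792\,I +
0.49239$, uncorrected $\mathrm{PET} = 16\,(10\,t/I)^a$ (standard
quadratic above 26.5 °C), scaled by the day-length correction
$K = (N/12)(\mathrm{NDM}/30)$ with $N$ computed from the mid-month solar
declination. Months at or below 0 °C have zero PET. The heat index is
computed per calendar year. Radiation-based PET (Hargreaves,
Penman–Monteith) is a deliberate non-goal: it needs inputs the station
family does not carry; `thornthwaitePet()` is the single extension point
if they become available.

**Aggregation and standardization.** `aggregateK()` forms
$D_k[m] = \sum_{j=m-k+1}^{m} D[j]$ (undefined for the first $k-1$ months;
any missing contributing month voids the window — no imputation). For
each calendar month, the $D_k$ sample over the calibration period
(default: the full record, 21 years in the synthetic scenario) is fitted
with a three-parameter log-logistic distribution by unbiased
probability-weighted moments,
$$\beta = \frac{b_0 - 2b_1}{6b_1 - b_0 - 6b_2},\qquad
\alpha = \frac{(2b_1 - b_0)\,\beta}{\Gamma(1{+}1/\beta)\Gamma(1{-}1/\beta)},
\qquad \gamma = b_0 - \alpha\,\Gamma(1{+}1/\beta)\Gamma(1{-}1/\beta),$$
and the index is $\mathrm{SPEI}[m] = \Phi^{-1}(F(D_k[m]))$ with that
month's fitted CDF $F$.

Numerical choices worth knowing:

* $\Phi^{-1}$ is `stats::qnorm`, the exact form of the rational
  approximation used in the classical construction.
* Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before the quantile
  so values at or below the fitted origin stay finite (floor ≈ ±4.75).
* A calibration sample with negative third L-moment (left skew — possible
  in 21-sample calendar months) admits no valid log-logistic shape; the
  fit is then performed on the reflected sample and the CDF flipped,
  preserving a proper monotone fit. `fitLogLogisticPwm()` records this in
  its `reflected` flag.
* Degenerate samples (constant, or fewer than 10 values) are errors, not
  silent fallbacks.

Self-calibration is the key invariant: on its own calibration period each
calendar month's SPEI has mean ≈ 0 and standard deviation ≈ 1; the test
suite checks $|\text{mean}| \le 0.1$ and sd within $[0.85, 1.15]$ on a
21-year synthetic station.

**Regional index.** The regional SPEI is computed from the pooled
(station-mean) temperature and precipitation series, not by averaging
per-station indices: standardizing the regional water-balance series is
what gives the regional index unit variance, so the severity classes
retain their meaning at regional scale.

# Run-theory events

`droughtMonths()` marks months with SPEI ≤ −1.0 (inclusive threshold;
mild droughts above it are deliberately ignored as having limited
vegetation effect). `identifyEvents()` then:

1. finds maximal sub-threshold runs;
2. merges runs separated by at most `mergeGap` non-drought months
   (default 1 — at monthly resolution a "separation of less than one
   month" is read as the common one-month pooling convention; the gap
   months count toward the event's duration and mask);
3. discards merged events shorter than `minDuration` months (default 2:
   events must last longer than one month).

Event severity is the class of the peak (minimum) SPEI using the
standard rating: mild (−1.0, −0.5], moderate (−1.5, −1.0], severe
(−2.0, −1.5], extreme ≤ −2.0. Seasons follow the meteorological
convention (spring Mar–May, …, winter of year $Y$ = Dec $Y$ – Feb
$Y{+}1$), and `seasonalMeanSpei()` averages the three member months.

# Greenness anomalies

16-day composites are assigned to the month containing their start date
and reduced by per-cell maximum value compositing (`mvcMonthly()`), which
suppresses one-sided cloud contamination. Baselines
(`baselineClimatology()`) are per-calendar-month means over the years
whose month is **not** inside an identified drought event — exclusion
follows the event mask (including merged gap months), not merely
sub-threshold months, so baselines describe undisturbed conditions.
Anomalies are `observed − baseline` (negative = suppressed growth) with
percent anomalies `100·absolute/baseline` reported only where
`|baseline| ≥ ε` (ε = 0.01 NDVI; variable-specific values for
hydrothermal fields, e.g. 1 mm for precipitation). By construction the
mean absolute anomaly over baseline-contributing years is zero for every
calendar month — an invariant tested at 1e−9.

The package computes regional means of cellwise anomalies (rather than
anomalies of regional means); the two differ only through cellwise
missingness, and the cellwise convention keeps stratified and unstratified
results consistent (`hydrothermalSummary()` for the whole domain equals
the regional anomaly series exactly).

`minimumShift()` reports the signed month lag between the observed and
baseline annual minima (ties resolved toward the earliest month and
flagged) — the "delayed spring minimum" diagnostic.

# Stratification

`zonalSummary()` and `crossStratify()` summarize any grid field by
vegetation class, landform (karst K / non-karst NK), or their
cross-classification, with listwise dropping of cells invalid in any
layer. The OTH class (croplands, urban, barren, wetlands) is excluded
from vegetation-response summaries by default because human management
confounds the drought signal; pass `excludeLabels = character()` to keep
it. The count-weighted recombination of stratum means equals the global
mean — tested against a brute-force loop.

# Interpolation

Station fields (SPEI, temperature, precipitation) are interpolated with
ordinary kriging under an exponential variogram
$\gamma(h) = c_0 + c\,(1 - e^{-h/r})$, fitted by weighted least squares
(weights $n_p/h^2$) to binned empirical semivariances up to half the
maximum separation. Kriging weights solve the standard system with the
unbiasedness constraint (they sum to 1; the interpolator is exact at
stations when the nugget is zero) and the kriging variance is reported.
Inverse-distance weighting is provided as a fast, degenerate-safe
alternative. Planar coordinates are assumed; CRS transforms are out of
scope.

A practical note baked into the API: the range of an exponential
variogram estimated from a *single* field realization at ~200 stations
carries ergodic noise of order 25 % — no geometry avoids this, because
the range must exceed the station spacing while the practical range must
stay well inside the domain. `fitVariogram()` therefore accepts replicate
time slices (`values` as a stations × slices matrix) and pools per-pair
semivariances across them, which is how a variogram should be fitted from
the pipeline's monthly fields; with 12 slices the range recovery error
drops to a few percent.

# The synthetic scenario

The generators (`simulateClimate()`, `simulateMasks()`,
`simulateNdvi()`, `simulateHydrothermal()`) emulate the four input
families. All randomness flows from the mandatory scenario seed;
identical seeds give bit-identical outputs.

* **Climate.** Temperature is a sinusoid (mean 15 °C, amplitude 9.5 °C,
  peak July) plus station noise; precipitation is gamma-distributed per
  calendar month (CV 0.3) around monthly means summing to ~1130 mm with
  ~83 % in April–October, scaled by a shared lognormal regional factor
  (sd 0.25) that induces realistic inter-station correlation and
  region-wide wet/dry months.
* **The planted drought.** One 8-month forcing window (May–December of
  year 11) halves precipitation and warms by 1 °C, followed by a 3-month
  1.8× wet rebound as the monsoon returns — the post-drought surge this
  climate actually delivers. These magnitudes were chosen to make the
  planted event *severe to extreme* (peak index −2 to −3.5) rather than
  a many-sigma outlier: an implausibly deep forcing would dominate its
  own 21-sample calibration and distort the fits.
* **Ground truth.** A 6-month index integrates forcing, so the months a
  drought index flags are not the forcing months. The generator records,
  alongside the forcing window, the *expected drought window* — derived
  analytically from the configuration alone (expected deficits against
  the climatological k-month standard deviation, with corrections for the
  forced months' contamination of the calibration mean and spread) and
  therefore independent of both the realized noise and the detection
  code. Planted-window recovery is judged by month-set Jaccard overlap
  against this window.
* **Masks.** Vegetation (six classes at the study-area shares: BDF 3.3 %,
  NDF 12.5 %, SCR 31.5 %, MDW 1.8 %, GRA 15.6 %, OTH the rest) and
  karst/non-karst (73 % karst) patches are allocated by seeded
  multi-seed nearest-neighbour (Voronoi) growth: contiguous patches,
  realized shares within ±5 points of the targets.
* **NDVI.** Per cell, a class seasonal curve (minimum January, peak July)
  plus `sensitivity × min(0, SPEI lagged 2 months)`, 1.5× amplified on
  karst, with sensitivities ordered MDW > SCR > BDF > GRA > NDF; wet
  anomalies do not boost greenness by default, keeping the planted signal
  one-sided. Two composites per month suffer one-sided cloud suppression
  so the MVC recovers the signal. The default scenario drives all cells
  with the regional SPEI series (the response is spatially uniform in the
  index by design); a gridded SPEI stack can be supplied instead.
* **Hydrothermal grids.** Temperature and precipitation spread the
  regional series over the grid; shortwave radiation is seasonal and
  anticorrelated with relative precipitation; surface and root-zone soil
  moisture are AR(1) low-pass filters of the standardized water balance
  (root zone slower), so both deplete with a lag through the planted
  drought.

What the generators do **not** emulate: spatially propagating drought
patches, MODIS QA artifacts, phenological plasticity, and any land
surface physics. Passing tests therefore demonstrate that the *machinery*
recovers known planted structure under realistic noise — not that the
scientific conclusions transfer to any particular real archive.

# Problem sizes and test design

The default scenario is a 60 × 60 grid (250 m cells), 12 stations,
21 years (252 months, 504 composites) — the desk-scale stand-in for the
full-province problem; one end-to-end run takes well under a second and
the 50-seed recovery experiment under a minute. Choices made to keep
fixed-seed tests meaningful rather than lucky:

* The distribution-recovery test draws its n = 1000 sample by jittered
  stratification (a 1-D Latin hypercube through the known quantile
  function): still a random draw from the target distribution, but with
  the sampling-luck variance removed, so the test verifies the estimator
  rather than the seed. An iid draw at n = 1000 has ~35 % probability of
  exceeding the 10 % error bound for at least one parameter — a property
  of L-moment estimation, not of the implementation.
* The variogram-recovery test pools 12 replicate monthly fields for the
  reason given above.
* Event-extraction exactness is tested on 50 constructed series with
  planted runs and one-month gaps, where ground truth is known by
  construction.

# Configuration and interfaces

All analysis constants (k = 6, threshold −1.0, minimum duration 2, merge
gap 1, season convention, strata) surface in `pipelineConfig()` /
`scenarioConfig()` defaults — never hard-coded inline — and a YAML file
(`readPipelineConfig()`) drives `runPipeline()`, which writes CSV/JSON
tables and plain-text ASCII grid rasters (`.asc`) with md5 checksums in
its run report. Grids use the ESRI ASCII format because it is the
standard *text* raster interchange format; a thin command-line wrapper
(`inst/scripts/drought-greenness.R`, subcommands `simulate`, `spei`,
`events`, `run`) exposes the same functions for shell use.

# Known limitations

* Thornthwaite PET is temperature-driven; in energy-limited winters it
  can understate PET relative to radiation-based methods, shifting the
  water balance slightly wet. The standardization absorbs a constant
  bias but not a seasonal-cycle error in trend studies.
* The calibration period includes identified droughts (the classical
  construction); a planted or real extreme event inflates its calendar
  months' fitted spread by a factor ≈ $\sqrt{1 + z^2/n}$.
* Monthly resolution: sub-monthly drought onset/termination and pentad
  dynamics are out of scope, as are post-drought recovery metrics.
* Kriging assumes isotropy and planar coordinates; co-kriging with
  elevation is not implemented.
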