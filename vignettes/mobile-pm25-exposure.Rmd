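---
title: "Estimating traffic-related PM2.5 exposure from bicycle-mounted low-cost sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating traffic-related PM2.5 exposure from bicycle-mounted low-cost sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fleets of low-cost optical PM2.5 sensors mounted on bicycles produce
opportunistic, GPS-tagged 10-second concentration records. Such data promise
street-level resolution of a cyclist's exposure — in particular the *extra*
PM2.5 contributed by nearby road traffic on top of the regional background —
but they arrive with every pathology of uncontrolled deployment: indoor and
stationary operation, devices carried on cars or trains, covered inlets,
drifting or biased sensors, humidity-dependent response, and no co-located
reference for most of the fleet.

`cyclepm` implements a complete analysis chain for such campaigns:

1. **Ingest**: read raw measurement and reference-station tables, derive
   point speeds from consecutive GPS fixes, and segment device streams into
   trips.
2. **Quality control**: a speed-window filter, device-level screening
   against the regional reference mean, trip-edge trimming, and a
   minimum-points rule.
3. **Calibration**: an hourly, fleet-wide multiplicative correction factor
   anchored at reference stations, validated by Leave-Station-Out
   cross-validation.
4. **Exposure**: per-trip background estimation by a low concentration
   percentile and signed traffic increments per point and per trip.
5. **Spatial aggregation**: increments binned into metric grid cells with
   small-count suppression and five quantile classes; a same-hour
   co-incidence diagnostic of mobile precision.
6. **Synthetic campaigns**: a generator with a ground-truth ledger, so that
   every stage above can be tested end to end for recovery of known truth.

## Quality control

Speeds are great-circle distances between consecutive fixes of one device
divided by the elapsed time; the first fix of a stream inherits its
successor-segment speed. Records outside the inclusive window
**5–45 km/h** are discarded: the lower bound removes stationary (mostly
indoor) use, the upper bound removes motorised transport. The bounds are
treated as inclusive because the exclusion rule is stated for speeds
strictly beyond them.

Device screening compares each device's mean concentration (over its
speed-valid points) with the official regional mean during the hours that
device was active, weighted by the device's records per hour. A device is
excluded as *flat-low* when its mean is below **3 µg/m³** (a covered or dead
inlet) and as a *high outlier* when its mean exceeds **3×** the matched
regional mean. The flat-low threshold is absolute; the high-outlier rule is
a ratio because "too high" only has meaning relative to what the region
actually experienced during the device's hours. The factor 3 splits the
printed examples of both categories (suspect sensors showed regional/sensor
ratios of 2–8, and the one high outlier read 4× the regional mean); it is
configurable.

Trips are segmented at recording gaps longer than **120 s** (12 missed
samples). Sensors equilibrating after being carried outdoors read
unreliably, so the first and last **floor(0.05·n)** points of each trip are
trimmed; trips with fewer than **25** remaining points are dropped. The
filter order is fixed: speed → device screening → trim → minimum points,
with device means computed on speed-valid points only.

## Hourly calibration

For hour $h$, let $C_{\mathrm{off},s}(h)$ be the official concentration at
reference station $s$ and $\bar C_{\mathrm{sens},s}(h)$ the pooled mean of
all sensor values recorded within 1 km of $s$ during $h$ — co-located kits
and passing bikes alike, with a minimum of 6 values per station-hour. The
fleet-wide correction factor is the across-station mean ratio

$$\beta(h) = \frac{1}{n}\sum_{s=1}^{n}
   \frac{C_{\mathrm{off},s}(h)}{\bar C_{\mathrm{sens},s}(h)},$$

applied multiplicatively to every sensor record of that hour. Guard rails,
applied in fixed order:

* $n < 2$: a single station cannot represent the area; $\beta = 1$.
* $\beta$ is clamped into $[0.5, 5]$.
* when the pooled sensor mean exceeds 15 µg/m³ and the official values
  disagree (across-station SD $\ge 0.15\times$ their mean), the hourly field
  is too non-uniform for a single factor; the raw data are kept
  ($\beta = 1$).

Hours with no factor use $\beta = 1$ and are flagged. A kit within the
radius of two stations contributes to both factors; that is intentional —
the factor is meant to be an area average, not a per-station calibration.
Because $\beta$ is a ratio of concentrations, it removes any fleet-common
multiplicative error, including the humidity-dependent part, hour by hour.
It cannot correct device-specific gain spread.

Two ambiguities had to be resolved: the pooled sensor mean entering the
stability guard is taken over all contributing values of the hour (weighted
by per-station value counts), and the official SD is computed across the
stations contributing ratio pairs. Both choices make the guard a statement
about the *area-wide* hour.

**Validation.** `lso_validate()` recomputes all hourly factors excluding one
station's official data, applies them to the pooled sensor series at that
station, and compares raw and calibrated series against the official one
(bias, MAE, RMSE, Pearson; plus across-station column means). The
95% confidence interval convention used throughout is `2 × SD` of the
differences (sample SD, $n-1$), not 1.96 × SD.

## Percentile background and traffic increments

A trip's background is the **10% percentile** (sorted-order linear
interpolation, verified against a brute-force oracle) of its calibrated
concentrations: part of a typical trip passes locations with little nearby
traffic, and a percentile above the minimum is robust to residual warm-up
effects and sensor noise. Increments are **signed**
(`pm25_cal − background`), never clamped at zero, so the identity
`mean increment = mean total − background` holds exactly and no positive
bias is introduced. Raising the percentile can only raise the background,
so the mean increment is monotonically non-increasing in the percentile —
a property the tests exercise directly.

Hours in which the across-station mean of the official series changed by
more than **2.5 µg/m³** relative to the preceding hour are flagged
*unstable*: a regional swing inside a trip would masquerade as traffic.
Trips with any point in such an hour are excluded from the
sensitivity-restricted summaries ("average variation per hour" is read as
the change of the across-station mean; the first hour of a series has no
predecessor and is never excluded). Summaries report 0.25 µg/m³ histograms,
means and counts, overall or by calendar quarter (Jan–Mar … Oct–Dec);
empty groups are absent rather than zero.

## Spatial aggregation

Point increments are projected to a metric CRS (built-in: the Dutch
national grid, EPSG:28992, via the published polynomial approximation,
accurate to well under a metre inside its validity area; any other metric
CRS can be supplied as a forward/inverse function pair). Cells are
half-open, `i = floor((x − x0)/cell)`, default 25 m. A cell is reported
only with **≥ 15 observations from ≥ 3 distinct devices** — with fewer, a
single enthusiastic cyclist or a single biased kit would dominate the map.
Reported cell means are classified into five quantile classes (linear
interpolation breaks over the cell means, ties to the lowest containing
class) and can be written as a GeoJSON FeatureCollection of cell polygons.

The co-incidence diagnostic bins *calibrated* measurements into 50 m cells
per hour; wherever at least two devices coincide it reports the sample SD
of the per-device means and the relative scatter (SD over the mean of the
device means) — a direct estimate of between-sensor precision under mobile
conditions.

## The synthetic campaign generator

The generator builds campaigns with known truth. Its defaults are the study
conditions the analysis is meant to operate under, chosen once:

* **Background**: hourly series $B(h) = \exp(\mu + z_h)$ with $z$ a
  stationary Gaussian AR(1), $\mu$ mean-corrected so the long-run mean is
  `background_mean` = 9.9 µg/m³; `background_sigma_log` = 0.5 reproduces the
  familiar lognormal shape of annual PM2.5 distributions, and
  `ar1_coef` = 0.98 gives synoptic (multi-day) persistence with hour-to-hour
  changes of about 1 µg/m³, typical of urban PM2.5. The series is held
  constant within each hour.
* **Streets and traffic**: a 500 m street grid over a 20 × 20 km square;
  each line carries busy traffic with probability 0.25 (sparse arterials
  between residential zones). The increment field is
  $T(x) = T_0\,e^{-d(x)/\lambda}$ with $T_0$ = 3.5 µg/m³ on a busy street
  and $\lambda$ = 75 m, so near-road increments are of order a few µg/m³
  and decay within a block.
* **Trips**: Poisson(2) trips per device-day starting in a 07–19 h window,
  gamma-distributed durations with mean 17 min, leg speeds drawn from
  10–25 km/h, sampled every 10 s. Routes start at a "home" drawn around the
  area centre (SD 2 km) at least 300 m from any arterial, ride quiet
  residential streets for the first ~12% of the route, then head for and
  follow arterials (with a strong tendency to continue straight on one),
  and finish on quiet streets near an off-network destination; start and
  end points leave the network with probability 0.8. This builds the
  analysis' central premise — every trip contains genuinely low-traffic
  sections — into the data by construction, which is exactly the situation
  the percentile background estimator assumes. Under these defaults the
  true mean trip increment is ≈ 2 µg/m³.
* **Sensor model**: reading =
  `gain_d · (1 + 0.003·(RH − 50)) · (B + T) + N(0, 0.5)`, floored at zero.
  Gains are lognormal around `device_gain_mean` with log-SD 0.1. Relative
  humidity follows a smooth diurnal sinusoid 50 ± 20% (peak at 04:00). The
  0.5 µg/m³ noise reflects that short-term fluctuations beyond
  0.5–1 µg/m³ in field data are dominated by real ambient variation, so
  the pure sensor term must lie below that. The humidity term is a
  stand-in — field studies report humidity-correlated ratios without
  giving a model — chosen multiplicative so that an hourly ratio factor
  can correct it.
* **Malfunctions**: 15% of devices are flat-low (gain 0.1) and 5%
  high-biased (gain 4), roughly the one-in-five suspect-kit rate seen in
  practice. Roles are assigned by a deterministic shuffle under the seed,
  so the counts are exact, not binomial.
* **Reference stations**: four stations placed mid-block (≥ 250 m from any
  street line, i.e. background locations), reporting
  `B + N(0, 0.4)` hourly. Each hosts a static co-located sensor kit
  sampling every 30 s around the clock; these kits share the fleet's
  sensor model, are exempt from the bicycle speed filter (they are fixed
  installations), and dominate the pooled station-hour means the way
  continuously-running co-located kits do in real deployments.

Every record carries a ground-truth ledger entry (true background, true
local increment); per-trip truth is the mean of its per-point truth. What
the generator does **not** emulate: meteorological dispersion, rush-hour
traffic dynamics, GPS dropouts in forests, sensor drift over months, and
particle-composition effects. Passing tests therefore demonstrate that the
*analysis chain* recovers truth under its own assumptions, not that those
assumptions hold for any particular real campaign.

## Numerical choices and degenerate inputs

* Percentile definition: linear interpolation over order statistics
  (`type = 7`); at p = 0 it is the minimum.
* Quantile classes: values equal to a break go to the lower class; all-equal
  values land in class 1.
* Pearson correlation of a constant series is reported as absent (`NA`),
  never 0; a comparison needs at least two paired hours.
* A station-hour with a zero pooled sensor mean is skipped and the station
  count decremented; an hour losing all pairs gets $\beta = 1$.
* Trips shrinking below the minimum point count after trimming are dropped,
  as are single-record "trips".
* Empty inputs (no measurements, no trips, no cells) yield empty outputs of
  the right shape rather than errors, except where a result is undefined
  (LSO with one station, quantile classes with fewer values than classes).

## Problem sizes used in the tests

The automated tests run campaigns of 2–8 devices over 1–5 days for unit
properties, one 20-device × 20-day campaign for increment recovery,
percentile sensitivity and the near-road gradient, one 20-device × 30-day
campaign with a common gain of 0.85 for calibration recovery, and twenty
8-device × 8-day replicates for the bias-reduction property. These sizes
are large enough that fleet-level means are stable to well within the
tolerances checked, while keeping the whole suite fast enough to run on
every change.

## Known limitations

* The hourly factor corrects the fleet, not individual kits; device-specific
  gain spread survives calibration and is only diagnosed (co-incidence
  scatter, device screening).
* The percentile background assumes each trip contains low-traffic
  sections; for trips ridden entirely along busy corridors the increment is
  underestimated.
* Backgrounds are piecewise-constant per hour; sub-hourly regional swings
  inside a trip are only handled by the stable-hour exclusion.
* The high-outlier screening ratio of 3 generalises a judgment call made on
  a single printed case; it is exposed as a parameter.
* The built-in projection is Dutch; other regions must supply their own
  projection pair.
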