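---
title: "Methods: detecting and characterizing extreme marine heatwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing extreme marine heatwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhwx)
```

## The model of a marine heatwave

A marine heatwave (MHW) is defined pointwise: a cell is in MHW state on
days when SST exceeds a *seasonally varying* 90th-percentile threshold,
and an event is a run of at least five such days. The seasonal threshold
matters scientifically: it measures exceedance against what is normal
*for that time of year*, so a winter anomaly of 2 °C in a quiet region
can out-rank a summer anomaly of 4 °C in an energetic one. The severity
index
$$S_{i,t} = \frac{\mathrm{SST}_{i,t} - \mathrm{SST}^{clim}_{i,d}}
                 {\mathrm{SST}^{PC90}_{i,d} - \mathrm{SST}^{clim}_{i,d}}$$
makes this explicit — it rescales the anomaly by the local, seasonal gap
between threshold and climatology, is exactly 1 at the threshold, and is
banded into the moderate/strong/severe/extreme categories at
$1{<}S{\le}2$, $2{<}S{\le}3$, $3{<}S{\le}4$, $S{>}4$. (The published
band edges overlap at exactly $S=4$; we use the non-overlapping reading,
which only matters on a measure-zero boundary.) Because $S$ is a ratio
of differences, it is invariant under any affine rescaling applied
jointly to SST, climatology and threshold — a property the test suite
asserts.

## Climatology and threshold

`build_climatology()` pools, for each day-of-year $d$ and cell, all
baseline-period days whose day-of-year lies within a centered 11-day
window of $d$ (circular across the year boundary), takes the mean and
the 90th percentile, and smooths both along the day-of-year axis with a
centered circular 31-day moving average. Parameters, with defaults and
why:

* `baseline` — the fixed multi-year period defining "normal". No
  default: it is a scientific choice that must be stated. The synthetic
  experiments use the first years of each simulated record, and any
  experiment that implants events places them *outside* the baseline so
  the threshold is not contaminated by the events it is meant to detect.
* `window = 11` days — pools ~11 × (baseline years) samples per
  percentile estimate, the robustness/seasonal-resolution trade-off
  standard in this framework.
* `smooth = 31` days — removes high-frequency sampling noise. A
  circular moving average attenuates the annual harmonic by the
  Dirichlet factor $\sin(31\pi/365)/(31\sin(\pi/365)) \approx 0.9882$
  (and the 11-day pooling by a further 0.9985), flattening the
  climatological summer maximum by a few hundredths of its amplitude;
  the acceptance checks verify the measured gain against the closed
  form of the composed filter, 0.98672, to four decimals.
* `percentile = 0.9`, `quantile_type = 7` — the percentile convention
  (linear interpolation between order statistics) is exposed because at
  small samples it visibly shifts thresholds; nearest-rank
  (`quantile_type = 1`) is available.

Cells/days where the threshold does not exceed the mean (zero variance,
e.g. constant input or ice-filled series) are flagged in a degenerate
mask and the severity field is masked there — never ±∞.

Leap days: all simulation runs on a 365-day no-leap calendar, which
removes a nuisance special case from every indexing step. Real
observations can be mapped with `noleap_doy()`, which assigns Feb 29 to
the Feb 28 pooling window.

`remove_seasonal_trend()` is the sensitivity variant: per cell and
day-of-year (with the same 11-day pooling) it removes an OLS linear
trend in year, so record metrics can be recomputed with secular warming
excluded. The main pipeline deliberately does *not* detrend: for impact
questions the absolute exceedance is what organisms experience.

## Detection and event metrics

`detect_events_series()` finds maximal runs of days strictly above the
threshold, keeps runs of ≥ `min_duration` (5) days, and merges runs
separated by ≤ `max_gap` below-threshold days. The gap rule is read
literally from its source ("below the threshold for less than 2 days"):
`max_gap = 1` by default, with the 2-day variant available because both
readings circulate. Gap days are included in the event span and their
(possibly negative) anomalies accrue to cumulative intensity — an event
is a single dated span, and the convention is configurable so results
are reproducible either way. Missing days are treated as below
threshold and therefore break runs. Equality with the threshold does
not count as exceedance; the tie is measure-zero on real data but must
be fixed for testing. Event metrics use the smoothed climatology — the
same object that defines the threshold — so the severity ratio is
internally consistent.

The implementation is run-length based; the test suite checks it
event-for-event (spans, intensities, cumulative intensities,
severities) against an independently written day-by-day state machine
on 1,000 random 2,000-day series.

## Spatial extent

Daily contiguous MHW regions are connected components of the
in-heatwave mask, with "connected in any direction" read as
8-connectivity (4-connectivity is a flag, since the original choice is
not stated) and a seam-free wrap across the longitude boundary; there
is no wrap over the poles. Cell areas use the exact spherical band
formula with $R = 6371$ km, which telescopes to $4\pi R^2$ over a
global grid — the acceptance checks assert this to machine precision.
Components are daily snapshots; no day-to-day identity tracking is
attempted, because extent varies strongly day to day and merging/
splitting makes event genealogy ill-defined. The largest-component
series can exclude components touching an equatorial-Pacific box
(default 5°S–5°N, east of 170°E) to show the extent record with the
directly ENSO-forced signal removed.

## Records and the most extreme extremes

`record_maps()` reduces the event table to per-cell records (longest
duration, maximum intensity, maximum cumulative intensity, maximum
severity, each with dates; ties to the earliest). Candidate cells for
the "most extreme extremes" are those whose record-severity day falls
inside the record cumulative-intensity event — the places where being
most severe and being longest/most-accumulated coincide in time.

The source analysis delineated regions by hand. Reproducibility demands
an algorithm, so `identify_extreme_regions()` offers two modes: (a)
user-supplied polygons intersected with the candidate mask, for
faithful reproduction of a published delineation; (b) a deterministic
automatic rule — connected components of candidate cells whose
record-severity dates agree within `date_window = 90` days (about the
synoptic-to-seasonal coherence of a single large event), with a minimum
region size. The automatic rule is an explicit stand-in, not a claim
about how the original polygons were drawn.

`characterize_region()` computes the four region timeseries (area
fraction in MHW state; largest intersecting contiguous area at S > 1
and S > 2; its area-integrated SSTA; member cells at their record-
severity day) and dates the event core as the longest span where the
area fraction exceeds `f_min = 0.3` *and* the contiguous area exceeds
`r_min = 0.5` of its own record. These two thresholds are free
parameters replacing a manual judgement; the defaults mark the period
when a third of the region is in heatwave state and the contiguous
event is at least half its peak size, and both are exposed for
sensitivity analysis. The region peak — used to anchor driver and
chlorophyll windows — is the core-period day of maximal area-weighted
region-mean severity. The duration quantiles reported per region are
those of each member cell's maximum-cumulative-intensity event,
following the source table's definition.

## ENSO conditioning

The Niño3.4 index is the area-weighted monthly SST anomaly over
5°S–5°N, 170°W–120°W, standardized over a stated base period (default:
the full overlap; the original standardization window is unstated, so
it is a config choice). Phases at |index| > 1 (moderate) and > 2
(strong). `record_fraction_by_phase()` compares the area fraction of
the ocean attaining records during each phase with the fraction of
months spent in that phase — the null expectation under independence —
and `regress_index_map()` gives the per-cell OLS slope of SSTA on the
index. The generator's imposed loading pattern is recoverable within
regression standard errors, which ties the two modules together in the
tests.

## Driver composites

For each region and driver field (sea-level pressure, wind speed, zonal
wind, shortwave and longwave radiation, latent and sensible heat flux),
`window_normalized_anomaly()` averages the area-weighted region-mean
series over a fixed window around the peak and normalizes by the
across-years spread of the *same calendar window*, making the anomaly
seasonality-free and shift-invariant by construction. The window
bounds: the source's methods text (pre = 6 to 2 weeks before, post = 2
to 6 weeks after; 28-day windows) and its figure caption (6 to 3 / 3 to
6 weeks) disagree; the default follows the methods text, the caption
variant is `weeks = c(6, 3)`. Record and top-decile flags rank the
window's |deviation from the calendar climatology| across years: a
record low-pressure anomaly is a record, the flags are one-in-ten by
construction under a null field (the test suite calibrates the rate at
~10% over 1,000 null regions), and record implies top-decile. Windows
truncated by the record edge are evaluated only at ≥ 75% coverage and
flagged.

## Chlorophyll response

The chlorophyll response of a region is the anomaly (relative to the
long-term composite-of-year climatology) averaged over the three 8-day
composites covering the 24-day window centred on the peak, normalized
by the standard deviation of the region's anomaly series over the full
record. Anomalies are computed in log10 space by default (ocean-colour
concentrations are approximately log-normal, so log space stabilizes
the variance); a linear-space option exists and reported results should
name the choice. Significance comes from two directions: the exact
binomial tail probability for the observed sign agreement across
regions, and a Monte Carlo null built by resampling windows from
non-heatwave dates (default 10,000 draws, seeded; the add-one-corrected
two-sided p-value is uniform under the null, which the tests verify by
Kolmogorov–Smirnov over 500 null regions). Events predating the
chlorophyll record are reported as unanalyzable with a reason rather
than silently dropped.

## The synthetic generator: what it emulates, and what it does not

`generate_fields()` builds SST as seasonal cycle + trend + ENSO loading
× index + AR(1) noise with seasonally modulated variance:

* Seasonal cycle: amplitude grows from 1 °C at the equator to 5 °C at
  mid-latitudes, with the hemispheres in antiphase (Southern peak ~182
  days after the Northern, late July vs late January).
* Noise: daily AR(1) (default lag-1 autocorrelation 0.8, marginal sd
  0.5 °C — representative of daily SSTA in mid-latitude open ocean).
  The seasonal variance modulation — the mixed-layer proxy: shallow
  summer mixed layers amplify SST responses — is a day-of-year sinusoid
  in variance peaking at local mid-summer, applied multiplicatively to
  the unit-variance AR(1) process. The sinusoid amplitude is calibrated
  so the *realized* summer:winter ratio of sample standard deviations
  equals the configured `mod_ratio`: a naive sinusoid with peak ratio
  $r$ undershoots the seasonal-mean ratio by ~10% because the mean of
  the cosine over a three-month season is ≈ 0.9, and the experiments
  are specified in terms of the seasonal ratio. The shape supports
  ratios up to ≈ 4.4.
* ENSO: a monthly AR(1) index (autocorrelation 0.8) imprinted through a
  Gaussian spatial loading centred on an equatorial-Pacific analogue.
  This reproduces the *statistical* teleconnection structure only — no
  phase locking, skewness, or dynamics.
* Drivers and chlorophyll are their climatology plus a linear response
  to the local SST anomaly plus independent AR(1) noise. Signs follow
  the build-up phenomenology: high pressure and weak winds over warm
  anomalies; heat fluxes are oriented positive-downward so suppressed
  ocean heat loss appears as a positive anomaly. The chlorophyll
  response is negative equatorward of 40° (stratification-limited
  nutrients) and positive poleward (light limitation), and
  climatological nitrate increases with |latitude|, giving the
  response–nutrient relationship a recoverable structure. No published
  coupling coefficients exist for this purpose; the defaults are chosen
  for testability, not realism.
* `implant_events()` adds trapezoidal anomalies (20% ramps by default —
  the temporal shape of real events is not documented, and a plateau
  with ramps is the simplest shape with distinct onset/decay phases)
  on non-overlapping footprints, and returns a truth table. Applied to
  a full bundle, drivers and chlorophyll receive the matching coupled
  responses, so implanted events behave like generated ones downstream.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: no spatial correlation in the noise
(real SSTA is coherent over hundreds of km, so real contiguous events
are larger and smoother than synthetic ones); no ocean dynamics,
advection or fronts (the intensity hot-spots along western boundary
currents have no analogue); no sea ice, land mask, or observational
error; linear, instantaneous driver coupling (no lead–lag structure).
Tests against the generator validate the *operations* — thresholds,
run rules, labeling, window statistics, calibration of the tests
themselves — not the climate realism of any particular number.

## Problem sizes and numerical choices

The simulated study conditions are desk-scale by design: default grid
5° × 10° over 60°S–60°N with a 10-year span; the seasonality experiment
uses ~1,000 cells over 10 years; the trend experiment uses single-cell
series with the observational-era layout (36 years, threshold baseline
fixed to years 2–31) at 200 replicates per trend rate; the null
calibrations use 1,000 driver regions and 500 chlorophyll regions with
199-draw Monte Carlo nulls. Quantile estimation is type-7 unless
configured otherwise; the degenerate-threshold guard is
pc90 − clim ≤ 10⁻⁸; component labels are deterministic (ordered by
smallest member cell index), and all stochastic outputs are exactly
reproducible from the configured seed. Implant-then-remove restores the
original field to floating-point round-off (~1 ulp), not bit identity.

## Known limitations

Daily-snapshot extents cannot follow an event across merges and splits;
region delineation reproduces published polygons only when they are
supplied; the Ekman-transport composite of the source figure is out of
scope because its computation is not specified; sub-daily forcing,
heat-budget closure and subsurface structure are not represented; and
the 365-day calendar means real leap-day observations are folded onto
Feb 28 rather than treated as a 366th climatological day.
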