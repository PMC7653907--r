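# mhwx — extreme marine heatwaves in gridded SST

Marine heatwaves (MHWs) — runs of at least five consecutive days with sea
surface temperature above the seasonally varying 90th-percentile
threshold — have reshaped ecosystems from coral reefs to kelp forests.
`mhwx` implements a complete analysis pipeline for identifying and
characterizing the *most extreme* of these events in gridded daily SST,
for climate and marine-ecosystem researchers who want the full chain —
detection, severity categorization, spatial tracking, ENSO conditioning,
atmospheric-driver composites, and chlorophyll-a response statistics —
as tested, reusable functions rather than one-off scripts.

## The core definitions

For each grid cell *i* and day-of-year *d*, a baseline climatology gives
the mean SST<sub>clim</sub> and the threshold PC90 (90th percentile of
all baseline days within an 11-day window of *d*, both smoothed with a
31-day circular moving average). A cell is in MHW state when
SST > PC90 for ≥ 5 days (interruptions of ≤ 1 day are absorbed). The
dimensionless **severity index**

S<sub>i,t</sub> = (SST<sub>i,t</sub> − SST<sup>clim</sup><sub>i,d</sub>) / (SST<sup>PC90</sup><sub>i,d</sub> − SST<sup>clim</sup><sub>i,d</sub>)

equals 1 exactly at the threshold and bands events into categories:
moderate (1 < S ≤ 2), strong (2–3), severe (3–4), extreme (S > 4).
Per-event metrics are **duration**, **maximum intensity** (largest daily
SSTA, °C) and **cumulative intensity** (∫ SSTA dt, °C·days). Daily
contiguous MHW regions (8-connected, dateline-wrapped) carry exact
spherical areas; the "most extreme extremes" are regions where the
record-severity day falls inside the record cumulative-intensity event.

Because the observational archives (¼° SST, reanalysis drivers, merged
ocean-colour chlorophyll) are not shipped, the package includes a
first-class synthetic-data generator — seasonal cycle, AR(1) noise with
seasonally modulated variance (a mixed-layer proxy), warming trend,
ENSO-like loading, and implantable events with known truth — so every
stage is testable end to end.

## Worked example

```r
library(mhwx)

cfg <- synth_config(lat_min = 0, lat_max = 60, dlat = 10,
                    lon_min = 90, lon_max = 330, dlon = 30,
                    n_years = 6, noise_sd = 0.1, ar1 = 0.3,
                    enso_amp = 0, seed = 403)
syn <- generate_fields(cfg, include_drivers = FALSE, include_chl = FALSE)

# implant a 60-day, 3 degC event after the baseline years
spec <- implant_spec(0, 60, 200, 320, start = 365 * 4 + 250,
                     duration = 60, amplitude = 3,
                     ramp_up = 0, ramp_down = 0)
imp  <- implant_events(syn$sst, list(spec))

clim <- build_climatology(imp$field, baseline = c(1983, 1986))
ev   <- detect_events_grid(imp$field, clim)
rec  <- record_maps(ev, cube_cells(imp$field), imp$field$time)

foot <- with(cube_cells(imp$field), which(lon >= 200 & lon <= 320))
summary(rec$longest_duration[foot])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   60.00   60.00   60.00   60.04   60.00   61.00

sign_binomial_test(38, 52)
#> [1] 0.0005975602
```

Every footprint cell recovers the implanted 60-day duration (one cell
picks up an extra day through the 1-day gap-absorption rule),
and the exact one-sided binomial tail probability that 38 of 52 regions
share a chlorophyll response sign by chance is 6.0 × 10⁻⁴ — i.e. the
suppression agreement is far beyond coin-flip (p < 0.01).

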