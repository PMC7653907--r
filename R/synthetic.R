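#' Configuration for the stochastic SST simulator
#'
#' Defines the statistical structure of the simulated ocean: a
#' latitude-dependent seasonal cycle with hemispherically opposed phase,
#' AR(1) daily anomalies whose variance is seasonally modulated (a proxy
#' for shallow summer mixed layers), an optional linear warming trend, and
#' an ENSO-like monthly index imprinted through a spatial loading pattern.
#' Atmospheric driver fields and chlorophyll-a covary linearly with the
#' local SST anomaly.
#'
#' The default grid (5 deg lat x 10 deg lon over 60S--60N) and 10-year
#' span are the package's desk-scale study conditions; they are not the
#' quarter-degree multi-decadal archives of the observational record.
#'
#' @param lat_min,lat_max,dlat latitude extent and step (degrees); cell
#'   centers are placed at band midpoints.
#' @param lon_min,lon_max,dlon longitude extent and step (degrees East).
#' @param start_year,n_years simulated span (no-leap years).
#' @param t_eq,t_pole60 annual-mean SST at the equator and at 60 degrees
#'   latitude (degC); the mean field interpolates quadratically in |lat|.
#' @param amp_eq,amp_mid seasonal-cycle amplitude (degC) at the equator
#'   and at 45 degrees latitude.
#' @param nh_peak_doy day-of-year of the Northern Hemisphere seasonal SST
#'   maximum.
#' @param phase_offset hemispheric phase offset (days); the Southern
#'   Hemisphere cycle peaks `nh_peak_doy - phase_offset` (mod 365).
#' @param ar1 daily lag-1 autocorrelation of the SST anomaly, in [0, 1).
#' @param noise_sd marginal standard deviation of the daily SST anomaly
#'   (degC) at the seasonal-neutral point.
#' @param mod_ratio target ratio of local-summer to local-winter anomaly
#'   standard deviation (mixed-layer proxy); 1 disables modulation. The
#'   sinusoidal variance shape supports ratios up to about 4.4.
#' @param trend linear warming trend (degC per decade), applied from the
#'   first simulated day.
#' @param enso_ar monthly lag-1 autocorrelation of the ENSO-like index.
#' @param enso_amp scale of the ENSO imprint (multiplies the loading
#'   pattern, degC per index s.d.).
#' @param loading_lat0,loading_lon0,loading_lat_scale,loading_lon_scale
#'   center and e-folding scales (degrees) of the Gaussian loading
#'   pattern (an equatorial-Pacific analogue by default).
#' @param slp_coupling,wind_coupling,uwind_coupling,sw_coupling,
#'   lw_coupling,lhf_coupling,shf_coupling linear response of each driver
#'   field to the local SST anomaly (field units per degC). Signs follow
#'   the build-up phenomenology: high pressure and weak winds over warm
#'   anomalies, heat fluxes positive downward so suppressed ocean heat
#'   loss appears as a positive anomaly.
#' @param driver_sd named list of driver noise standard deviations.
#' @param driver_ar1 daily AR(1) coefficient of driver noise.
#' @param chl_coupling magnitude of the chlorophyll response (log10 units
#'   per degC of SST anomaly).
#' @param chl_lat_switch latitude (degrees) where the chlorophyll response
#'   changes sign: suppression equatorward (stratified, nutrient-limited),
#'   enhancement poleward (light-limited).
#' @param chl_sd,chl_ar1 chlorophyll noise parameters (log10 space, daily
#'   before 8-day compositing).
#' @param seed integer random seed.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(lat_min = -60, lat_max = 60, dlat = 5,
                         lon_min = 0, lon_max = 360, dlon = 10,
                         start_year = 1983, n_years = 10,
                         t_eq = 28, t_pole60 = 6,
                         amp_eq = 1, amp_mid = 5,
                         nh_peak_doy = 212, phase_offset = 182,
                         ar1 = 0.8, noise_sd = 0.5, mod_ratio = 1,
                         trend = 0,
                         enso_ar = 0.8, enso_amp = 1,
                         loading_lat0 = 0, loading_lon0 = 210,
                         loading_lat_scale = 12, loading_lon_scale = 45,
                         slp_coupling = 2, wind_coupling = -1.5,
                         uwind_coupling = -1, sw_coupling = 10,
                         lw_coupling = 5, lhf_coupling = 12,
                         shf_coupling = 5,
                         driver_sd = list(slp = 4, wind_speed = 2,
                                          u10 = 2.5, swdown = 25,
                                          lwdown = 12, lhf = 30, shf = 15),
                         driver_ar1 = 0.7,
                         chl_coupling = 0.08, chl_lat_switch = 40,
                         chl_sd = 0.1, chl_ar1 = 0.8,
                         seed = 1L) {
  if (!(ar1 >= 0 && ar1 < 1)) stop("ar1 must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (mod_ratio <= 0) stop("mod_ratio must be > 0")
  for (ext in list(c(lat_min, lat_max, dlat), c(lon_min, lon_max, dlon))) {
    if (abs((ext[2] - ext[1]) / ext[3] - round((ext[2] - ext[1]) / ext[3])) >
        1e-8)
      stop("grid step must divide the extent exactly")
  }
  if (n_years < 1) stop("n_years must be >= 1")
  cfg <- as.list(environment())
  cfg$lat <- seq(lat_min + dlat / 2, lat_max - dlat / 2, by = dlat)
  cfg$lon <- seq(lon_min + dlon / 2, lon_max - dlon / 2, by = dlon)
  # calibrate the variance sinusoid so that local summer / local winter
  # sample-sd ratio equals mod_ratio in expectation
  cfg$mod_b <- .calibrate_mod(mod_ratio)
  class(cfg) <- "synth_config"
  cfg
}

# Solve (1 + b*cs)/(1 + b*cw) = r^2 where cs, cw are the seasonal means of
# the day-of-year cosine over JJA/DJF (peak at the mid-summer doy).
.calibrate_mod <- function(r) {
  if (r == 1) return(0)
  peak <- 197  # mid-JJA
  summer <- 152:243
  winter <- c(335:365, 1:59)
  cs <- mean(cos(2 * pi * (summer - peak) / 365))
  cw <- mean(cos(2 * pi * (winter - peak) / 365))
  b <- (r^2 - 1) / (cs - r^2 * cw)
  if (!is.finite(b) || abs(b) >= 1)
    stop("mod_ratio too extreme for the sinusoidal variance shape ",
         "(supported range is about 0.23..4.4)")
  b
}

# seasonal climatology (no noise) for a latitude vector, [365 x nlat]
.seasonal_clim <- function(cfg) {
  doy <- 1:365
  vapply(cfg$lat, FUN.VALUE = numeric(365), function(phi) {
    t0 <- cfg$t_eq - (cfg$t_eq - cfg$t_pole60) * (abs(phi) / 60)^2
    a <- cfg$amp_eq +
      (cfg$amp_mid - cfg$amp_eq) * abs(sin(2 * phi * pi / 180))
    peak <- if (phi >= 0) cfg$nh_peak_doy else
      ((cfg$nh_peak_doy - cfg$phase_offset - 1) %% 365) + 1
    t0 + a * cos(2 * pi * (doy - peak) / 365)
  })
}

# sd multiplier m(doy, lat): m^2 = 1 + b*cos(2*pi*(doy - peak_mod)/365)
.mod_shape <- function(cfg, doy) {
  vapply(cfg$lat, FUN.VALUE = numeric(length(doy)), function(phi) {
    peak <- if (phi >= 0) 197 else ((197 - 182 - 1) %% 365) + 1
    sqrt(pmax(1 + cfg$mod_b * cos(2 * pi * (doy - peak) / 365), 1e-6))
  })
}

# AR(1) matrix [n x k] with unit marginal variance per column
.ar1_matrix <- function(n, k, a) {
  e <- matrix(stats::rnorm(n * k), n, k)
  if (a == 0) return(e)
  x <- stats::filter(e * sqrt(1 - a^2), a, method = "recursive")
  matrix(as.numeric(x), n, k)
}

#' Generate the synthetic observational input set
#'
#' Produces, for a fixed seed, a deterministic bundle of all fields the
#' pipeline consumes: daily SST, the monthly SST-anomaly field, the
#' ENSO-like index and its loading pattern, daily atmospheric driver
#' fields, an 8-day chlorophyll-a composite series (log10 space), and a
#' climatological surface-nitrate field.
#'
#' SST is assembled as seasonal cycle + linear trend + ENSO loading x
#' index + AR(1) noise with seasonally modulated standard deviation.
#' Driver and chlorophyll fields are their climatology + coupling x local
#' SST anomaly + independent AR(1) noise.
#'
#' @param config a [synth_config()].
#' @param include_drivers,include_chl generate the atmospheric driver /
#'   chlorophyll-and-nitrate components (disable to save memory when only
#'   SST is needed).
#' @return a list of class `mhw_synth` with elements `sst` ([sst_cube()]),
#'   `monthly_ssta` (list `values` `[n_months, nlat, nlon]`, `time`),
#'   `enso_index` (data.frame `year`, `month`, `index`), `loading`
#'   (matrix `[nlat, nlon]`, degC per index s.d.), `drivers` (named list
#'   of [sst_cube()]), `chl` (8-day composite list: `data`
#'   `[n_comp, nlat, nlon]`, `time`, `units`), `nitrate` (matrix,
#'   umol kg-1), and `config`.
#' @export
generate_fields <- function(config, include_drivers = TRUE,
                            include_chl = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cal <- noleap_calendar(config$start_year, config$n_years)
  nt <- nrow(cal)
  nlat <- length(config$lat)
  nlon <- length(config$lon)
  ncell <- nlat * nlon

  clim365 <- .seasonal_clim(config)               # [365 x nlat]
  mod365 <- .mod_shape(config, 1:365)             # [365 x nlat]
  sd_mat <- config$noise_sd * mod365[cal$doy, , drop = FALSE]  # [nt x nlat]

  # ENSO-like monthly index (unit marginal variance) and loading pattern
  n_mon <- config$n_years * 12L
  idx <- as.numeric(.ar1_matrix(n_mon, 1L, config$enso_ar))
  loading <- outer(config$lat, config$lon, function(phi, lam) {
    config$enso_amp *
      exp(-((phi - config$loading_lat0) / config$loading_lat_scale)^2 -
            ((lam - config$loading_lon0) / config$loading_lon_scale)^2)
  })
  mon_of_day <- (cal$year - config$start_year) * 12L + cal$month
  idx_daily <- idx[mon_of_day]

  # anomaly = modulated AR(1) noise + ENSO imprint + trend
  noise <- .ar1_matrix(nt, ncell, config$ar1)
  anom <- noise * as.numeric(sd_mat[, rep(seq_len(nlat), nlon),
                                    drop = FALSE])
  anom <- anom + outer(idx_daily, as.numeric(loading))
  trend_series <- config$trend / 10 / 365 * (seq_len(nt) - 1)
  anom <- anom + trend_series

  sst_mat <- anom + clim365[cal$doy, rep(seq_len(nlat), nlon),
                            drop = FALSE]
  sst <- sst_cube(array(sst_mat, c(nt, nlat, nlon)), cal,
                  config$lat, config$lon, units = "degC")

  # monthly SSTA: monthly mean of the anomaly component (deviation from
  # the seasonal cycle; trend and ENSO retained, as in observations)
  mgrp <- factor(mon_of_day, levels = seq_len(n_mon))
  monthly <- apply(anom, 2, function(v) tapply(v, mgrp, mean))
  monthly_ssta <- list(
    values = array(monthly, c(n_mon, nlat, nlon)),
    time = data.frame(year = config$start_year + (seq_len(n_mon) - 1) %/% 12,
                      month = (seq_len(n_mon) - 1) %% 12 + 1))

  out <- list(
    sst = sst,
    monthly_ssta = monthly_ssta,
    enso_index = cbind(monthly_ssta$time, index = idx),
    loading = loading,
    config = config)

  if (include_drivers) {
    couplings <- c(slp = config$slp_coupling,
                   wind_speed = config$wind_coupling,
                   u10 = config$uwind_coupling,
                   swdown = config$sw_coupling,
                   lwdown = config$lw_coupling,
                   lhf = config$lhf_coupling,
                   shf = config$shf_coupling)
    clim0 <- c(slp = 1013, wind_speed = 7, u10 = 2, swdown = 180,
               lwdown = 340, lhf = -100, shf = -15)
    units <- c(slp = "hPa", wind_speed = "m s-1", u10 = "m s-1",
               swdown = "W m-2", lwdown = "W m-2", lhf = "W m-2",
               shf = "W m-2")
    out$drivers <- lapply(stats::setNames(names(couplings), names(couplings)),
      function(f) {
        dn <- .ar1_matrix(nt, ncell, config$driver_ar1) *
          config$driver_sd[[f]]
        m <- clim0[[f]] + couplings[[f]] * anom + dn
        sst_cube(array(m, c(nt, nlat, nlon)), cal, config$lat, config$lon,
                 units = units[[f]])
      })
  }

  if (include_chl) {
    # chlorophyll response: suppression at low |lat|, enhancement poleward
    chl_coef <- ifelse(abs(config$lat) <= config$chl_lat_switch,
                       -config$chl_coupling, config$chl_coupling)
    chl_clim <- -1 + 0.8 * (abs(config$lat) / 60)  # log10 mg m-3
    coefv <- chl_coef[rep(seq_len(nlat), nlon)]
    chl_daily <- .ar1_matrix(nt, ncell, config$chl_ar1) * config$chl_sd +
      sweep(anom, 2, coefv, `*`)
    chl_daily <- sweep(chl_daily, 2, chl_clim[rep(seq_len(nlat), nlon)], `+`)
    out$chl <- bin_8day(chl_daily, cal, nlat, nlon)
    out$nitrate <- matrix(0.5 + 20 * (abs(config$lat) / 60)^2,
                          nlat, nlon)
  }
  class(out) <- "mhw_synth"
  out
}

# Average a daily time x cell matrix into 8-day composites (46 per year,
# the 46th covering 5 days), returning the chl composite container.
bin_8day <- function(mat, cal, nlat, nlon) {
  comp_in_year <- pmin((cal$doy - 1) %/% 8L + 1L, 46L)
  comp <- (cal$year - cal$year[1]) * 46L + comp_in_year
  grp <- factor(comp, levels = seq_len(max(comp)))
  binned <- apply(mat, 2, function(v) tapply(v, grp, mean))
  n_comp <- max(comp)
  time <- data.frame(
    year = cal$year[1] + (seq_len(n_comp) - 1) %/% 46,
    comp = (seq_len(n_comp) - 1) %% 46 + 1)
  time$start_doy <- (time$comp - 1) * 8 + 1
  time$mid_doy <- pmin(time$start_doy + 3.5, 363)
  list(data = array(binned, c(n_comp, nlat, nlon)), time = time,
       units = "log10 mg m-3")
}

#' Specification of an implanted heatwave event
#'
#' A rectangular footprint, start day, duration and peak anomaly amplitude
#' with a trapezoidal temporal shape (linear ramp up over `ramp_up` of the
#' duration, plateau at the peak amplitude, linear ramp down over
#' `ramp_down`).
#'
#' @param lat_min,lat_max,lon_min,lon_max footprint bounding box (cells
#'   whose centers fall inside are affected).
#' @param start running day index (`t` in the cube calendar) of the first
#'   event day.
#' @param duration event length in days (>= 1).
#' @param amplitude peak anomaly (degC).
#' @param ramp_up,ramp_down ramp fractions of the duration, in [0, 0.5].
#' @return a list of class `implant_spec`.
#' @export
implant_spec <- function(lat_min, lat_max, lon_min, lon_max,
                         start, duration, amplitude,
                         ramp_up = 0.2, ramp_down = 0.2) {
  stopifnot(duration >= 1, is.finite(amplitude),
            ramp_up >= 0, ramp_down >= 0, ramp_up + ramp_down <= 1)
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 start = as.integer(start), duration = as.integer(duration),
                 amplitude = amplitude,
                 ramp_up = ramp_up, ramp_down = ramp_down),
            class = "implant_spec")
}

# trapezoid shape, length == duration, peak == 1
.implant_shape <- function(spec) {
  d <- spec$duration
  n_up <- round(spec$ramp_up * d)
  n_dn <- round(spec$ramp_down * d)
  shape <- rep(1, d)
  if (n_up > 0) shape[seq_len(n_up)] <- seq_len(n_up) / (n_up + 1)
  if (n_dn > 0) shape[d - n_dn + seq_len(n_dn)] <- rev(seq_len(n_dn)) /
      (n_dn + 1)
  shape * spec$amplitude
}

.spec_cells <- function(spec, cells) {
  which(cells$lat >= spec$lat_min & cells$lat <= spec$lat_max &
          cells$lon >= spec$lon_min & cells$lon <= spec$lon_max)
}

#' Implant heatwave events with known truth
#'
#' Adds the specified anomalies on top of a generated field and returns
#' the modified field together with a truth table for parameter-recovery
#' tests. Specs that overlap in both space and time are rejected. Applied
#' to a full synthetic bundle, the coupled driver and chlorophyll fields
#' receive the matching linear responses, so implanted events behave like
#' generated ones downstream.
#'
#' @param x an [sst_cube()] or a bundle from [generate_fields()].
#' @param specs list of [implant_spec()]s.
#' @param sign `+1` to implant, `-1` to remove a previous implant exactly.
#' @return list with `field` (same class as `x`) and `truth` (data.frame,
#'   one row per spec: `event_id`, footprint bounds, `start`, `end`,
#'   `duration`, `amplitude_C`).
#' @export
implant_events <- function(x, specs, sign = 1) UseMethod("implant_events")

.check_overlap <- function(specs) {
  if (length(specs) < 2) return(invisible())
  for (i in seq_along(specs)) for (j in seq_len(i - 1)) {
    a <- specs[[i]]; b <- specs[[j]]
    sp <- a$lat_min <= b$lat_max && b$lat_min <= a$lat_max &&
      a$lon_min <= b$lon_max && b$lon_min <= a$lon_max
    tm <- a$start <= b$start + b$duration - 1 &&
      b$start <= a$start + a$duration - 1
    if (sp && tm)
      stop(sprintf("implant specs %d and %d overlap in space and time",
                   j, i))
  }
}

.truth_table <- function(specs) {
  if (length(specs) == 0)
    return(data.frame(event_id = integer(), lat_min = numeric(),
                      lat_max = numeric(), lon_min = numeric(),
                      lon_max = numeric(), start = integer(),
                      end = integer(), duration = integer(),
                      amplitude_C = numeric()))
  data.frame(
    event_id = seq_along(specs),
    lat_min = vapply(specs, `[[`, 0, "lat_min"),
    lat_max = vapply(specs, `[[`, 0, "lat_max"),
    lon_min = vapply(specs, `[[`, 0, "lon_min"),
    lon_max = vapply(specs, `[[`, 0, "lon_max"),
    start = vapply(specs, `[[`, 0L, "start"),
    end = vapply(specs, function(s) s$start + s$duration - 1L, 0L),
    duration = vapply(specs, `[[`, 0L, "duration"),
    amplitude_C = vapply(specs, `[[`, 0, "amplitude"))
}

# add spec anomalies (times `coef`) to a time x cell matrix in place
.apply_specs <- function(mat, specs, cells, coef = 1) {
  nt <- nrow(mat)
  for (spec in specs) {
    ix <- .spec_cells(spec, cells)
    if (length(ix) == 0) stop("implant footprint contains no grid cells")
    tt <- spec$start:(spec$start + spec$duration - 1L)
    if (min(tt) < 1 || max(tt) > nt)
      stop("implant dates fall outside the simulated span")
    mat[tt, ix] <- mat[tt, ix] + coef * .implant_shape(spec)
  }
  mat
}

#' @export
implant_events.sst_cube <- function(x, specs, sign = 1) {
  .check_overlap(specs)
  cells <- cube_cells(x)
  mat <- .apply_specs(cube_matrix(x), specs, cells, coef = sign)
  x$data <- array(mat, dim(x$data))
  list(field = x, truth = .truth_table(specs))
}

#' @export
implant_events.mhw_synth <- function(x, specs, sign = 1) {
  .check_overlap(specs)
  cfg <- x$config
  cells <- cube_cells(x$sst)
  x$sst$data <- array(.apply_specs(cube_matrix(x$sst), specs, cells, sign),
                      dim(x$sst$data))
  if (!is.null(x$drivers)) {
    couplings <- c(slp = cfg$slp_coupling, wind_speed = cfg$wind_coupling,
                   u10 = cfg$uwind_coupling, swdown = cfg$sw_coupling,
                   lwdown = cfg$lw_coupling, lhf = cfg$lhf_coupling,
                   shf = cfg$shf_coupling)
    for (f in names(x$drivers)) {
      cube <- x$drivers[[f]]
      cube$data <- array(
        .apply_specs(cube_matrix(cube), specs, cells,
                     coef = sign * couplings[[f]]),
        dim(cube$data))
      x$drivers[[f]] <- cube
    }
  }
  if (!is.null(x$chl)) {
    # rebuild the implant response at daily resolution, then 8-day bin
    cal <- x$sst$time
    nlat <- length(cfg$lat); nlon <- length(cfg$lon)
    chl_coef <- ifelse(abs(cells$lat) <= cfg$chl_lat_switch,
                       -cfg$chl_coupling, cfg$chl_coupling)
    add <- matrix(0, nrow(cal), nrow(cells))
    add <- .apply_specs(add, specs, cells, coef = sign)
    add <- sweep(add, 2, chl_coef, `*`)
    binned <- bin_8day(add, cal, nlat, nlon)
    x$chl$data <- x$chl$data + binned$data
  }
  list(field = x, truth = .truth_table(specs))
}

#' Duration of the longest heatwave as a function of warming trend
#'
#' Monte Carlo experiment on single-cell series: for each trend rate,
#' simulate daily SST (seasonal cycle + AR(1) noise + trend), hold the
#' percentile threshold to a fixed baseline period, detect events, and
#' record the duration of the longest event. Because warming shifts the
#' whole distribution towards a fixed threshold, mean longest duration
#' grows nonlinearly (convexly) with the trend rate.
#'
#' @param config a [synth_config()]; only the temporal/noise parameters
#'   are used (single cell at `ref_lat`).
#' @param trend_rates vector of trend rates (degC per decade).
#' @param replicates Monte Carlo replicates per rate.
#' @param baseline length-2 year range for the threshold climatology
#'   (default: years 2..31 of the simulated span, or the whole span if
#'   shorter).
#' @param ref_lat latitude of the simulated cell.
#' @param window,smooth climatology pooling and smoothing widths (days).
#' @return data.frame with one row per rate: `trend`, `mean_longest`
#'   (days), `se` (Monte Carlo standard error), `replicates`. The
#'   per-replicate longest durations and the calendar year of each
#'   longest event are attached as the `"replicate_detail"` attribute.
#' @export
trend_duration_experiment <- function(config, trend_rates, replicates,
                                      baseline = NULL, ref_lat = 40,
                                      window = 11, smooth = 31) {
  stopifnot(replicates >= 1)
  set.seed(config$seed)
  cal <- noleap_calendar(config$start_year, config$n_years)
  nt <- nrow(cal)
  if (is.null(baseline)) {
    y1 <- config$start_year + min(1L, config$n_years - 1L)
    y2 <- min(y1 + 29L, max(cal$year))
    baseline <- c(y1, y2)
  }
  phi <- ref_lat
  t0 <- config$t_eq - (config$t_eq - config$t_pole60) * (abs(phi) / 60)^2
  a <- config$amp_eq +
    (config$amp_mid - config$amp_eq) * abs(sin(2 * phi * pi / 180))
  peak <- if (phi >= 0) config$nh_peak_doy else
    ((config$nh_peak_doy - config$phase_offset - 1) %% 365) + 1
  seas <- t0 + a * cos(2 * pi * ((1:365) - peak) / 365)
  mod <- sqrt(pmax(1 + config$mod_b *
                     cos(2 * pi * ((1:365) - 197) / 365), 1e-6))
  sd_day <- config$noise_sd * mod[cal$doy]

  detail <- lapply(trend_rates, function(rate) {
    reps <- vapply(seq_len(replicates), function(k) {
      noise <- as.numeric(.ar1_matrix(nt, 1L, config$ar1)) * sd_day
      sst <- seas[cal$doy] + noise + rate / 10 / 365 * (seq_len(nt) - 1)
      clim <- .cell_climatology(sst, cal, baseline, window, smooth)
      ev <- detect_events_series(sst, clim$clim_mean, clim$pc90, cal)
      if (nrow(ev) == 0) return(c(0, NA))
      i <- which.max(ev$duration)
      c(ev$duration[i],
        cal$year[floor((ev$start[i] + ev$end[i]) / 2)])
    }, numeric(2))
    data.frame(trend = rate, rep = seq_len(replicates),
               longest = reps[1, ], central_year = reps[2, ])
  })
  detail <- do.call(rbind, detail)
  out <- do.call(rbind, lapply(split(detail, detail$trend), function(d)
    data.frame(trend = d$trend[1], mean_longest = mean(d$longest),
               se = stats::sd(d$longest) / sqrt(nrow(d)),
               replicates = nrow(d))))
  out <- out[order(out$trend), ]
  rownames(out) <- NULL
  attr(out, "replicate_detail") <- detail
  out
}
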