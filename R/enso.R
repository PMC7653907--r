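#' Nino3.4 index and ENSO phase classification
#'
#' Area-weighted mean monthly SST anomaly over the Nino3.4 box (5S--5N,
#' 170W--120W, i.e. 190--240 E), standardized by its standard deviation
#' over a base period. Phases: moderate El Nino (index > 1), strong
#' (> 2); La Nina the mirror image; neutral otherwise.
#'
#' @param monthly_ssta list with `values` (`[n_months, nlat, nlon]`) and
#'   `time` (data.frame `year`, `month`), as produced by
#'   [generate_fields()].
#' @param lat,lon grid-cell centers.
#' @param box `c(lat_min, lat_max, lon_min, lon_max)` averaging box
#'   (degrees, lon in 0--360).
#' @param base_years optional `c(first, last)` standardization period
#'   (default: all months).
#' @return data.frame of class `enso_series`: `year`, `month`, `index`
#'   (standardized), `phase` (factor: `strong_nina`, `moderate_nina`,
#'   `neutral`, `moderate_nino`, `strong_nino`).
#' @export
nino34_series <- function(monthly_ssta, lat, lon,
                          box = c(-5, 5, 190, 240), base_years = NULL) {
  nlat <- length(lat); nlon <- length(lon)
  cells <- data.frame(lat = rep(lat, nlon), lon = rep(lon, each = nlat))
  sel <- cells$lat >= box[1] & cells$lat <= box[2] &
    cells$lon >= box[3] & cells$lon <= box[4]
  if (!any(sel)) stop("Nino3.4 box contains no grid cells")
  dlat <- if (nlat > 1) diff(lat)[1] else 1
  dlon <- if (nlon > 1) diff(lon)[1] else 1
  w <- cell_areas(cells$lat[sel], dlat, dlon)
  mat <- matrix(monthly_ssta$values, nrow = dim(monthly_ssta$values)[1])
  raw <- as.numeric(mat[, sel, drop = FALSE] %*% (w / sum(w)))
  tm <- monthly_ssta$time
  in_base <- if (is.null(base_years)) rep(TRUE, nrow(tm)) else
    tm$year >= base_years[1] & tm$year <= base_years[2]
  s <- stats::sd(raw[in_base])
  idx <- if (s == 0) raw - mean(raw[in_base]) else
    (raw - mean(raw[in_base])) / s
  phase <- cut(idx, c(-Inf, -2, -1, 1, 2, Inf),
               labels = c("strong_nina", "moderate_nina", "neutral",
                          "moderate_nino", "strong_nino"))
  out <- data.frame(year = tm$year, month = tm$month, index = idx,
                    phase = phase)
  class(out) <- c("enso_series", "data.frame")
  out
}

#' Record attainment by month and ENSO phase
#'
#' The area fraction of the ocean attaining its record (severity,
#' intensity or duration) in each month, and the cumulative area fraction
#' attained during each ENSO phase, against the fraction of months spent
#' in that phase (the null expectation if records were independent of
#' ENSO).
#'
#' @param records a [record_maps()] table.
#' @param enso an `enso_series` from [nino34_series()].
#' @param cal daily calendar of the record.
#' @param metric `"max_sev"`, `"max_int"` or `"duration"` (attributed to
#'   the event's central date, as duration has no single record day).
#' @return list: `monthly` (data.frame `year`, `month`, `index`, `phase`,
#'   `frac` of ocean area attaining its record that month), `by_phase`
#'   (data.frame `phase`, `months_frac`, `area_frac`).
#' @export
record_fraction_by_phase <- function(records, enso, cal,
                                     metric = "max_sev") {
  tcol <- switch(metric, max_int = "t_max_int", max_sev = "t_max_sev",
                 duration = "t_longest_central",
                 stop("unknown metric"))
  tt <- records[[tcol]]
  ulat <- sort(unique(records$lat))
  ulon <- sort(unique(records$lon))
  area <- cell_areas(records$lat, diff(ulat)[1],
                     if (length(ulon) > 1) diff(ulon)[1] else 360)
  atot <- sum(area[!is.na(tt)])
  mkey <- function(y, m) (y - enso$year[1]) * 12 + m
  rec_m <- ifelse(is.na(tt), NA, mkey(cal$year[tt], cal$month[tt]))
  monthly <- enso
  monthly$frac <- vapply(seq_len(nrow(enso)), function(i)
    sum(area[which(rec_m == i)]) / atot, 0)
  by_phase <- do.call(rbind, lapply(levels(enso$phase), function(p) {
    sel <- enso$phase == p
    data.frame(phase = p, months_frac = mean(sel),
               area_frac = sum(monthly$frac[sel]))
  }))
  list(monthly = monthly, by_phase = by_phase)
}

#' Regression of the ENSO index onto the SST anomaly field
#'
#' Per-cell ordinary least-squares slope of monthly SSTA on the
#' standardized index (degC per index standard deviation). Cells with
#' fewer than `min_months` overlapping months are masked.
#'
#' @param enso an `enso_series` from [nino34_series()].
#' @param monthly_ssta monthly anomaly container (see [nino34_series()]).
#' @param nlat,nlon grid shape.
#' @param min_months minimum overlap.
#' @return list: `slope` matrix `[nlat, nlon]`, `se` matrix of standard
#'   errors.
#' @export
regress_index_map <- function(enso, monthly_ssta, nlat, nlon,
                              min_months = 24) {
  x <- enso$index
  Y <- matrix(monthly_ssta$values, nrow = length(x))
  ok <- stats::complete.cases(x)
  n_ok <- colSums(!is.na(Y[ok, , drop = FALSE]))
  xc <- x[ok] - mean(x[ok])
  Yok <- Y[ok, , drop = FALSE]
  sxx <- sum(xc^2)
  slope <- as.numeric(crossprod(xc, sweep(Yok, 2, colMeans(Yok))) / sxx)
  fit <- outer(xc, slope)
  resid <- sweep(Yok, 2, colMeans(Yok)) - fit
  n <- sum(ok)
  se <- sqrt(colSums(resid^2) / (n - 2) / sxx)
  slope[n_ok < min_months] <- NA
  se[n_ok < min_months] <- NA
  list(slope = matrix(slope, nlat, nlon), se = matrix(se, nlat, nlon))
}
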