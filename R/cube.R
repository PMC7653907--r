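#' No-leap calendar table
#'
#' Builds the day-by-day calendar used throughout the package: every year
#' has 365 days (February always has 28). Working on a no-leap calendar
#' removes the leap-day special case from climatology indexing; real
#' observations with leap days can be mapped onto it with
#' [noleap_doy()].
#'
#' @param start_year first calendar year.
#' @param n_years number of whole years.
#' @return data.frame with columns `year`, `month`, `day`, `doy` (1--365)
#'   and `t` (running day index starting at 1).
#' @export
noleap_calendar <- function(start_year, n_years) {
  stopifnot(n_years >= 1)
  mlen <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  month <- rep(rep.int(1:12, mlen), n_years)
  day <- rep(unlist(lapply(mlen, seq_len)), n_years)
  doy <- rep(1:365, n_years)
  year <- rep(start_year + seq_len(n_years) - 1L, each = 365L)
  data.frame(year = year, month = month, day = day, doy = doy,
             t = seq_along(year))
}

#' Map calendar dates onto no-leap day-of-year
#'
#' Feb 29 observations are assigned doy 59 (Feb 28), so they pool into the
#' Feb 28 climatology window; all later days keep their no-leap doy.
#'
#' @param dates a `Date` vector.
#' @return integer day-of-year in 1..365.
#' @export
noleap_doy <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  cml <- cumsum(c(0L, 31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L))
  doy <- cml[m] + pmin(d, ifelse(m == 2L, 28L, 31L))
  as.integer(doy)
}

#' Gridded daily field container
#'
#' The package's primary container for a daily field on a regular
#' latitude--longitude grid: a 3-D array indexed `[time, lat, lon]`
#' together with the no-leap calendar and the grid axes. Used for SST,
#' atmospheric driver fields and (with an 8-day time axis) chlorophyll.
#'
#' @param data numeric array `[n_time, n_lat, n_lon]`.
#' @param time calendar data.frame as from [noleap_calendar()] (or any
#'   data.frame with `year`, `month`, `doy`, `t` columns of length
#'   `n_time`).
#' @param lat,lon grid-cell center coordinates (degrees); `lat` increasing,
#'   `lon` in `[0, 360)`.
#' @param units unit string carried as metadata.
#' @return an object of class `sst_cube`.
#' @export
sst_cube <- function(data, time, lat, lon, units = "degC") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stopifnot(dim(data)[1] == nrow(time),
            dim(data)[2] == length(lat),
            dim(data)[3] == length(lon))
  structure(list(data = data, time = time, lat = lat, lon = lon,
                 units = units),
            class = "sst_cube")
}

#' @export
print.sst_cube <- function(x, ...) {
  cat(sprintf("<sst_cube> %d days x %d lat x %d lon [%s]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$units))
  cat(sprintf("  years %d-%d; lat %.1f..%.1f; lon %.1f..%.1f\n",
              min(x$time$year), max(x$time$year),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Flatten a cube to a time x cell matrix
#'
#' Cells are ordered latitude-fastest (column `k` holds grid cell
#' `ilat = (k - 1) %% n_lat + 1`, `ilon = (k - 1) %/% n_lat + 1`).
#'
#' @param cube an [sst_cube()].
#' @return numeric matrix `[n_time, n_lat * n_lon]`.
#' @keywords internal
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1], ncol = d[2] * d[3])
}

#' Cell index bookkeeping for a cube grid
#'
#' @param cube an [sst_cube()] (or any list with `lat`, `lon`).
#' @return data.frame with one row per cell: `cell`, `ilat`, `ilon`,
#'   `lat`, `lon`, in the latitude-fastest order used by [cube_matrix()].
#' @export
cube_cells <- function(cube) {
  nlat <- length(cube$lat)
  nlon <- length(cube$lon)
  data.frame(cell = seq_len(nlat * nlon),
             ilat = rep(seq_len(nlat), nlon),
             ilon = rep(seq_len(nlon), each = nlat),
             lat = rep(cube$lat, nlon),
             lon = rep(cube$lon, each = nlat))
}

#' Area-weighted spatial mean of a field over a set of cells
#'
#' @param mat time x cell matrix (as from [cube_matrix()]).
#' @param cells integer cell indices.
#' @param w per-cell weights aligned with `cells` (typically areas).
#' @return numeric vector over time.
#' @keywords internal
wmean_cells <- function(mat, cells, w) {
  w <- w / sum(w)
  as.numeric(mat[, cells, drop = FALSE] %*% w)
}
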