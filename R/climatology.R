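# circular moving average over a 365-day axis (matrix columns are cells)
.circ_ma <- function(x, width) {
  if (width <= 1) return(x)
  as.matrix(stats::filter(x, rep(1 / width, width), sides = 2,
                          circular = TRUE))
}

# quantile of a numeric vector: type 7 (linear interpolation between
# order statistics, the default convention) or type 1 (nearest rank)
.qtl <- function(x, p, type = 7) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (type == 1) {
    j <- ceiling(n * p)
    return(sort(x, partial = j)[j])
  }
  h <- (n - 1) * p + 1
  j <- floor(h)
  xs <- sort(x, partial = c(j, min(j + 1, n)))
  if (j == n) return(xs[n])
  xs[j] + (h - j) * (xs[j + 1] - xs[j])
}

# climatology for one cell: series `sst` on calendar `cal`; baseline a
# year range; returns raw-then-smoothed clim_mean / pc90 on 365 days
.cell_climatology <- function(sst, cal, baseline, window = 11,
                              smooth = 31, percentile = 0.9, type = 7) {
  half <- (window - 1L) %/% 2L
  in_base <- cal$year >= baseline[1] & cal$year <= baseline[2]
  v <- sst[in_base]
  doy <- cal$doy[in_base]
  ny <- length(v) / 365
  # values as [ny x 365]; baseline years are whole no-leap years
  V <- matrix(v[order(doy)], nrow = ny, ncol = 365)
  wrap <- function(d) ((d - 1L) %% 365L) + 1L
  idx <- vapply(1:365, function(d) wrap((d - half):(d + half)),
                integer(window))                       # [window x 365]
  pooled <- matrix(V[, as.vector(idx)], nrow = ny * window)
  clim_raw <- colMeans(pooled, na.rm = TRUE)
  pc_raw <- vapply(1:365, function(d) .qtl(pooled[, d], percentile, type),
                   0)
  clim <- as.numeric(.circ_ma(cbind(clim_raw), smooth))
  pc <- as.numeric(.circ_ma(cbind(pc_raw), smooth))
  list(clim_mean = clim, pc90 = pc,
       degenerate = !is.finite(pc - clim) | (pc - clim) <= 1e-8)
}

#' Day-of-year climatology and 90th-percentile threshold
#'
#' For every grid cell and day-of-year `d`, pools all baseline values
#' whose day-of-year lies within a centered window around `d` (circular
#' across the year boundary), takes their mean (`clim_mean`) and their
#' 90th percentile (`pc90`), and smooths both along the day-of-year axis
#' with a centered circular moving average. Cells/days where the
#' threshold does not exceed the mean (zero local variance) are flagged
#' degenerate.
#'
#' @param sst an [sst_cube()] of daily SST.
#' @param baseline inclusive year range `c(first, last)` defining
#'   "normal"; must lie inside the record and span at least one year.
#' @param window pooling window width in days (odd).
#' @param smooth smoothing width in days (odd); applied to both fields.
#' @param percentile threshold probability (0.9 for the standard
#'   definition).
#' @param quantile_type 7 for linear interpolation between order
#'   statistics (default convention), 1 for nearest rank.
#' @return an object of class `mhw_climatology`: `clim_mean` and `pc90`
#'   arrays `[365, nlat, nlon]`, logical `degenerate` of the same shape,
#'   plus the parameters used.
#' @export
build_climatology <- function(sst, baseline, window = 11, smooth = 31,
                              percentile = 0.9, quantile_type = 7) {
  stopifnot(inherits(sst, "sst_cube"))
  if (window %% 2 != 1 || smooth %% 2 != 1 || window < 1 || smooth < 1)
    stop("window and smooth must be odd positive integers")
  yrs <- range(sst$time$year)
  if (baseline[1] < yrs[1] || baseline[2] > yrs[2])
    stop("baseline must lie inside the SST record")
  if (baseline[2] < baseline[1])
    stop("baseline must span at least one year")
  nlat <- length(sst$lat)
  nlon <- length(sst$lon)
  mat <- cube_matrix(sst)
  ncell <- ncol(mat)
  clim <- matrix(NA_real_, 365, ncell)
  pc <- matrix(NA_real_, 365, ncell)
  degen <- matrix(TRUE, 365, ncell)
  for (k in seq_len(ncell)) {
    if (all(is.na(mat[, k]))) next  # land / all-missing cell stays masked
    cc <- .cell_climatology(mat[, k], sst$time, baseline, window, smooth,
                            percentile, quantile_type)
    clim[, k] <- cc$clim_mean
    pc[, k] <- cc$pc90
    degen[, k] <- cc$degenerate
  }
  structure(list(clim_mean = array(clim, c(365, nlat, nlon)),
                 pc90 = array(pc, c(365, nlat, nlon)),
                 degenerate = array(degen, c(365, nlat, nlon)),
                 baseline = baseline, window = window, smooth = smooth,
                 percentile = percentile, quantile_type = quantile_type,
                 lat = sst$lat, lon = sst$lon),
            class = "mhw_climatology")
}

#' @export
print.mhw_climatology <- function(x, ...) {
  cat(sprintf(paste0("<mhw_climatology> baseline %d-%d, window %d d, ",
                     "smooth %d d, percentile %.2f\n"),
              x$baseline[1], x$baseline[2], x$window, x$smooth,
              x$percentile))
  invisible(x)
}

#' Remove the seasonally varying linear warming trend
#'
#' For each cell and each day-of-year (pooled with the same centered
#' window used for climatologies), fits an ordinary least-squares linear
#' trend in year and subtracts it, so the output has zero per-day linear
#' trend by construction. Used as a sensitivity variant: record maps can
#' be recomputed on the detrended field to ask how much of a result is
#' owed to secular warming.
#'
#' @param sst an [sst_cube()] spanning at least 10 years.
#' @param window day-of-year pooling width (odd).
#' @return an [sst_cube()] of the same shape.
#' @export
remove_seasonal_trend <- function(sst, window = 11) {
  stopifnot(inherits(sst, "sst_cube"))
  ny <- length(unique(sst$time$year))
  if (ny < 10) stop("record must span at least 10 years")
  if (nrow(sst$time) != ny * 365)
    stop("record must consist of whole no-leap years")
  half <- (window - 1L) %/% 2L
  mat <- cube_matrix(sst)
  yr <- sst$time$year
  doy <- sst$time$doy
  ybar <- mean(unique(yr))
  ydev <- unique(yr) - ybar
  syy <- sum(ydev^2)
  ord <- order(doy, yr)
  for (k in seq_len(ncol(mat))) {
    v <- mat[, k]
    if (all(is.na(v))) next
    V <- matrix(v[ord], nrow = ny, ncol = 365)     # [year x doy]
    cm <- colMeans(V, na.rm = TRUE)
    C <- colSums((V - rep(cm, each = ny)) * ydev, na.rm = TRUE)  # per-doy
    slope <- as.numeric(.circ_ma(cbind(C), window)) / syy  # pooled OLS
    mat[, k] <- v - slope[doy] * (yr - ybar)
  }
  sst$data <- array(mat, dim(sst$data))
  sst
}
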