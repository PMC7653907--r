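#' Region-mean chlorophyll anomaly series
#'
#' Area-weighted regional mean of the 8-day chlorophyll composites
#' (log10 space by default), as anomalies from the long-term climatology
#' of each composite-of-year.
#'
#' @param chl 8-day composite container (`data` `[n_comp, nlat, nlon]`,
#'   `time` with `year`/`comp`), e.g. from [generate_fields()].
#' @param cells integer cell indices of the region.
#' @param lat,lon grid axes (for area weights).
#' @param log_space if FALSE, anomalies are computed after transforming
#'   the stored log10 values back to concentration.
#' @return data.frame per composite: `year`, `comp`, `value`, `anom`.
#' @export
chl_region_series <- function(chl, cells, lat, lon, log_space = TRUE) {
  area_vec <- .cell_area_vec(lat, lon)
  mat <- matrix(chl$data, nrow = dim(chl$data)[1])
  if (!log_space) mat <- 10^mat
  v <- wmean_cells(mat, cells, area_vec[cells])
  clim <- stats::ave(v, chl$time$comp, FUN = function(x) mean(x, na.rm = TRUE))
  data.frame(year = chl$time$year, comp = chl$time$comp,
             value = v, anom = v - clim)
}

#' Chlorophyll response to an extreme heatwave
#'
#' The regional chlorophyll anomaly averaged over the three 8-day
#' composites covering the 24-day window centred on the heatwave peak,
#' normalized by the standard deviation of the regional anomaly series
#' over the full record. Events predating the chlorophyll record return
#' NA with a reason (in the observational analogue only 52 of 62 regions
#' are analyzable for exactly this reason).
#'
#' @param chl 8-day composite container.
#' @param region characterized region (needs `id`, `cells`,
#'   `lat_center`, `peak_t`).
#' @param cal daily calendar of the SST record (maps `peak_t` onto a
#'   composite).
#' @param lat,lon grid axes.
#' @param log_space see [chl_region_series()].
#' @return one-row data.frame: `region_id`, `norm_anom`, `lat_center`,
#'   `sign`, `peak_comp`, `reason` (NA on success).
#' @export
chl_mhw_response <- function(chl, region, cal, lat, lon,
                             log_space = TRUE) {
  out <- data.frame(region_id = region$id, norm_anom = NA_real_,
                    lat_center = region$lat_center, sign = NA_integer_,
                    peak_comp = NA_integer_, reason = NA_character_)
  if (is.null(region$peak_t) || is.na(region$peak_t)) {
    out$reason <- "no peak date"
    return(out)
  }
  py <- cal$year[region$peak_t]
  pdoy <- cal$doy[region$peak_t]
  ci <- which(chl$time$year == py &
                chl$time$comp == pmin((pdoy - 1) %/% 8 + 1, 46))
  if (length(ci) == 0) {
    out$reason <- "peak outside chlorophyll record"
    return(out)
  }
  ser <- chl_region_series(chl, region$cells, lat, lon, log_space)
  win <- intersect((ci - 1):(ci + 1), seq_len(nrow(ser)))
  sdv <- stats::sd(ser$anom, na.rm = TRUE)
  out$norm_anom <- mean(ser$anom[win], na.rm = TRUE) / sdv
  out$sign <- as.integer(sign(out$norm_anom))
  out$peak_comp <- ci
  out
}

#' Exact binomial sign test
#'
#' One-sided tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`: the
#' chance that at least `k` of `n` independent regions would share the
#' observed response sign if signs were coin flips.
#'
#' @param k number of regions with the tested sign.
#' @param n number of regions tested (> 0).
#' @param p0 null probability of the sign.
#' @return the exact one-sided p-value.
#' @export
sign_binomial_test <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Monte Carlo null for a windowed chlorophyll anomaly
#'
#' Draws window anomalies centred on randomly chosen composites that do
#' not correspond to heatwave conditions in the region, building the
#' null distribution of the 3-composite window anomaly; the empirical
#' two-sided p-value for the observed anomaly uses the add-one
#' correction `p = (1 + #{|null| >= |obs|}) / (n + 1)`.
#'
#' @param chl 8-day composite container.
#' @param region region (needs `cells`).
#' @param observed observed window anomaly on the same scale as the
#'   series (not normalized).
#' @param exclude_comps composite indices counted as heatwave-affected
#'   and excluded from the null.
#' @param n_resamples number of draws.
#' @param seed integer seed (results are reproducible for a fixed seed).
#' @param lat,lon grid axes.
#' @param log_space see [chl_region_series()].
#' @return list: `p`, `null` (numeric vector), `n_candidates`.
#' @export
monte_carlo_null <- function(chl, region, observed, exclude_comps,
                             n_resamples = 10000, seed = 1, lat, lon,
                             log_space = TRUE) {
  ser <- chl_region_series(chl, region$cells, lat, lon, log_space)
  n_comp <- nrow(ser)
  candidates <- setdiff(seq_len(n_comp), exclude_comps)
  candidates <- candidates[candidates > 1 & candidates < n_comp]
  if (length(candidates) < 100)
    stop("fewer than 100 candidate non-heatwave composites")
  set.seed(seed)
  centers <- sample(candidates, n_resamples, replace = TRUE)
  null <- (ser$anom[centers - 1] + ser$anom[centers] +
             ser$anom[centers + 1]) / 3
  p <- (1 + sum(abs(null) >= abs(observed), na.rm = TRUE)) /
    (n_resamples + 1)
  list(p = p, null = null, n_candidates = length(candidates))
}

#' Chlorophyll response versus climatological nitrate
#'
#' Pairs each region's normalized chlorophyll anomaly with its
#' climatological surface nitrate and latitude, and summarizes the
#' latitudinal sign structure: the fraction of negative responses in the
#' tropical band (|lat| <= 20) and outside it, and the Spearman rank
#' correlation between nitrate and the anomaly.
#'
#' @param responses data.frame of [chl_mhw_response()] rows.
#' @param nitrate matrix `[nlat, nlon]` (umol kg-1).
#' @param regions list of regions aligned with `responses` by `id`.
#' @param lat,lon grid axes.
#' @return list: `table` (per region: `region_id`, `norm_anom`,
#'   `lat_center`, `abs_lat`, `nitrate`, `sign`), `summary` (list
#'   `frac_negative_tropical`, `frac_negative_extratropical`,
#'   `rank_cor`, `n`).
#' @export
nitrate_relation <- function(responses, nitrate, regions, lat, lon) {
  if (nrow(responses) == 0)
    return(list(table = data.frame(), summary = list(
      frac_negative_tropical = NA, frac_negative_extratropical = NA,
      rank_cor = NA, n = 0)))
  nit <- vapply(regions, function(r)
    mean(nitrate[r$cells], na.rm = TRUE), 0)
  tab <- responses
  tab$nitrate <- nit[match(tab$region_id,
                           vapply(regions, `[[`, 0L, "id"))]
  tab$abs_lat <- abs(tab$lat_center)
  ok <- !is.na(tab$norm_anom)
  trop <- ok & tab$abs_lat <= 20
  extr <- ok & tab$abs_lat > 20
  rc <- if (sum(ok) >= 3)
    stats::cor(tab$nitrate[ok], tab$norm_anom[ok], method = "spearman")
  else NA_real_
  list(table = tab,
       summary = list(
         frac_negative_tropical =
           if (any(trop)) mean(tab$norm_anom[trop] < 0) else NA_real_,
         frac_negative_extratropical =
           if (any(extr)) mean(tab$norm_anom[extr] < 0) else NA_real_,
         rank_cor = rc, n = sum(ok)))
}
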