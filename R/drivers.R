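#' Normalized calendar-window anomaly of a driver field
#'
#' The mean of a daily series over a fixed window relative to an event
#' peak (pre: 6 to 2 weeks before; post: 2 to 6 weeks after, by
#' default), expressed as an anomaly from the climatological mean of the
#' same calendar window across all available years, and normalized by the
#' across-years standard deviation of that window. Because the
#' comparison set is the same calendar window every year, the anomaly is
#' seasonality-free by construction and invariant to adding any constant
#' to the field.
#'
#' Flags rank the window by the magnitude of its deviation from the
#' calendar-window climatology: `record` means the most extreme deviation
#' of all years (in either direction — a record low-pressure anomaly is a
#' record), `top_decile` that it ranks within the most extreme
#' `floor(n_years / 10)` (at least 1) deviations. `record` implies
#' `top_decile`, and under a null field the top-decile rate is the decile
#' fraction by construction.
#'
#' @param series daily values (typically an area-weighted region mean).
#' @param cal calendar aligned with `series`.
#' @param peak_t running day index of the event peak.
#' @param phase `"pre"` or `"post"`.
#' @param weeks `c(far, near)` bounds of the window in weeks from the
#'   peak: `c(6, 2)` gives days -42..-15 before (or +15..+42 after) the
#'   peak; the 3-week variant is `c(6, 3)`.
#' @param min_coverage minimum fraction of window days inside the record
#'   for a truncated window to still be evaluated.
#' @return list: `anom` (normalized), `raw_anom` (field units),
#'   `clim_mean`, `sd`, `top_decile`, `record`, `n_years`, `truncated`.
#'   `anom` is NA when coverage is insufficient.
#' @export
window_normalized_anomaly <- function(series, cal, peak_t,
                                      phase = c("pre", "post"),
                                      weeks = c(6, 2),
                                      min_coverage = 0.75) {
  phase <- match.arg(phase)
  far <- max(weeks) * 7L
  near <- min(weeks) * 7L + 1L
  offsets <- if (phase == "pre") -(far:near) else near:far
  nt <- length(series)
  # the same calendar window in every year of the record
  shifts <- 365L * (-(ceiling(nt / 365)):(ceiling(nt / 365)))
  win_len <- length(offsets)
  rows <- lapply(shifts, function(s) {
    tt <- peak_t + offsets + s
    inside <- tt >= 1 & tt <= nt
    if (sum(inside) < min_coverage * win_len) return(NULL)
    c(mean(series[tt[inside]], na.rm = TRUE), s == 0,
      sum(inside) < win_len)
  })
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(rows) || !any(rows[, 2] == 1))
    return(list(anom = NA_real_, raw_anom = NA_real_,
                clim_mean = NA_real_, sd = NA_real_,
                top_decile = NA, record = NA, n_years = 0,
                truncated = TRUE))
  vals <- rows[, 1]
  own <- which(rows[, 2] == 1)
  n_years <- length(vals)
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  raw <- vals[own] - mu
  anom <- if (sdv == 0) (if (raw == 0) 0 else NA_real_) else raw / sdv
  m_decile <- max(1L, floor(n_years / 10))
  r <- sum(abs(vals - mu) >= abs(raw))   # 1 = most extreme deviation
  list(anom = anom, raw_anom = raw, clim_mean = mu, sd = sdv,
       top_decile = r <= m_decile, record = r == 1L,
       n_years = n_years, truncated = any(rows[own, 3] == 1))
}

#' Driver composites across extreme regions
#'
#' For every region and atmospheric field, the normalized pre-peak and
#' post-peak window anomalies of the area-weighted region-mean series,
#' with top-decile/record flags; plus the per-field sign-agreement
#' percentages (fraction of regions with positive anomaly) and the
#' cross-region Pearson correlation between pre-peak wind-speed and
#' latent-heat-flux anomalies.
#'
#' @param regions list of characterized regions (need `id`, `cells`,
#'   `peak_t`).
#' @param fields named list of driver [sst_cube()]s on a common grid and
#'   calendar.
#' @param weeks window definition, see [window_normalized_anomaly()].
#' @return list: `table` (data.frame `region_id`, `field`, `phase`,
#'   `norm_anom`, `top_decile`, `record`), `sign_agreement` (data.frame
#'   `field`, `phase`, `pct_positive`, `n`), `wind_latent_cor` (list
#'   `r`, `p`, `n`; NULL unless both `wind_speed` and `lhf` fields are
#'   present). Regions without a peak date are excluded.
#' @export
driver_composites <- function(regions, fields, weeks = c(6, 2)) {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  f1 <- fields[[1]]
  cal <- f1$time
  area_vec <- .cell_area_vec(f1$lat, f1$lon)
  mats <- lapply(fields, cube_matrix)
  rows <- list()
  for (reg in regions) {
    if (is.null(reg$peak_t) || is.na(reg$peak_t)) next
    for (fn in names(fields)) {
      series <- wmean_cells(mats[[fn]], reg$cells, area_vec[reg$cells])
      for (ph in c("pre", "post")) {
        wa <- window_normalized_anomaly(series, cal, reg$peak_t, ph,
                                        weeks)
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = reg$id, field = fn, phase = ph,
          norm_anom = wa$anom, top_decile = wa$top_decile,
          record = wa$record)
      }
    }
  }
  tab <- as.data.frame(data.table::rbindlist(rows))
  sign_agreement <- stats::aggregate(
    norm_anom ~ field + phase, data = tab[!is.na(tab$norm_anom), ],
    FUN = function(v) 100 * mean(v > 0))
  names(sign_agreement)[3] <- "pct_positive"
  nn <- stats::aggregate(norm_anom ~ field + phase,
                         data = tab[!is.na(tab$norm_anom), ],
                         FUN = length)
  sign_agreement$n <- nn$norm_anom
  wl <- NULL
  if (all(c("wind_speed", "lhf") %in% names(fields))) {
    pre <- tab[tab$phase == "pre", ]
    w <- pre$norm_anom[pre$field == "wind_speed"]
    l <- pre$norm_anom[pre$field == "lhf"]
    ok <- !is.na(w) & !is.na(l)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(w[ok], l[ok])
      wl <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  }
  list(table = tab, sign_agreement = sign_agreement,
       wind_latent_cor = wl)
}
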