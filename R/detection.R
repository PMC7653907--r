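#' Severity category from a severity value
#'
#' Bands the continuous severity index into the standard categories:
#' 0 = none (S <= 1), 1 = moderate (1 < S <= 2), 2 = strong (2 < S <= 3),
#' 3 = severe (3 < S <= 4), 4 = extreme (S > 4).
#'
#' @param s numeric severity values.
#' @return integer categories (NA preserved).
#' @export
severity_category <- function(s) {
  out <- integer(length(s))
  out[is.na(s)] <- NA_integer_
  pos <- !is.na(s) & s > 1
  out[pos] <- pmin(4L, as.integer(ceiling(s[pos] - 1e-12)) - 1L)
  out
}

#' Severity index field
#'
#' Computes the dimensionless severity `S = (SST - clim) / (pc90 - clim)`
#' at every grid point and day: S = 0 at the climatological mean, S = 1
#' exactly at the threshold, and the category bands follow
#' [severity_category()]. Where the threshold equals the mean (degenerate
#' cells) the field is masked rather than infinite, and the number of
#' masked points is reported via a message.
#'
#' Category is an event-level notion: a day only counts once the 5-day
#' duration rule is met. If an event table is supplied, the `category`
#' array is zeroed outside detected events and an `in_event` mask is
#' included.
#'
#' @param sst an [sst_cube()].
#' @param clim an [mhw_climatology()][build_climatology] on the same grid.
#' @param events optional event table from [detect_events_grid()].
#' @return list of class `severity_field`: `S` and integer `category`
#'   arrays `[time, lat, lon]`, optional logical `in_event`, plus the
#'   calendar and grid axes.
#' @export
severity <- function(sst, clim, events = NULL) {
  stopifnot(inherits(sst, "sst_cube"), inherits(clim, "mhw_climatology"))
  if (!isTRUE(all.equal(sst$lat, clim$lat)) ||
      !isTRUE(all.equal(sst$lon, clim$lon)))
    stop("SST and climatology grids are not aligned")
  doy <- sst$time$doy
  nt <- length(doy)
  cm <- matrix(clim$clim_mean, 365)[doy, , drop = FALSE]
  den <- matrix(clim$pc90 - clim$clim_mean, 365)[doy, , drop = FALSE]
  dg <- matrix(clim$degenerate, 365)[doy, , drop = FALSE]
  den[dg] <- NA_real_
  s <- (cube_matrix(sst) - cm) / den
  n_masked <- sum(dg & !is.na(cube_matrix(sst)))
  if (n_masked > 0)
    message(sprintf("severity: %d point-days masked (degenerate threshold)",
                    n_masked))
  cat_mat <- matrix(severity_category(s), nt)
  out <- list(S = array(s, dim(sst$data)),
              ssta = array(cube_matrix(sst) - cm, dim(sst$data)),
              category = array(cat_mat, dim(sst$data)),
              time = sst$time, lat = sst$lat, lon = sst$lon)
  if (!is.null(events)) {
    inev <- matrix(FALSE, nt, ncol(s))
    for (i in seq_len(nrow(events)))
      inev[events$start[i]:events$end[i], events$cell[i]] <- TRUE
    out$category[!inev] <- 0L
    out$in_event <- array(inev, dim(sst$data))
  }
  class(out) <- "severity_field"
  out
}

#' Detect heatwave events in a single-cell series
#'
#' A marine heatwave is a run of at least `min_duration` consecutive days
#' with SST strictly above the seasonally varying threshold; two
#' qualifying runs separated by at most `max_gap` days below the
#' threshold are merged into a single event whose span includes the gap
#' days. Missing days are treated as below threshold and therefore break
#' runs. Event metrics are computed from the daily anomaly
#' `SSTA = SST - clim_mean` over the merged span (gap days included).
#'
#' @param sst numeric daily series.
#' @param clim_mean,pc90 365-value day-of-year climatology and threshold
#'   for this cell.
#' @param cal calendar data.frame aligned with `sst` (needs `doy`).
#' @param min_duration minimum event length in days.
#' @param max_gap longest below-threshold interruption absorbed into an
#'   event (days); the literal reading of the "below threshold for less
#'   than 2 days" rule gives 1.
#' @return data.frame with one row per event: `start`, `end` (day
#'   indices), `duration`, `max_int` (degC) and `t_max_int`, `cum_int`
#'   (degC days), `max_sev`, `t_max_sev`, `category`.
#' @export
detect_events_series <- function(sst, clim_mean, pc90, cal,
                                 min_duration = 5, max_gap = 1) {
  nt <- length(sst)
  empty <- data.frame(start = integer(), end = integer(),
                      duration = integer(), max_int = numeric(),
                      t_max_int = integer(), cum_int = numeric(),
                      max_sev = numeric(), t_max_sev = integer(),
                      category = integer())
  if (nt < min_duration) return(empty)
  thr <- pc90[cal$doy]
  above <- !is.na(sst) & !is.na(thr) & sst > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_duration)
  if (length(qual) == 0) return(empty)
  # merge qualifying runs separated by <= max_gap days not above threshold
  ev_start <- starts[qual[1]]
  ev_end <- ends[qual[1]]
  spans <- list()
  for (q in qual[-1]) {
    if (starts[q] - ev_end - 1L <= max_gap) {
      ev_end <- ends[q]
    } else {
      spans[[length(spans) + 1L]] <- c(ev_start, ev_end)
      ev_start <- starts[q]
      ev_end <- ends[q]
    }
  }
  spans[[length(spans) + 1L]] <- c(ev_start, ev_end)

  cm <- clim_mean[cal$doy]
  den <- pc90[cal$doy] - cm
  den[den <= 1e-8] <- NA_real_
  ssta <- sst - cm
  sev <- ssta / den
  res <- lapply(spans, function(sp) {
    tt <- sp[1]:sp[2]
    a <- ssta[tt]
    s <- sev[tt]
    i_max <- tt[which.max(a)]
    i_sev <- tt[which.max(s)]
    ms <- suppressWarnings(max(s, na.rm = TRUE))
    data.frame(start = sp[1], end = sp[2],
               duration = sp[2] - sp[1] + 1L,
               max_int = max(a, na.rm = TRUE), t_max_int = i_max,
               cum_int = sum(a, na.rm = TRUE),
               max_sev = ms, t_max_sev = i_sev,
               category = severity_category(ms))
  })
  do.call(rbind, res)
}

#' Detect heatwave events on the whole grid
#'
#' Runs [detect_events_series()] at every cell and assembles a single
#' event table.
#'
#' @param sst an [sst_cube()].
#' @param clim an [mhw_climatology()][build_climatology] on the same grid.
#' @inheritParams detect_events_series
#' @return data.frame: `cell`, `ilat`, `ilon`, `lat`, `lon` plus the
#'   per-event columns of [detect_events_series()].
#' @export
detect_events_grid <- function(sst, clim, min_duration = 5, max_gap = 1) {
  stopifnot(inherits(sst, "sst_cube"), inherits(clim, "mhw_climatology"))
  mat <- cube_matrix(sst)
  cm <- matrix(clim$clim_mean, 365)
  pc <- matrix(clim$pc90, 365)
  cells <- cube_cells(sst)
  res <- vector("list", ncol(mat))
  for (k in seq_len(ncol(mat))) {
    ev <- detect_events_series(mat[, k], cm[, k], pc[, k], sst$time,
                               min_duration, max_gap)
    if (nrow(ev) > 0)
      res[[k]] <- cbind(cells[rep(k, nrow(ev)), ], ev, row.names = NULL)
  }
  out <- data.table::rbindlist(res)
  as.data.frame(out)
}

#' Per-cell record metrics across all events
#'
#' Rolls the event table up to one record per cell: the longest event,
#' the largest maximum intensity, the largest cumulative intensity and
#' the highest severity, each with its date (ties broken to the earliest
#' date). Cells with no events get an all-NA record.
#'
#' @param events event table from [detect_events_grid()].
#' @param cells cell table from [cube_cells()] (defines the full set of
#'   cells, including event-free ones).
#' @return data.frame with one row per cell and columns
#'   `longest_duration`, `t_longest_start`, `t_longest_end`,
#'   `max_int`, `t_max_int`, `max_cum_int`, `t_cum_start`, `t_cum_end`,
#'   `dur_of_max_cum`, `max_sev`, `t_max_sev`, `max_category`.
#' @export
event_metrics_rollup <- function(events, cells) {
  pick <- function(df, metric, tiecol) {
    df[order(-df[[metric]], df[[tiecol]]), ][1, ]
  }
  out <- cells
  cols <- c("longest_duration", "t_longest_start", "t_longest_end",
            "max_int", "t_max_int", "max_cum_int", "t_cum_start",
            "t_cum_end", "dur_of_max_cum", "max_sev", "t_max_sev",
            "max_category")
  for (cc in cols) out[[cc]] <- NA_real_
  if (nrow(events) == 0) return(out)
  sp <- split(events, events$cell)
  for (df in sp) {
    k <- df$cell[1]
    e1 <- pick(df, "duration", "start")
    e2 <- pick(df, "max_int", "t_max_int")
    e3 <- pick(df, "cum_int", "start")
    e4 <- pick(df, "max_sev", "t_max_sev")
    out[k, cols] <- c(e1$duration, e1$start, e1$end,
                      e2$max_int, e2$t_max_int,
                      e3$cum_int, e3$start, e3$end, e3$duration,
                      e4$max_sev, e4$t_max_sev, e4$category)
  }
  out$max_category <- as.integer(out$max_category)
  out
}
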