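#' Per-cell record maps
#'
#' The per-cell records across the full record: maximum experienced
#' category/severity, maximum intensity, longest duration and largest
#' cumulative intensity, each with its date (ties to the earliest). Adds
#' calendar columns to the raw rollup: the year/month of the record
#' intensity and severity days, and the central year of the longest and
#' of the largest-cumulative-intensity events.
#'
#' @param events event table from [detect_events_grid()].
#' @param cells cell table from [cube_cells()].
#' @param cal calendar from the SST cube.
#' @return data.frame, one row per cell (class `record_maps`).
#' @export
record_maps <- function(events, cells, cal) {
  rec <- event_metrics_rollup(events, cells)
  at <- function(tt, col) ifelse(is.na(tt), NA, cal[[col]][tt])
  rec$year_max_int <- at(rec$t_max_int, "year")
  rec$month_max_int <- at(rec$t_max_int, "month")
  rec$year_max_sev <- at(rec$t_max_sev, "year")
  rec$month_max_sev <- at(rec$t_max_sev, "month")
  t_c_long <- floor((rec$t_longest_start + rec$t_longest_end) / 2)
  rec$t_longest_central <- t_c_long
  rec$central_year_longest <- at(t_c_long, "year")
  t_c_cum <- floor((rec$t_cum_start + rec$t_cum_end) / 2)
  rec$t_cum_central <- t_c_cum
  rec$central_year_cum <- at(t_c_cum, "year")
  class(rec) <- c("record_maps", "data.frame")
  rec
}

.season_of_month <- c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)
.season_names <- c("DJF", "MAM", "JJA", "SON")

#' Seasonality of record events
#'
#' Area fractions of the ocean attaining its record (by the chosen
#' metric) in each calendar month and season, split by hemisphere
#' (cells within `hemi_bound` degrees of the equator are excluded from
#' the hemispheric split, as neither hemisphere's seasons apply).
#' The local-summer fraction is DJF for the Southern Hemisphere and JJA
#' for the Northern. Cells whose record date falls in an excluded set of
#' days (e.g. El Nino months) can be dropped, with the remaining area
#' renormalized.
#'
#' @param records a [record_maps()] table.
#' @param cal calendar data.frame.
#' @param metric which record date to use: `"max_int"` (day of record
#'   intensity), `"max_sev"`, or `"duration"` (central day of the longest
#'   event).
#' @param hemi_bound equatorial exclusion half-width (degrees).
#' @param exclude_t optional integer day indices; cells whose record date
#'   is among them are excluded.
#' @return list with `by_month` (data.frame `hemi`, `month`, `frac`;
#'   fractions sum to 1 within each hemisphere), `by_season`, and
#'   `local_summer` (named vector, NH/SH summer fractions).
#' @export
record_seasonality <- function(records, cal, metric = "max_int",
                               hemi_bound = 5, exclude_t = NULL) {
  tcol <- switch(metric, max_int = "t_max_int", max_sev = "t_max_sev",
                 duration = "t_longest_central",
                 stop("unknown metric"))
  tt <- records[[tcol]]
  keep <- !is.na(tt)
  if (!is.null(exclude_t)) keep <- keep & !(tt %in% exclude_t)
  ulat <- sort(unique(records$lat))
  ulon <- sort(unique(records$lon))
  area <- cell_areas(records$lat, diff(ulat)[1],
                     if (length(ulon) > 1) diff(ulon)[1] else 360)
  hemi <- ifelse(records$lat > hemi_bound, "NH",
                 ifelse(records$lat < -hemi_bound, "SH", NA))
  month <- cal$month[tt]
  by_month <- do.call(rbind, lapply(c("NH", "SH"), function(h) {
    sel <- keep & !is.na(hemi) & hemi == h
    w <- area[sel]
    m <- month[sel]
    frac <- vapply(1:12, function(mm) sum(w[m == mm]) / sum(w), 0)
    data.frame(hemi = h, month = 1:12, frac = frac)
  }))
  by_season <- do.call(rbind, lapply(c("NH", "SH"), function(h) {
    bm <- by_month[by_month$hemi == h, ]
    data.frame(hemi = h, season = .season_names,
               frac = vapply(1:4, function(s)
                 sum(bm$frac[.season_of_month[bm$month] == s]), 0))
  }))
  ls <- c(NH = by_season$frac[by_season$hemi == "NH" &
                                by_season$season == "JJA"],
          SH = by_season$frac[by_season$hemi == "SH" &
                                by_season$season == "DJF"])
  list(by_month = by_month, by_season = by_season,
       local_summer = c(NH = unname(ls["NH"]), SH = unname(ls["SH"])))
}

#' Identify the most extreme heatwave regions
#'
#' Candidate cells are those whose most severe recorded day fell during
#' that cell's largest-cumulative-intensity event — the cells where the
#' severity and cumulative-intensity records coincide in time. Regions
#' are then either user-supplied polygons (bounding boxes) intersected
#' with the candidate mask, or, absent polygons, a deterministic
#' automatic delineation: connected components (8-connectivity,
#' longitude wrap) of candidate cells whose record-severity dates agree
#' within `date_window` days.
#'
#' @param records a [record_maps()] table.
#' @param polygons optional list of `c(lat_min, lat_max, lon_min,
#'   lon_max)` boxes.
#' @param date_window record-date agreement window for the automatic rule
#'   (days).
#' @param min_cells minimum region size (cells) for automatic regions.
#' @param connectivity,wrap_longitude see [label_contiguous()].
#' @return list of regions, each a list with `id`, `cells` (cell
#'   indices), `lat_center`, and `candidate` (the full candidate cell
#'   set); empty (with a warning) if no candidate cells exist.
#' @export
identify_extreme_regions <- function(records, polygons = NULL,
                                     date_window = 90, min_cells = 4,
                                     connectivity = 8,
                                     wrap_longitude = TRUE) {
  cand <- !is.na(records$t_max_sev) & !is.na(records$t_cum_start) &
    records$t_max_sev >= records$t_cum_start &
    records$t_max_sev <= records$t_cum_end
  if (!any(cand)) {
    warning("no candidate cells: severity and cumulative-intensity ",
            "records never coincide")
    return(list())
  }
  lat <- sort(unique(records$lat))
  lon <- sort(unique(records$lon))
  nlat <- length(lat); nlon <- length(lon)
  make_region <- function(id, cells) {
    list(id = id, cells = cells,
         lat_center = stats::weighted.mean(
           records$lat[cells],
           cell_areas(records$lat[cells], diff(lat)[1], diff(lon)[1])),
         candidate = which(cand))
  }
  if (!is.null(polygons)) {
    regions <- lapply(seq_along(polygons), function(i) {
      b <- polygons[[i]]
      cells <- which(cand & records$lat >= b[1] & records$lat <= b[2] &
                       records$lon >= b[3] & records$lon <= b[4])
      if (length(cells) == 0) return(NULL)
      make_region(i, cells)
    })
    return(Filter(Negate(is.null), regions))
  }
  # automatic: grid-adjacent candidate cells with record dates within the
  # window are linked; regions are the components
  mask <- matrix(FALSE, nlat, nlon)
  mask[records$cell[cand]] <- TRUE
  tmax <- matrix(NA_real_, nlat, nlon)
  tmax[records$cell] <- records$t_max_sev
  on <- which(mask)
  id <- matrix(0L, nlat, nlon)
  id[on] <- seq_along(on)
  edges <- NULL
  for (off in .conn_offsets(connectivity)) {
    i <- ((on - 1L) %% nlat) + 1L
    j <- ((on - 1L) %/% nlat) + 1L
    i2 <- i + off[1]
    j2 <- j + off[2]
    if (wrap_longitude) j2 <- ((j2 - 1L) %% nlon) + 1L
    ok <- i2 >= 1L & i2 <= nlat & j2 >= 1L & j2 <= nlon
    tgt <- (j2[ok] - 1L) * nlat + i2[ok]
    src <- on[ok]
    hit <- mask[tgt] & abs(tmax[src] - tmax[tgt]) <= date_window
    if (any(hit)) edges <- rbind(edges, cbind(id[src[hit]], id[tgt[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  first <- tapply(on, memb, min)
  ord <- order(first)
  regions <- list()
  rid <- 0L
  for (comp in ord) {
    cells <- on[memb == comp]
    if (length(cells) < min_cells) next
    rid <- rid + 1L
    regions[[rid]] <- make_region(rid, cells)
  }
  regions
}

#' Characterize an extreme region
#'
#' Computes the region's four diagnostic timeseries — (i) the fraction of
#' region area in at least the configured category, (ii) the area of the
#' largest contiguous heatwave component intersecting the region (at
#' S > 1 and S > 2), (iii) that component's area-integrated SSTA, and
#' (iv) the number of member cells at their record-severity day — then
#' dates the event core as the longest span where (i) exceeds `f_min`
#' and (ii) (at S > 1) exceeds `r_min` of its own maximum, and evaluates
#' the extent/intensity/duration metric set over the record.
#'
#' @param region one region from [identify_extreme_regions()].
#' @param sev a `severity_field` (with event mask) from [severity()].
#' @param records a [record_maps()] table.
#' @param f_min region-fraction threshold for the core period.
#' @param r_min fraction of the contiguous-area maximum for the core
#'   period.
#' @param connectivity,wrap_longitude see [label_contiguous()].
#' @return list of class `extreme_region`: the region plus `timeseries`
#'   (per-day data.frame), `core` (`c(start, end)` day indices or NA),
#'   `peak_t` (core day of maximal region-mean severity), and `metrics`
#'   (max areal intensity and max contiguous area at S > 2 / S > 1 with
#'   their days; median and IQR of member-cell durations of the
#'   largest-cumulative-intensity events). Degenerate regions (no
#'   heatwave days) give NA metrics.
#' @export
characterize_region <- function(region, sev, records, f_min = 0.3,
                                r_min = 0.5, connectivity = 8,
                                wrap_longitude = TRUE) {
  stopifnot(inherits(sev, "severity_field"))
  nlat <- length(sev$lat)
  nlon <- length(sev$lon)
  nt <- dim(sev$S)[1]
  area_vec <- .cell_area_vec(sev$lat, sev$lon)
  rcells <- region$cells
  ra <- area_vec[rcells]
  in_region <- rep(FALSE, nlat * nlon)
  in_region[rcells] <- TRUE
  rec_t <- records$t_max_sev[rcells]

  ts <- data.frame(t = seq_len(nt), frac_moderate = 0,
                   contig_area_s1 = 0, contig_area_s2 = 0,
                   contig_int_s1 = 0, contig_int_s2 = 0,
                   n_record_cells = 0L, mean_sev = 0)
  for (tt in seq_len(nt)) {
    Smat <- matrix(sev$S[tt, , ], nlat, nlon)
    inev <- if (is.null(sev$in_event)) NULL else
      matrix(sev$in_event[tt, , ], nlat, nlon)
    sstam <- matrix(sev$ssta[tt, , ], nlat, nlon)
    m1 <- Smat > 1
    m1[is.na(m1)] <- FALSE
    if (!is.null(inev)) m1 <- m1 & inev
    ts$frac_moderate[tt] <- sum(ra[m1[rcells]]) / sum(ra)
    sv <- Smat[rcells]
    sv[is.na(sv) | (!is.null(inev) & !m1[rcells] & sv <= 1)] <- NA
    ts$mean_sev[tt] <- {
      x <- Smat[rcells]; x[is.na(x)] <- 0
      if (!is.null(inev)) x[!inev[rcells]] <- 0
      sum(x * ra) / sum(ra)
    }
    ts$n_record_cells[tt] <- sum(rec_t == tt, na.rm = TRUE)
    if (!any(m1)) next
    for (thr in c(1, 2)) {
      m <- if (thr == 1) m1 else {
        m2 <- Smat > 2
        m2[is.na(m2)] <- FALSE
        if (!is.null(inev)) m2 <- m2 & inev
        m2
      }
      if (!any(m & matrix(in_region, nlat, nlon))) next
      lab <- label_contiguous(m, connectivity, wrap_longitude)
      touching <- unique(lab[in_region & lab > 0])
      tab <- component_table(lab, area_vec, sstam)
      tab <- tab[tab$label %in% touching, ]
      if (nrow(tab) == 0) next
      k <- which.max(tab$area_Mkm2)
      if (thr == 1) {
        ts$contig_area_s1[tt] <- tab$area_Mkm2[k]
        ts$contig_int_s1[tt] <- tab$int_ssta[k]
      } else {
        ts$contig_area_s2[tt] <- tab$area_Mkm2[k]
        ts$contig_int_s2[tt] <- tab$int_ssta[k]
      }
    }
  }

  # core period: longest run where the region fraction and the contiguous
  # area (relative to its own record) are both elevated
  amax <- max(ts$contig_area_s1)
  ok <- ts$frac_moderate > f_min & amax > 0 &
    ts$contig_area_s1 > r_min * amax
  core <- c(NA_integer_, NA_integer_)
  peak_t <- NA_integer_
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    core <- c(ends[best] - r$lengths[best] + 1L, ends[best])
    span <- core[1]:core[2]
    peak_t <- span[which.max(ts$mean_sev[span])]
  }

  argmaxd <- function(v) if (max(v) <= 0) NA_integer_ else which.max(v)
  dur <- records$dur_of_max_cum[rcells]
  qs <- stats::quantile(dur, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  metrics <- data.frame(
    max_int_s2 = max(ts$contig_int_s2), t_max_int_s2 = argmaxd(ts$contig_int_s2),
    max_int_s1 = max(ts$contig_int_s1), t_max_int_s1 = argmaxd(ts$contig_int_s1),
    max_area_s2 = max(ts$contig_area_s2), t_max_area_s2 = argmaxd(ts$contig_area_s2),
    max_area_s1 = max(ts$contig_area_s1), t_max_area_s1 = argmaxd(ts$contig_area_s1),
    dur_q25 = qs[1], dur_median = qs[2], dur_q75 = qs[3])
  if (all(ts$frac_moderate == 0)) metrics[1, ] <- NA

  out <- c(region, list(timeseries = ts, core = core, peak_t = peak_t,
                        metrics = metrics,
                        params = list(f_min = f_min, r_min = r_min)))
  class(out) <- "extreme_region"
  out
}
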