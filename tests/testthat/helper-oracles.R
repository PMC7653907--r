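# Independent oracles, deliberately implemented with different algorithms
# than the package (day-by-day state machines, breadth-first flood fill,
# explicit summation) so that agreement is evidence, not tautology.

# Brute-force event scan: walks the series day by day, closing an event
# only when the below-threshold gap exceeds max_gap; qualification and
# merging follow the written definition directly.
oracle_detect <- function(sst, clim_mean, pc90, doy, min_duration = 5,
                          max_gap = 1) {
  nt <- length(sst)
  thr <- pc90[doy]
  cm <- clim_mean[doy]
  above <- !is.na(sst) & !is.na(thr) & sst > thr
  # collect maximal above-threshold runs by explicit scan
  runs <- list()
  i <- 1
  while (i <= nt) {
    if (above[i]) {
      j <- i
      while (j < nt && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  qual <- Filter(function(r) r[2] - r[1] + 1 >= min_duration, runs)
  if (length(qual) == 0) return(NULL)
  # merge pass
  merged <- list(qual[[1]])
  for (r in qual[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= max_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else merged[[length(merged) + 1]] <- r
  }
  den <- thr - cm
  den[den <= 1e-8] <- NA
  do.call(rbind, lapply(merged, function(sp) {
    tt <- sp[1]:sp[2]
    a <- sst[tt] - cm[tt]
    s <- a / den[tt]
    data.frame(start = sp[1], end = sp[2], duration = sp[2] - sp[1] + 1,
               max_int = max(a, na.rm = TRUE),
               t_max_int = tt[which.max(a)],
               cum_int = sum(a, na.rm = TRUE),
               max_sev = suppressWarnings(max(s, na.rm = TRUE)))
  }))
}

# Breadth-first flood fill labeling (queue-based), with optional
# longitude wrap; returns the set of components as sorted cell-index
# vectors so comparisons are label-permutation-free.
oracle_flood_fill <- function(mask, connectivity = 8,
                              wrap_longitude = TRUE) {
  nlat <- nrow(mask); nlon <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand <- expand.grid(di = -1:1, dj = -1:1)
    lapply(seq_len(9), function(k) c(expand$di[k], expand$dj[k]))[-5]
  }
  seen <- matrix(FALSE, nlat, nlon)
  comps <- list()
  for (start in which(mask)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer()
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      ci <- (cur - 1) %% nlat + 1
      cj <- (cur - 1) %/% nlat + 1
      for (o in offs) {
        ni <- ci + o[1]; nj <- cj + o[2]
        if (wrap_longitude) nj <- (nj - 1) %% nlon + 1
        if (ni < 1 || ni > nlat || nj < 1 || nj > nlon) next
        nxt <- (nj - 1) * nlat + ni
        if (mask[nxt] && !seen[nxt]) {
          seen[nxt] <- TRUE
          queue <- c(queue, nxt)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(as.integer(members))
  }
  comps[order(vapply(comps, min, 0))]
}

# canonical component sets from a label matrix, for comparison
label_components <- function(lab) {
  on <- which(lab > 0)
  comps <- split(on, lab[on])
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, min, 0L))])
}

# exact binomial upper tail by explicit summation
oracle_binom_tail <- function(k, n, p0 = 0.5) {
  if (k > n) return(0)
  sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
}

# flat climatology helper: 365-day constant mean and threshold
flat_clim <- function(mean = 0, pc90 = 1) {
  list(clim_mean = rep(mean, 365), pc90 = rep(pc90, 365))
}

# single-cell cube from a daily series
series_cube <- function(x, start_year = 1983) {
  n_years <- length(x) / 365
  cal <- noleap_calendar(start_year, n_years)
  sst_cube(array(x, c(length(x), 1, 1)), cal, lat = 40, lon = 180)
}

# small grid config used across tests (overridable defaults)
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(lat_min = -60, lat_max = 60, dlat = 10,
         lon_min = 0, lon_max = 360, dlon = 30, n_years = 6),
    list(...))
  do.call(synth_config, args)
}
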