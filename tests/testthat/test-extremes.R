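# A small low-noise pipeline with one implanted basin-scale event;
# reused across the record/region tests below.
implanted_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(lat_min = 10, lat_max = 60, dlat = 10,
                        lon_min = 120, lon_max = 300, dlon = 30,
                        n_years = 6, noise_sd = 0.12, ar1 = 0.3,
                        enso_amp = 0, amp_eq = 1, amp_mid = 3,
                        seed = 77)
    syn <- generate_fields(cfg, include_drivers = FALSE,
                           include_chl = FALSE)
    # implant outside the baseline years so the threshold stays clean
    spec <- implant_spec(20, 50, 150, 270, start = 365 * 4 + 100,
                         duration = 60, amplitude = 3)
    imp <- implant_events(syn$sst, list(spec))
    clim <- build_climatology(imp$field, baseline = c(1983, 1986))
    ev <- detect_events_grid(imp$field, clim)
    sev <- severity(imp$field, clim, ev)
    rec <- record_maps(ev, cube_cells(imp$field), imp$field$time)
    cache <<- list(cfg = cfg, spec = spec, truth = imp$truth,
                   sst = imp$field, clim = clim, ev = ev, sev = sev,
                   rec = rec)
    cache
  }
})

test_that("record maps point at a single dominant implanted event", {
  p <- implanted_pipeline()
  cells <- cube_cells(p$sst)
  foot <- cells$lat >= 20 & cells$lat <= 50 &
    cells$lon >= 150 & cells$lon <= 270
  r <- p$rec
  expect_true(all(r$longest_duration[foot] >= 55))
  expect_true(all(r$t_longest_start[foot] >= p$truth$start - 3))
  expect_true(all(r$t_longest_end[foot] <= p$truth$end + 3))
  # outside the footprint the longest events are background-noise scale
  expect_true(all(is.na(r$longest_duration[!foot]) |
                    r$longest_duration[!foot] < 40))
  # records carry their calendar attribution
  expect_true(all(r$central_year_longest[foot] ==
                    p$sst$time$year[p$truth$start + 30]))
})

test_that("equal-duration events resolve to the earlier one", {
  cells <- data.frame(cell = 1L, ilat = 1L, ilon = 1L, lat = 0, lon = 0)
  ev <- data.frame(cell = 1L, ilat = 1L, ilon = 1L, lat = 0, lon = 0,
                   start = c(50L, 400L), end = c(69L, 419L),
                   duration = c(20L, 20L), max_int = c(1, 2),
                   t_max_int = c(55L, 405L), cum_int = c(10, 20),
                   max_sev = c(1.5, 2), t_max_sev = c(55L, 405L),
                   category = c(1L, 1L))
  r <- record_maps(ev, cells, noleap_calendar(1983, 2))
  expect_equal(r$t_longest_start, 50)
})

test_that("seasonality fractions are exact for constructed record dates", {
  lat <- seq(-55, 55, by = 10)
  lon <- seq(15, 345, by = 30)
  cells <- data.frame(cell = seq_len(length(lat) * length(lon)),
                      lat = rep(lat, length(lon)),
                      lon = rep(lon, each = length(lat)))
  cal <- noleap_calendar(1983, 1)
  rec <- cells
  rec$t_max_int <- 15L  # everyone's record on Jan 15
  rec$t_max_sev <- 15L
  rec$t_longest_central <- 15L
  s <- record_seasonality(rec, cal)
  expect_equal(s$by_month$frac[s$by_month$hemi == "NH" &
                                 s$by_month$month == 1], 1)
  expect_equal(s$local_summer[["SH"]], 1)  # January is austral summer
  expect_equal(s$local_summer[["NH"]], 0)
  # fractions sum to one within each hemisphere
  expect_equal(sum(s$by_month$frac[s$by_month$hemi == "SH"]), 1)
})

test_that("uniform record dates give near-equal season fractions", {
  set.seed(83)
  lat <- seq(-55, 55, by = 5)
  lon <- seq(5, 355, by = 10)
  cells <- data.frame(cell = seq_len(length(lat) * length(lon)),
                      lat = rep(lat, length(lon)),
                      lon = rep(lon, each = length(lat)))
  cal <- noleap_calendar(1983, 1)
  rec <- cells
  rec$t_max_int <- sample.int(365, nrow(cells), replace = TRUE)
  s <- record_seasonality(rec, cal)
  expect_true(all(abs(s$by_season$frac - 0.25) < 0.06))
})

test_that("phase-excluded cells are dropped and fractions renormalized", {
  lat <- seq(25, 55, by = 10)
  lon <- seq(15, 345, by = 30)
  cells <- data.frame(cell = seq_len(length(lat) * length(lon)),
                      lat = rep(lat, length(lon)),
                      lon = rep(lon, each = length(lat)))
  cal <- noleap_calendar(1983, 1)
  rec <- cells
  rec$t_max_int <- rep(c(15L, 196L), length.out = nrow(cells))
  s_all <- record_seasonality(rec, cal)
  s_excl <- record_seasonality(rec, cal, exclude_t = 15L)
  expect_lt(s_all$by_month$frac[s_all$by_month$hemi == "NH" &
                                  s_all$by_month$month == 7], 1)
  expect_equal(s_excl$by_month$frac[s_excl$by_month$hemi == "NH" &
                                      s_excl$by_month$month == 7], 1)
})

test_that("candidate cells require records to coincide in time", {
  cells <- data.frame(cell = 1:2, ilat = 1:2, ilon = 1L,
                      lat = c(20, 30), lon = c(15, 15))
  rec <- cells
  rec$t_max_sev <- c(100, 500)
  rec$t_cum_start <- c(90, 90)
  rec$t_cum_end <- c(120, 120)
  rec$lat <- c(20, 30); rec$lon <- 15
  expect_warning(r <- identify_extreme_regions(rec[2, , drop = FALSE]),
                 "no candidate")
  expect_equal(length(r), 0)
})

test_that("supplied polygons intersect the candidate mask exactly", {
  p <- implanted_pipeline()
  regs <- identify_extreme_regions(
    p$rec, polygons = list(c(20, 50, 150, 270), c(-90, 5, 0, 360)))
  expect_equal(length(regs), 1)  # second box has no candidates
  cells <- cube_cells(p$sst)
  foot <- which(cells$lat >= 20 & cells$lat <= 50 &
                  cells$lon >= 150 & cells$lon <= 270)
  expect_true(all(regs[[1]]$cells %in% foot))
  expect_gt(length(regs[[1]]$cells), 0.8 * length(foot))
})

test_that("automatic delineation recovers the implanted footprint", {
  p <- implanted_pipeline()
  regs <- identify_extreme_regions(p$rec, min_cells = 4)
  expect_gte(length(regs), 1)
  sizes <- vapply(regs, function(r) length(r$cells), 0L)
  main <- regs[[which.max(sizes)]]
  cells <- cube_cells(p$sst)
  foot <- which(cells$lat >= 20 & cells$lat <= 50 &
                  cells$lon >= 150 & cells$lon <= 270)
  expect_gt(length(intersect(main$cells, foot)),
            0.8 * length(main$cells))
  # deterministic: identical input, identical regions
  regs2 <- identify_extreme_regions(p$rec, min_cells = 4)
  expect_identical(lapply(regs, `[[`, "cells"),
                   lapply(regs2, `[[`, "cells"))
})

test_that("region characterization recovers the implanted core period", {
  p <- implanted_pipeline()
  regs <- identify_extreme_regions(p$rec, min_cells = 4)
  main <- regs[[which.max(vapply(regs, function(r) length(r$cells), 0L))]]
  cr <- characterize_region(main, p$sev, p$rec)
  expect_false(any(is.na(cr$core)))
  expect_lt(abs(cr$core[1] - p$truth$start), 10)
  expect_lt(abs(cr$core[2] - p$truth$end), 10)
  expect_true(cr$peak_t >= cr$core[1] && cr$peak_t <= cr$core[2])
  expect_equal(cr$metrics$dur_median, 60, tolerance = 0.1)
  expect_true(cr$metrics$dur_q25 <= cr$metrics$dur_median &&
                cr$metrics$dur_median <= cr$metrics$dur_q75)
  # timeseries invariants
  ts <- cr$timeseries
  expect_true(all(ts$frac_moderate >= 0 & ts$frac_moderate <= 1))
  expect_true(all(ts$contig_area_s2 <= ts$contig_area_s1 + 1e-12))
  # core period lies inside the span where member cells are in events
  any_event <- which(ts$frac_moderate > 0)
  expect_gte(cr$core[1], min(any_event))
  expect_lte(cr$core[2], max(any_event))
})

test_that("single-day region arithmetic is exact", {
  lat <- seq(5, 25, by = 10)
  lon <- seq(15, 105, by = 30)
  nlat <- length(lat); nlon <- length(lon)
  S <- array(0, c(2, nlat, nlon))
  ssta <- array(0, c(2, nlat, nlon))
  S[1, , 1:2] <- 3; ssta[1, , 1:2] <- 2   # 6 cells at S=3, SSTA 2
  sev <- structure(list(S = S, ssta = ssta,
                        category = array(0L, dim(S)),
                        time = noleap_calendar(1983, 1)[1:2, ],
                        lat = lat, lon = lon),
                   class = "severity_field")
  region_cells <- as.integer(c(1:3, nlat + 1:3))
  rec <- data.frame(cell = seq_len(nlat * nlon))
  rec$dur_of_max_cum <- NA_real_
  rec$t_max_sev <- NA_real_
  region <- list(id = 1L, cells = region_cells, lat_center = 15)
  cr <- characterize_region(region, sev, rec, f_min = 0.3, r_min = 0.5)
  av <- rep(cell_areas(lat, 10, 30), nlon)
  a_tot <- sum(av[region_cells]) / 1e6
  expect_equal(cr$timeseries$frac_moderate[1], 1)
  expect_equal(cr$timeseries$frac_moderate[2], 0)
  expect_equal(cr$timeseries$contig_area_s2[1], a_tot)
  expect_equal(cr$timeseries$contig_int_s2[1], 2 * a_tot)
  # half-cover day: put the other half out of heatwave state
  S2 <- S; S2[1, , 2] <- 0
  sev2 <- sev; sev2$S <- S2
  cr2 <- characterize_region(region, sev2, rec)
  a_half <- sum(av[1:3]) / 1e6
  expect_equal(cr2$timeseries$frac_moderate[1], a_half / a_tot)
})
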