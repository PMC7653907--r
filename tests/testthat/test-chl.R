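# 8-day composite container on a tiny grid, built from a daily matrix
make_chl <- function(daily_mat, n_years, lat, lon, start_year = 1983) {
  cal <- noleap_calendar(start_year, n_years)
  mhwx:::bin_8day(daily_mat, cal, length(lat), length(lon))
}

test_that("the exact binomial sign test matches the summation oracle", {
  expect_equal(sign_binomial_test(4, 4), 0.0625)
  for (n in c(1, 5, 17, 38, 52, 60)) {
    for (k in 0:n) {
      expect_equal(sign_binomial_test(k, n), oracle_binom_tail(k, n),
                   tolerance = 1e-12)
    }
  }
  # the headline case: 38 of 52 regions sharing a sign
  p38 <- sign_binomial_test(38, 52)
  expect_equal(p38, oracle_binom_tail(38, 52), tolerance = 1e-12)
  expect_lt(p38, 0.01)
  # the null-consistent case is unremarkable
  expect_equal(sign_binomial_test(26, 52), oracle_binom_tail(26, 52),
               tolerance = 1e-12)
  expect_gt(sign_binomial_test(26, 52), 0.5)
  expect_error(sign_binomial_test(1, 0), "positive")
})

test_that("a field at its climatology yields exactly zero response", {
  lat <- c(5, 15); lon <- c(100, 130)
  n_years <- 4
  nt <- 365 * n_years
  seasonal <- rep(sin(2 * pi * (1:365) / 365), n_years)
  region <- list(id = 1L, cells = 1:2, lat_center = 10,
                 peak_t = 365 * 2 + 100)
  cal <- noleap_calendar(1983, n_years)
  # seasonal cycle repeated identically every year: the window equals
  # its climatology; a lone perturbation away from the window keeps the
  # normalizing sd nonzero without touching the window anomaly
  daily0 <- matrix(seasonal, nt, 4)
  daily0[400, ] <- daily0[400, ] + 1
  chl0 <- make_chl(daily0, n_years, lat, lon)
  resp0 <- chl_mhw_response(chl0, region, cal, lat, lon)
  expect_equal(resp0$norm_anom, 0)
  expect_equal(resp0$region_id, 1L)
})

test_that("the peak maps into its composite and a 3-composite window", {
  lat <- c(5, 15); lon <- c(100, 130)
  n_years <- 3
  nt <- 365 * n_years
  daily <- matrix(0, nt, 4)
  cal <- noleap_calendar(1983, n_years)
  # peak on doy 17 of year 2 -> composite 3 of year 2 (46 + 3 = index 49)
  peak_t <- 365 + 17
  region <- list(id = 1L, cells = 1:4, lat_center = 10, peak_t = peak_t)
  # put a signal only in the adjacent composite (t+1: days 25..32 of y2)
  daily[365 + 25:32, ] <- 3
  chl <- make_chl(daily, n_years, lat, lon)
  resp <- chl_mhw_response(chl, region, cal, lat, lon)
  expect_equal(resp$peak_comp, 46 + 3)
  expect_gt(resp$norm_anom, 0)  # t+1 signal enters the window mean
  # a signal two composites away does not
  daily2 <- matrix(0, nt, 4)
  daily2[365 + 41:48, ] <- 3    # composite t+3
  chl2 <- make_chl(daily2, n_years, lat, lon)
  resp2 <- chl_mhw_response(chl2, region, cal, lat, lon)
  expect_equal(resp2$norm_anom, 0)  # outside the window it cannot enter
})

test_that("events before the chlorophyll record return a reason", {
  lat <- c(5, 15); lon <- c(100, 130)
  chl <- make_chl(matrix(0, 365 * 2, 4), 2, lat, lon, start_year = 1997)
  cal <- noleap_calendar(1982, 20)   # SST record starts much earlier
  region <- list(id = 7L, cells = 1:2, lat_center = 10, peak_t = 100)
  resp <- chl_mhw_response(chl, region, cal, lat, lon)
  expect_true(is.na(resp$norm_anom))
  expect_match(resp$reason, "outside")
})

test_that("an implanted suppression of one sigma is recovered", {
  # single-window recovery is noisy (the window's own noise is order
  # 1 sigma / sqrt(3)), so average over independent regions
  lat <- c(5, 15); lon <- c(100, 130)
  n_years <- 10
  nt <- 365 * n_years
  cal <- noleap_calendar(1983, n_years)
  set.seed(131)
  vals <- replicate(8, {
    daily <- matrix(rnorm(nt * 4, sd = 0.2), nt, 4)
    chl_pre <- make_chl(daily, n_years, lat, lon)
    sd0 <- sd(chl_region_series(chl_pre, 1:4, lat, lon)$anom)
    peak_t <- 365 * 4 + 100
    # dip aligned with the three 8-day composites covering the peak,
    # scaled up to offset its own dilution of the window climatology
    win <- 365 * 4 + 89:112
    daily[win, ] <- daily[win, ] - sd0 * n_years / (n_years - 1)
    chl <- make_chl(daily, n_years, lat, lon)
    region <- list(id = 1L, cells = 1:4, lat_center = 10,
                   peak_t = peak_t)
    resp <- chl_mhw_response(chl, region, cal, lat, lon)
    expect_equal(resp$sign, -1L)
    resp$norm_anom
  })
  expect_lt(abs(mean(vals) - (-1)), 0.35)
})

test_that("Monte Carlo p-values behave at the null center and extremes", {
  lat <- c(5, 15); lon <- c(100, 130)
  n_years <- 10
  set.seed(137)
  daily <- matrix(rnorm(365 * n_years * 4, sd = 0.2), 365 * n_years, 4)
  chl <- make_chl(daily, n_years, lat, lon)
  region <- list(id = 1L, cells = 1:4)
  mc0 <- monte_carlo_null(chl, region, observed = 0,
                          exclude_comps = integer(), n_resamples = 999,
                          seed = 5, lat = lat, lon = lon)
  expect_gt(mc0$p, 0.9)
  big <- max(abs(mc0$null)) * 2
  mc1 <- monte_carlo_null(chl, region, observed = big,
                          exclude_comps = integer(), n_resamples = 999,
                          seed = 5, lat = lat, lon = lon)
  expect_equal(mc1$p, 1 / 1000)
  # deterministic under a fixed seed
  mc2 <- monte_carlo_null(chl, region, observed = big,
                          exclude_comps = integer(), n_resamples = 999,
                          seed = 5, lat = lat, lon = lon)
  expect_identical(mc1$null, mc2$null)
  # too few candidates is an error
  expect_error(monte_carlo_null(chl, region, 0,
                                exclude_comps = 1:450,
                                n_resamples = 99, seed = 1,
                                lat = lat, lon = lon), "100")
})

test_that("Monte Carlo p-values converge with the resample count", {
  lat <- c(5, 15); lon <- c(100, 130)
  n_years <- 10
  set.seed(139)
  daily <- matrix(rnorm(365 * n_years * 4, sd = 0.2), 365 * n_years, 4)
  chl <- make_chl(daily, n_years, lat, lon)
  region <- list(id = 1L, cells = 1:4)
  ser <- chl_region_series(chl, 1:4, lat, lon)
  obs <- stats::quantile(abs(ser$anom), 0.8)
  p1 <- monte_carlo_null(chl, region, obs, integer(), 10000, 3,
                         lat, lon)$p
  p2 <- monte_carlo_null(chl, region, obs, integer(), 100000, 4,
                         lat, lon)$p
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("nitrate pairing and latitudinal sign summary are correct", {
  responses <- data.frame(region_id = 1:6,
                          norm_anom = c(-1.2, -0.4, -0.8, 0.6, 1.1, -0.2),
                          lat_center = c(5, -12, 18, 45, -50, 30),
                          sign = c(-1L, -1L, -1L, 1L, 1L, -1L),
                          peak_comp = 10L, reason = NA_character_)
  nitrate <- matrix(seq(0.5, 12, length.out = 12), 3, 4)
  regions <- lapply(1:6, function(i) list(id = i, cells = i + 1))
  out <- nitrate_relation(responses, nitrate, regions,
                          lat = 1:3, lon = 1:4)
  expect_equal(out$summary$frac_negative_tropical, 1)   # |lat| <= 20
  expect_equal(out$summary$frac_negative_extratropical, 1 / 3)
  expect_equal(nrow(out$table), 6)
  # anomalies exactly proportional to nitrate: rank correlation 1
  r2 <- responses
  r2$norm_anom <- 0.1 * vapply(regions, function(r)
    nitrate[r$cells], 0)
  out2 <- nitrate_relation(r2, nitrate, regions, 1:3, 1:4)
  expect_equal(out2$summary$rank_cor, 1)
  # empty input
  out0 <- nitrate_relation(responses[0, ], nitrate, regions, 1:3, 1:4)
  expect_equal(out0$summary$n, 0)
})

test_that("tropical suppression from the coupled generator is recovered", {
  cfg <- synth_config(lat_min = 0, lat_max = 20, dlat = 10,
                      lon_min = 120, lon_max = 240, dlon = 30,
                      n_years = 6, noise_sd = 0.25, enso_amp = 0,
                      chl_coupling = 0.15, seed = 149)
  syn <- generate_fields(cfg, include_drivers = FALSE)
  specs <- list(implant_spec(0, 20, 150, 210, start = 365 * 3 + 30,
                             duration = 30, amplitude = 3))
  imp <- implant_events(syn, specs)
  cells <- cube_cells(imp$field$sst)
  foot <- which(cells$lat >= 0 & cells$lat <= 20 &
                  cells$lon >= 150 & cells$lon <= 210)
  region <- list(id = 1L, cells = foot, lat_center = 10,
                 peak_t = specs[[1]]$start + 15)
  resp <- chl_mhw_response(imp$field$chl, region, imp$field$sst$time,
                           cfg$lat, cfg$lon)
  expect_equal(resp$sign, -1L)
  expect_lt(resp$norm_anom, -0.5)
})
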