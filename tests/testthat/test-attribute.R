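# Synthetic curve with a known inverted-J shape, negligible uncertainty.
demo_curve <- function(vcov_scale = 1e-8) {
  temps <- seq(-10, 35, length.out = 3000)
  f <- function(x) ifelse(x < 20, 0.0015 * (x - 20)^2, 0.006 * (x - 20)^2)
  find_mmt(curve_from_function(f, temps, vcov_scale = vcov_scale), temps)
}

# Single-GCM scenario table at given daily temperatures, spanning a decade.
decade_series <- function(temps_fn, years = 2090:2099, gcm = "gcm01",
                          scenario = "TEST") {
  dates <- seq(lubridate::make_date(years[1], 1, 1),
               lubridate::make_date(years[length(years)], 12, 31), by = "day")
  tibble::tibble(date = dates, gcm = gcm, scenario = scenario,
                 temp_c = temps_fn(dates))
}

test_that("the daily attributable formula matches its closed form", {
  curve <- demo_curve()
  at <- daily_attributable(curve, curve$mmt, 10)
  expect_equal(at$an, 0)
  # delta = log 2 above the curve: pick the temperature where log RR = log 2
  grid <- seq(curve$mmt, 35, by = 0.001)
  lr <- cumulative_log_rr(curve, grid)
  t2 <- grid[which.min(abs(lr - log(2)))]
  at2 <- daily_attributable(curve, t2, 10)
  expect_equal(at2$an, 5, tolerance = 1e-3)
  expect_equal(at2$component, "heat")
  # sums over a series match a per-day loop
  set.seed(2)
  temps <- runif(400, -5, 33)
  tab <- daily_attributable(curve, temps, 7)
  brute <- sapply(temps, function(x) 7 * (1 - exp(-cumulative_log_rr(curve, x))))
  expect_equal(sum(tab$an), sum(brute), tolerance = 1e-9)
})

test_that("heat and cold attributable numbers partition the total", {
  curve <- demo_curve()
  set.seed(5)
  ser <- decade_series(function(d) 15 + 12 * sin(seq_along(d) / 50) +
                         rnorm(length(d), 0, 3))
  burden <- decade_burden(curve, ser, 9, "2090s", by_gcm = TRUE)
  w <- tidyr::pivot_wider(burden, names_from = "component",
                          values_from = c("an", "af_pct"))
  expect_equal(w$an_heat + w$an_cold, w$an_total, tolerance = 1e-9)
  expect_true(all(c(w$an_heat, w$an_cold) >= 0))
  # AF definition: AN over total deaths of the cell, in percent
  n_days <- sum(lubridate::year(ser$date) %in% 2090:2099)
  expect_equal(w$af_pct_total, w$an_total / (9 * n_days) * 100,
               tolerance = 1e-9)
})

test_that("a flat curve attributes nothing", {
  temps <- seq(-10, 35, length.out = 200)
  flat <- find_mmt(curve_from_function(function(x) rep(0, length(x)), temps,
                                       vcov_scale = 0), temps)
  ser <- decade_series(function(d) 15 + rnorm(length(d), 0, 5))
  burden <- decade_burden(flat, ser, 5, "2090s")
  expect_equal(burden$an, rep(0, 3), tolerance = 1e-9)
})

test_that("a constant series reproduces the closed-form daily value", {
  curve <- demo_curve()
  t_hot <- curve$mmt + 6
  ser <- decade_series(function(d) rep(t_hot, length(d)))
  burden <- decade_burden(curve, ser, 4, "2090s")
  daily <- daily_attributable(curve, t_hot, 4)$an
  n_days <- dplyr::n_distinct(ser$date)
  got <- burden$an[burden$component == "heat"]
  expect_equal(got, daily * n_days, tolerance = 1e-9)
  expect_equal(burden$an[burden$component == "cold"], 0)
})

test_that("attributable fractions are invariant to rescaling baseline deaths", {
  curve <- demo_curve()
  set.seed(6)
  ser <- decade_series(function(d) 16 + rnorm(length(d), 0, 6))
  b1 <- decade_burden(curve, ser, 5, "2090s")
  b2 <- decade_burden(curve, ser, 50, "2090s")
  expect_equal(b2$af_pct, b1$af_pct, tolerance = 1e-9)
  expect_equal(b2$an, 10 * b1$an, tolerance = 1e-9)
})

test_that("uniform warming raises heat and lowers cold attribution", {
  curve <- demo_curve()
  set.seed(7)
  ser <- decade_series(function(d) 14 + 10 * cos(seq_along(d) / 58) +
                         rnorm(length(d), 0, 3))
  warm <- dplyr::mutate(ser, temp_c = temp_c + 1)
  b0 <- decade_burden(curve, ser, 5, "2090s")
  b1 <- decade_burden(curve, warm, 5, "2090s")
  expect_gte(b1$an[b1$component == "heat"], b0$an[b0$component == "heat"])
  expect_lte(b1$an[b1$component == "cold"], b0$an[b0$component == "cold"])
})

test_that("eCIs collapse to the point estimate without uncertainty", {
  curve <- demo_curve(vcov_scale = 0)
  set.seed(8)
  ser <- decade_series(function(d) 15 + rnorm(length(d), 0, 6))
  cells <- mc_eci(curve, ser, 5, "2090s", draws = mc_draws(200, seed = 4))
  expect_equal(cells$eci_low, cells$an, tolerance = 1e-9)
  expect_equal(cells$eci_high, cells$an, tolerance = 1e-9)
})

test_that("eCIs are stable across Monte Carlo seeds at large n_sim", {
  temps <- seq(-10, 35, length.out = 3000)
  f <- function(x) ifelse(x < 20, 0.0015 * (x - 20)^2, 0.006 * (x - 20)^2)
  curve <- find_mmt(curve_from_function(f, temps, vcov_scale = 1e-4), temps)
  set.seed(9)
  ser <- decade_series(function(d) 15 + 10 * cos(seq_along(d) / 58) +
                         rnorm(length(d), 0, 3))
  c1 <- mc_eci(curve, ser, 5, "2090s", draws = mc_draws(10000, seed = 1))
  c2 <- mc_eci(curve, ser, 5, "2090s", draws = mc_draws(10000, seed = 2))
  rel <- abs(c1$eci_high - c2$eci_high) / abs(c1$eci_high)
  expect_true(all(rel < 0.02))
  rel_low <- abs(c1$eci_low - c2$eci_low) / pmax(abs(c1$eci_low), 1e-8)
  expect_true(all(rel_low < 0.02))
})

test_that("differences versus an identical historical climatology vanish", {
  curve <- demo_curve(vcov_scale = 1e-6)
  set.seed(10)
  base_temp <- function(d) {
    doy <- lubridate::yday(d)
    14 + 10 * cos(2 * pi * (doy - 196) / 365.25)
  }
  hist_ser <- purrr::map_dfr(c("1980s", "1990s", "2000s"), function(dec) {
    y0 <- as.integer(sub("s$", "", dec))
    decade_series(function(d) base_temp(d) + rnorm(length(d), 0, 2),
                  years = y0:(y0 + 9))
  })
  scen_ser <- decade_series(function(d) base_temp(d) + rnorm(length(d), 0, 2),
                            years = 2090:2099)
  eta_mat <- tempburden:::draw_eta(curve, mc_draws(300, seed = 3))
  scen_tab <- tempburden:::burden_draw_table(curve, scen_ser, 5, "2090s",
                                             eta_mat)
  hist_tab <- tempburden:::burden_draw_table(curve, hist_ser, 5,
                                             c("1980s", "1990s", "2000s"),
                                             eta_mat)
  diffs <- difference_vs_historical(scen_tab, hist_tab)
  expect_lt(max(abs(diffs$d_af_pct)), 0.5)
  expect_true(all(diffs$eci_low <= diffs$eci_high))
  # net equals heat + cold within each key
  w <- tidyr::pivot_wider(diffs[, c("scenario", "decade", "component", "d_an")],
                          names_from = "component", values_from = "d_an")
  expect_equal(w$net, w$heat + w$cold, tolerance = 1e-9)
})

test_that("a heat-only curve under warming changes nothing on the cold side", {
  temps <- seq(-10, 35, length.out = 2000)
  heat_only <- function(x) ifelse(x > 20, 0.01 * (x - 20)^2, 0)
  curve <- find_mmt(curve_from_function(heat_only, temps,
                                        vcov_scale = 0), temps)
  # flat below the minimum: every sub-threshold day attributes zero,
  # so the cold difference is exactly zero under any warming
  base_temp <- function(d) 14 + 10 * cos(2 * pi * lubridate::yday(d) / 365.25)
  hist_ser <- purrr::map_dfr(c("1980s", "1990s", "2000s"), function(dec) {
    y0 <- as.integer(sub("s$", "", dec))
    decade_series(function(d) base_temp(d), years = y0:(y0 + 9))
  })
  scen_ser <- decade_series(function(d) base_temp(d) + 3, years = 2090:2099)
  scen_tab <- tempburden:::burden_draw_table(curve, scen_ser, 5, "2090s")
  hist_tab <- tempburden:::burden_draw_table(curve, hist_ser, 5,
                                             c("1980s", "1990s", "2000s"))
  diffs <- difference_vs_historical(scen_tab, hist_tab)
  expect_equal(diffs$d_an[diffs$component == "cold"], 0)
  expect_gt(diffs$d_an[diffs$component == "heat"], 0)
})

test_that("mismatched cell keys are rejected", {
  curve <- demo_curve()
  ser <- decade_series(function(d) rep(25, length(d)))
  tab <- tempburden:::burden_draw_table(curve, ser, 5, "2090s")
  other <- dplyr::mutate(tab, gcm = "gcmXX")
  expect_error(difference_vs_historical(tab, other), "keys do not match")
})
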