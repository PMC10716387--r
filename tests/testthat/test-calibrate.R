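obs_series <- function() {
  cached("obs7", simulate_weather(weather_params(seed = 23)))[
    , c("date", "temp_c")]
}

test_that("identical model and observations give zero offsets", {
  obs <- obs_series()
  corr <- fit_correction(obs, obs)
  expect_equal(max(abs(corr$offset)), 0, tolerance = 1e-10)
  out <- apply_correction(obs, corr)
  expect_equal(out$temp_c, obs$temp_c, tolerance = 1e-10)
})

test_that("a constant model bias is removed exactly", {
  obs <- obs_series()
  biased <- dplyr::mutate(obs, temp_c = temp_c + 2)
  corr <- fit_correction(obs, biased)
  expect_lt(max(abs(corr$offset + 2)), 0.05)
  fixed <- apply_correction(biased, corr)
  expect_lt(max(abs(fixed$temp_c - obs$temp_c)), 0.1)
})

test_that("corrected quantiles match observed after a variance inflation", {
  obs <- obs_series()
  scaled <- dplyr::mutate(obs,
                          temp_c = 1.5 * (temp_c - mean(temp_c)) + mean(temp_c))
  corr <- fit_correction(obs, scaled)
  fixed <- apply_correction(scaled, corr)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(pctl(fixed$temp_c, p) - pctl(obs$temp_c, p))), 0.1)
})

test_that("a constant-offset correction leaves a ramp's slope unchanged", {
  obs <- obs_series()
  n <- nrow(obs)
  ramped <- dplyr::mutate(obs, temp_c = temp_c + 3 +
                            seq(0, 4, length.out = n))
  corr <- fit_correction(obs, dplyr::mutate(obs, temp_c = temp_c + 3))
  fixed <- apply_correction(ramped, corr)
  t_num <- as.numeric(obs$date)
  slope_before <- coef(lm(ramped$temp_c ~ t_num))[2]
  slope_after <- coef(lm(fixed$temp_c ~ t_num))[2]
  expect_equal(unname(slope_after), unname(slope_before), tolerance = 1e-6)
})

test_that("bias removal and trend preservation hold jointly on a synthetic ensemble", {
  obs <- simulate_weather(weather_params(seed = 23))
  # ten-member ensemble, as a typical downscaled-GCM product provides;
  # decadal means of a single member carry ~0.15 degC of internal noise
  scen <- simulate_scenario_series(
    obs, scenario_params("SSP585", 5.4, gcm_bias_offset = 1.5, n_gcms = 10,
                         seed = 71))
  fixed <- calibrate_ensemble(scen, obs)
  yr <- lubridate::year(fixed$date)
  hist_mean <- mean(fixed$temp_c[yr <= 2009])
  obs_mean <- mean(obs$temp_c)
  expect_lt(abs(hist_mean - obs_mean), 0.1)
  diff_2090s <- mean(fixed$temp_c[yr >= 2090]) - hist_mean
  expect_lt(abs(diff_2090s - 5.4), 0.15)
})

test_that("the correction preserves within-month rank order", {
  obs <- obs_series()
  scaled <- dplyr::mutate(obs,
                          temp_c = 1.4 * (temp_c - mean(temp_c)) + mean(temp_c) - 1)
  fixed <- apply_correction(scaled, fit_correction(obs, scaled))
  key <- format(fixed$date, "%Y-%m")
  for (m in unique(key)) {
    idx <- key == m
    expect_equal(order(fixed$temp_c[idx]), order(scaled$temp_c[idx]))
  }
})

test_that("refitting on corrected output yields near-zero offsets", {
  # remove the 7-year sample's incidental noise trend first, so the check
  # isolates distribution-mapping idempotence from the (documented)
  # spurious-trend reshuffling noise
  obs <- obs_series()
  t_num <- as.numeric(obs$date)
  obs$temp_c <- stats::resid(lm(obs$temp_c ~ t_num)) + mean(obs$temp_c)
  scaled <- dplyr::mutate(obs,
                          temp_c = 1.3 * (temp_c - mean(temp_c)) + mean(temp_c) + 1)
  fixed <- apply_correction(scaled, fit_correction(obs, scaled))
  corr2 <- fit_correction(obs, fixed[, c("date", "temp_c")])
  expect_lt(max(abs(corr2$offset)), 0.1)
})

test_that("months with too few overlap days are rejected", {
  obs <- obs_series()
  short <- obs[1:40, ]
  expect_error(fit_correction(short, short), "Fewer than 20")
})
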