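#' Parameters for a synthetic climate-scenario ensemble
#'
#' Describes one emissions scenario as simulated by an ensemble of general
#' circulation models (GCMs): a scenario label, the warming reached by the
#' 2090s decade relative to the 1980-2009 historical period, a constant
#' additive model bias, a multiplicative inflation of day-to-day variability
#' and the ensemble size.
#'
#' @param scenario_id Scenario label, e.g. `"SSP126"`, `"SSP245"`,
#'   `"SSP585"`.
#' @param warming_by_2090s Decadal-mean warming (degrees C) of the 2090s
#'   relative to the historical (1980-2009) mean.
#' @param gcm_bias_offset Constant additive bias of the modelled series,
#'   degrees C.
#' @param gcm_variance_scale Multiplier (> 0) on the observed residual
#'   variability.
#' @param n_gcms Number of ensemble members (>= 1).
#' @param seed Integer seed.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(scenario_id, warming_by_2090s,
                            gcm_bias_offset = 1.5, gcm_variance_scale = 1,
                            n_gcms = 5L, seed = 1L) {
  assert_that(is.character(scenario_id) && length(scenario_id) == 1L,
              "`scenario_id` must be a single string.")
  assert_scalar_number(warming_by_2090s, "warming_by_2090s")
  assert_scalar_number(gcm_bias_offset, "gcm_bias_offset")
  assert_scalar_number(gcm_variance_scale, "gcm_variance_scale", lower = 0,
                       strict_lower = TRUE)
  assert_that(is.numeric(n_gcms) && length(n_gcms) == 1L && n_gcms >= 1,
              "`n_gcms` must be an integer >= 1.")
  structure(list(scenario_id = scenario_id,
                 warming_by_2090s = warming_by_2090s,
                 gcm_bias_offset = gcm_bias_offset,
                 gcm_variance_scale = gcm_variance_scale,
                 n_gcms = as.integer(n_gcms), seed = as.integer(seed)),
            class = "scenario_params")
}

#' Default scenario set
#'
#' Three standard shared-socioeconomic-pathway scenarios with national-scale
#' 2090s warming of 1.9 (SSP126, strict mitigation), 2.9 (SSP245,
#' intermediate) and 5.4 degrees C (SSP585, unrestricted emissions).
#'
#' @param gcm_bias_offset,gcm_variance_scale,n_gcms,seed Shared ensemble
#'   settings passed to [scenario_params()]; each ensemble derives its own
#'   sub-seed from `seed`.
#' @return A named list of [scenario_params()] objects.
#' @export
ssp_scenarios <- function(gcm_bias_offset = 1.5, gcm_variance_scale = 1,
                          n_gcms = 5L, seed = 1L) {
  warm <- c(SSP126 = 1.9, SSP245 = 2.9, SSP585 = 5.4)
  out <- lapply(seq_along(warm), function(i) {
    scenario_params(names(warm)[i], warm[[i]],
                    gcm_bias_offset = gcm_bias_offset,
                    gcm_variance_scale = gcm_variance_scale,
                    n_gcms = n_gcms, seed = as.integer(seed) + 101L * i)
  })
  setNames(out, names(warm))
}

#' Simulate a GCM ensemble of daily scenario temperature series
#'
#' Each ensemble member over `horizon` (default 1980-2099) is the observed
#' day-of-year climatology plus the constant model bias, plus a warming ramp,
#' plus AR(1) noise whose persistence matches the observed residuals and
#' whose standard deviation is the observed residual SD times
#' `gcm_variance_scale`. The ramp is zero throughout the historical segment
#' (1980-2009) *and* the observation window used for calibration --
#' projections share the observed climate until the observations end and
#' diverge afterwards -- then increases linearly so that the 2090s decadal
#' mean sits `warming_by_2090s` degrees above the historical mean.
#'
#' @param obs Observed daily weather tibble used to build the climatology
#'   (at least one full year).
#' @param params A [scenario_params()] object.
#' @param horizon Length-2 integer vector of first and last simulated year.
#' @return A tibble with columns `date, gcm, scenario, temp_c`; `n_gcms`
#'   members stacked long.
#' @export
simulate_scenario_series <- function(obs, params,
                                     horizon = c(1980L, 2099L)) {
  check_daily_series(obs, "obs")
  assert_that(inherits(params, "scenario_params"),
              "`params` must be a `scenario_params`.")
  assert_that(nrow(obs) >= 365,
              "`obs` must cover at least one full year to define a climatology.")
  assert_that(length(horizon) == 2L && horizon[1] < horizon[2],
              "`horizon` must be two increasing years.")

  obs_date <- lubridate::as_date(obs$date)
  doy <- pmin(lubridate::yday(obs_date), 365L)
  clim <- tapply(obs$temp_c, doy, mean)
  clim_vec <- as.numeric(clim[as.character(1:365)])
  resid <- obs$temp_c - clim_vec[doy]
  resid_sd <- sd(resid)
  phi <- if (length(resid) > 2) {
    max(0, min(0.98, stats::cor(resid[-1], resid[-length(resid)])))
  } else 0

  dates <- seq(lubridate::make_date(horizon[1], 1, 1),
               lubridate::make_date(horizon[2], 12, 31), by = "day")
  n <- length(dates)
  season <- clim_vec[pmin(lubridate::yday(dates), 365L)]

  # warming ramp: 0 through the end of the observation window (and never
  # before 2010), linear afterwards, calibrated so the mean over the 2090s
  # decade equals warming_by_2090s
  t_num <- as.numeric(dates)
  ramp_start <- as.numeric(max(max(obs_date) + 1,
                               lubridate::make_date(2010, 1, 1)))
  target_mid <- mean(as.numeric(seq(lubridate::make_date(2090, 1, 1),
                                    lubridate::make_date(2099, 12, 31),
                                    by = "day")))
  ramp <- params$warming_by_2090s *
    pmax(0, t_num - ramp_start) / (target_mid - ramp_start)

  noise_sd <- params$gcm_variance_scale * resid_sd
  innov_sd <- noise_sd * sqrt(1 - phi^2)
  members <- withr::with_seed(params$seed, {
    lapply(seq_len(params$n_gcms), function(g) {
      eps <- rnorm(n, sd = innov_sd)
      z <- numeric(n)
      z[1] <- rnorm(1, sd = noise_sd)
      for (t in seq_len(n)[-1]) z[t] <- phi * z[t - 1] + eps[t]
      tibble::tibble(
        date = dates,
        gcm = sprintf("gcm%02d", g),
        scenario = params$scenario_id,
        temp_c = season + params$gcm_bias_offset + ramp + z
      )
    })
  })
  dplyr::bind_rows(members)
}

#' Write or read scenario series as CSV
#'
#' On-disk contract: headered CSV with columns `date,gcm,scenario,temp_c`.
#'
#' @param series Scenario tibble (see [simulate_scenario_series()]).
#' @param path File path.
#' @return `write_scenario_csv()` returns `series` invisibly;
#'   `read_scenario_csv()` the tibble.
#' @export
write_scenario_csv <- function(series, path) {
  cols <- c("date", "gcm", "scenario", "temp_c")
  assert_that(all(cols %in% names(series)),
              "`series` is missing required scenario columns.")
  readr::write_csv(series[cols], path)
  invisible(series)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), gcm = readr::col_character(),
    scenario = readr::col_character(), temp_c = readr::col_double()
  ))
}
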