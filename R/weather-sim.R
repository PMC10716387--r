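#' Parameters for the synthetic daily weather generator
#'
#' Bundles everything [simulate_weather()] needs to draw one region's daily
#' weather series: a sinusoidal seasonal temperature cycle, stationary AR(1)
#' day-to-day noise, and independent relative humidity.
#'
#' @param start_date,end_date Calendar bounds of the series (inclusive);
#'   anything `lubridate::as_date()` understands.
#' @param mean_temp Annual mean temperature, degrees C.
#' @param seasonal_amplitude Half-range of the seasonal cycle, degrees C.
#'   The cycle peaks in mid July (day of year 196).
#' @param ar1_coef Lag-1 autocorrelation of the temperature noise, in
#'   `[0, 1)`.
#' @param daily_sd Stationary standard deviation of the temperature noise,
#'   degrees C (the AR(1) innovation SD is scaled so the marginal SD equals
#'   this value).
#' @param humidity_mean,humidity_sd Mean and SD of daily relative humidity
#'   in percent; draws are clipped to `[0, 100]`.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters including the seed.
#'
#' @return An object of class `weather_params` (a named list).
#' @seealso [simulate_weather()]
#' @export
weather_params <- function(start_date = "2013-01-01", end_date = "2019-12-31",
                           mean_temp = 13.5, seasonal_amplitude = 11,
                           ar1_coef = 0.75, daily_sd = 3,
                           humidity_mean = 70, humidity_sd = 12,
                           seed = 1L) {
  start_date <- as_date_scalar(start_date, "start_date")
  end_date <- as_date_scalar(end_date, "end_date")
  assert_that(end_date > start_date, "`end_date` must be after `start_date`.")
  assert_scalar_number(mean_temp, "mean_temp")
  assert_scalar_number(seasonal_amplitude, "seasonal_amplitude", lower = 0)
  assert_scalar_number(ar1_coef, "ar1_coef", lower = 0, upper = 1,
                       strict_upper = TRUE)
  assert_scalar_number(daily_sd, "daily_sd", lower = 0)
  assert_scalar_number(humidity_mean, "humidity_mean", lower = 0, upper = 100)
  assert_scalar_number(humidity_sd, "humidity_sd", lower = 0)
  structure(list(start_date = start_date, end_date = end_date,
                 mean_temp = mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_coef = ar1_coef, daily_sd = daily_sd,
                 humidity_mean = humidity_mean, humidity_sd = humidity_sd,
                 seed = as.integer(seed)),
            class = "weather_params")
}

# Fixed synthetic holiday calendar: weekends plus ten fixed month-day pairs
# per year. Deliberately simple and country-agnostic.
.holiday_md <- c("01-01", "01-02", "01-03", "02-11", "05-01",
                 "06-20", "10-01", "10-02", "10-03", "12-25")

synthetic_holiday <- function(dates) {
  wd <- lubridate::wday(dates, week_start = 1)
  md <- format(dates, "%m-%d")
  wd >= 6L | md %in% .holiday_md
}

seasonal_cycle <- function(dates, mean_temp, amplitude, peak_doy = 196) {
  doy <- lubridate::yday(dates)
  mean_temp + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Simulate a daily weather series
#'
#' Draws one region's calendar-indexed daily series of mean temperature,
#' relative humidity and a holiday flag. Temperature is a seasonal cosine
#' plus stationary AR(1) noise; humidity is independent Gaussian clipped to
#' `[0, 100]`; holidays are weekends plus ten fixed dates per year.
#'
#' @param params A [weather_params()] object.
#'
#' @return A tibble with one row per calendar day and columns `date`,
#'   `temp_c`, `rh_pct`, `holiday`.
#' @examples
#' wx <- simulate_weather(weather_params(end_date = "2013-12-31", seed = 7))
#' head(wx)
#' @export
simulate_weather <- function(params) {
  assert_that(inherits(params, "weather_params"),
              "`params` must be created with `weather_params()`.")
  dates <- seq(params$start_date, params$end_date, by = "day")
  n <- length(dates)
  withr::with_seed(params$seed, {
    innov_sd <- params$daily_sd * sqrt(1 - params$ar1_coef^2)
    eps <- rnorm(n, sd = innov_sd)
    noise <- numeric(n)
    if (n > 0) {
      # start the chain at its stationary distribution
      noise[1] <- rnorm(1, sd = params$daily_sd)
      phi <- params$ar1_coef
      for (t in seq_len(n)[-1]) noise[t] <- phi * noise[t - 1] + eps[t]
    }
    rh <- rnorm(n, params$humidity_mean, params$humidity_sd)
  })
  tibble::tibble(
    date = dates,
    temp_c = seasonal_cycle(dates, params$mean_temp,
                            params$seasonal_amplitude) + noise,
    rh_pct = pmin(pmax(rh, 0), 100),
    holiday = synthetic_holiday(dates)
  )
}

#' Write or read a daily weather series as CSV
#'
#' The on-disk contract is a headered CSV with columns
#' `date,temp_c,rh_pct,holiday`.
#'
#' @param weather A weather tibble as returned by [simulate_weather()].
#' @param path File path.
#' @return `write_weather_csv()` returns `weather` invisibly;
#'   `read_weather_csv()` returns the weather tibble.
#' @export
write_weather_csv <- function(weather, path) {
  check_daily_series(weather)
  readr::write_csv(weather[c("date", "temp_c", "rh_pct", "holiday")], path)
  invisible(weather)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), temp_c = readr::col_double(),
    rh_pct = readr::col_double(), holiday = readr::col_logical()
  ))
  check_daily_series(out)
  out
}
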