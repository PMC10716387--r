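#' Demographic sampling specification for synthetic death records
#'
#' Category probabilities for the individual attributes attached to each
#' synthetic death. Attributes are sampled independently of each other and
#' of temperature, so subgroup analyses on synthetic data are unconfounded
#' by construction. Defaults mirror the demographic mix typical of
#' neurodegenerative-disease mortality registries: mostly 75+, slightly
#' more female, predominantly lower education.
#'
#' @param age_group,sex,education,region,cause Named probability vectors
#'   (normalised internally).
#' @return An object of class `demographics_spec`.
#' @export
demographics_spec <- function(
    age_group = c("<=64" = 0.08, "65-74" = 0.25, ">=75" = 0.67),
    sex = c(female = 0.535, male = 0.465),
    education = c(low = 0.916, high = 0.084),
    region = c(region1 = 1),
    cause = c(neurodegenerative = 1)) {
  fields <- list(age_group = age_group, sex = sex, education = education,
                 region = region, cause = cause)
  for (nm in names(fields)) {
    p <- fields[[nm]]
    assert_that(is.numeric(p) && length(p) >= 1 && all(p >= 0) && sum(p) > 0 &&
                  !is.null(names(p)) && all(nzchar(names(p))),
                sprintf("`%s` must be a named nonnegative probability vector.", nm))
    fields[[nm]] <- p / sum(p)
  }
  structure(fields, class = "demographics_spec")
}

#' Simulate death records from a known exposure-lag-response surface
#'
#' Daily death counts are Poisson with rate
#' `baseline_rate * exp(sum_l w[l] * f(T[t-l]))`, where `f` and `w` come
#' from the supplied [true_surface()]. Deaths occur only on days with a
#' complete lag window of weather history, so the first `max_lag` days of
#' the series act as warm-up. Each death is expanded into one individual
#' record with demographic attributes sampled from `demographics`.
#'
#' @param weather Daily weather tibble (see [simulate_weather()]); must
#'   cover at least `max_lag + 1` days.
#' @param surface A [true_surface()].
#' @param baseline_rate Expected deaths per day at the reference
#'   temperature.
#' @param demographics A [demographics_spec()].
#' @param seed Integer seed.
#'
#' @return A tibble of death records with columns
#'   `id, date, cause, age_group, sex, education, region`.
#' @export
simulate_deaths <- function(weather, surface, baseline_rate,
                            demographics = demographics_spec(), seed = 1L) {
  dates <- check_daily_series(weather)
  assert_that(inherits(surface, "true_surface"),
              "`surface` must be a `true_surface`.")
  assert_scalar_number(baseline_rate, "baseline_rate", lower = 0)
  assert_that(inherits(demographics, "demographics_spec"),
              "`demographics` must be a `demographics_spec`.")
  L <- surface$max_lag
  assert_that(nrow(weather) > L,
              sprintf("`weather` must cover more than %d days so deaths have a full lag history.", L))

  f_temp <- surface$exposure_log_rr(weather$temp_c)
  # distributed-lag log RR: weighted moving sum of f over the lag window
  log_rr <- stats::filter(f_temp, surface$lag_weights, method = "convolution",
                          sides = 1)
  usable <- (L + 1):nrow(weather)
  rate <- baseline_rate * exp(as.numeric(log_rr[usable]))

  withr::with_seed(as.integer(seed), {
    counts <- rpois(length(usable), rate)
    total <- sum(counts)
    rec_dates <- rep(dates[usable], counts)
    attrs <- lapply(demographics, function(p) {
      sample(names(p), total, replace = TRUE, prob = p)
    })
  })
  tibble::tibble(
    id = if (total > 0) sprintf("d%06d", seq_len(total)) else character(),
    date = rec_dates,
    cause = attrs$cause,
    age_group = attrs$age_group,
    sex = attrs$sex,
    education = attrs$education,
    region = attrs$region
  )
}

#' Write or read death records as CSV
#'
#' On-disk contract: headered CSV with columns
#' `id,date,cause,age_group,sex,education,region`.
#'
#' @param deaths Death-record tibble (see [simulate_deaths()]).
#' @param path File path.
#' @return `write_deaths_csv()` returns `deaths` invisibly;
#'   `read_deaths_csv()` the tibble.
#' @export
write_deaths_csv <- function(deaths, path) {
  cols <- c("id", "date", "cause", "age_group", "sex", "education", "region")
  assert_that(all(cols %in% names(deaths)),
              "`deaths` is missing required record columns.")
  readr::write_csv(deaths[cols], path)
  invisible(deaths)
}

#' @rdname write_deaths_csv
#' @export
read_deaths_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), date = readr::col_date(),
    .default = readr::col_character()
  ))
}
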