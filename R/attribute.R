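# Attributable-burden machinery: daily attributable deaths from a reduced
# curve, decade/scenario aggregation over a GCM ensemble, Monte Carlo
# empirical CIs, and differences versus the historical baseline.

#' Daily attributable deaths at given temperatures
#'
#' The number of deaths attributable to non-optimum temperature on a day
#' with temperature `T` is `D * (1 - exp(-delta))`, where `delta` is the
#' overall cumulative log relative risk at `T` versus the
#' minimum-mortality temperature and `D` is the average daily number of
#' deaths. Days above the minimum-mortality temperature contribute to the
#' heat component, days below to the cold component.
#'
#' @param curve A [reduced_curve()] with `mmt` set.
#' @param temp Daily temperatures (degrees C); vectorised.
#' @param baseline_deaths Average daily number of deaths `D` (>= 0).
#' @return Tibble `temperature, log_rr, an, component`.
#' @export
daily_attributable <- function(curve, temp, baseline_deaths) {
  assert_that(inherits(curve, "reduced_curve"),
              "`curve` must be a `reduced_curve`.")
  assert_that(is.finite(curve$mmt), "`curve$mmt` is not set; call `find_mmt()` first.")
  assert_scalar_number(baseline_deaths, "baseline_deaths", lower = 0)
  delta <- cumulative_log_rr(curve, temp)
  tibble::tibble(
    temperature = as.numeric(temp),
    log_rr = delta,
    an = baseline_deaths * (1 - exp(-delta)),
    component = ifelse(temp > curve$mmt, "heat", "cold")
  )
}

#' Monte Carlo draw settings for empirical confidence intervals
#'
#' @param n_sim Number of coefficient draws (default 1000).
#' @param seed Integer seed making the draws reproducible.
#' @return An object of class `mc_draws`.
#' @export
mc_draws <- function(n_sim = 1000L, seed = 1L) {
  assert_that(is.numeric(n_sim) && length(n_sim) == 1L && n_sim >= 1,
              "`n_sim` must be an integer >= 1.")
  structure(list(n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "mc_draws")
}

draw_eta <- function(curve, draws) {
  m <- withr::with_seed(draws$seed, {
    MASS::mvrnorm(draws$n_sim, mu = curve$eta, Sigma = curve$vcov,
                  tol = 1e-8)
  })
  matrix(m, nrow = draws$n_sim)
}

check_decade_coverage <- function(dates, decade) {
  y0 <- decade_start(decade)
  expected <- seq(lubridate::make_date(y0, 1, 1),
                  lubridate::make_date(y0 + 9, 12, 31), by = "day")
  assert_that(all(expected %in% dates),
              sprintf("Scenario series does not fully cover decade %s.", decade))
  expected
}

# Attributable numbers for one temperature vector under one or many
# coefficient vectors. Returns a (n_coef x 2) matrix [heat, cold].
# The heat/cold split uses the point-estimate T_mm throughout, so Monte
# Carlo draws perturb coefficients only, not the reference.
an_components <- function(curve, temp, baseline_deaths, eta_mat = NULL) {
  B <- ns_basis(temp, curve$exposure_spec)
  B0 <- ns_basis(curve$mmt, curve$exposure_spec)
  D <- B - matrix(B0, nrow(B), ncol(B), byrow = TRUE)
  etas <- if (is.null(eta_mat)) matrix(curve$eta, nrow = 1) else eta_mat
  delta <- D %*% t(etas)                       # days x n_coef
  an <- baseline_deaths * (1 - exp(-delta))
  hot <- temp > curve$mmt
  cbind(heat = colSums(an[hot, , drop = FALSE]),
        cold = colSums(an[!hot & temp != curve$mmt, , drop = FALSE]))
}

# Long tibble of attributable numbers per scenario/gcm/decade/component for
# the point estimate (draw 0) and optionally each Monte Carlo draw.
burden_draw_table <- function(curve, series, baseline_deaths, decades,
                              eta_mat = NULL) {
  assert_that(inherits(curve, "reduced_curve") && is.finite(curve$mmt),
              "`curve` must be a `reduced_curve` with `mmt` set (see `find_mmt()`).")
  assert_that(all(c("date", "gcm", "scenario", "temp_c") %in% names(series)),
              "`series` must have columns `date, gcm, scenario, temp_c`.")
  assert_scalar_number(baseline_deaths, "baseline_deaths", lower = 0)
  series <- dplyr::mutate(series, date = lubridate::as_date(.data$date))

  keys <- dplyr::distinct(series, .data$scenario, .data$gcm)
  purrr::pmap_dfr(keys, function(scenario, gcm) {
    sub <- series[series$scenario == scenario & series$gcm == gcm, ]
    purrr::map_dfr(decades, function(dec) {
      days <- check_decade_coverage(sub$date, dec)
      temp <- sub$temp_c[match(days, sub$date)]
      point <- an_components(curve, temp, baseline_deaths)
      res <- tibble::tibble(scenario = scenario, gcm = gcm, decade = dec,
                            draw = 0L,
                            heat = point[, "heat"], cold = point[, "cold"],
                            n_days = length(days))
      if (!is.null(eta_mat)) {
        dr <- an_components(curve, temp, baseline_deaths, eta_mat)
        res <- dplyr::bind_rows(res, tibble::tibble(
          scenario = scenario, gcm = gcm, decade = dec,
          draw = seq_len(nrow(eta_mat)),
          heat = dr[, "heat"], cold = dr[, "cold"], n_days = length(days)))
      }
      res
    })
  }) |>
    tidyr::pivot_longer(c("heat", "cold"), names_to = "component",
                        values_to = "an") |>
    dplyr::mutate(af_pct = .data$an / (baseline_deaths * .data$n_days) * 100)
}

#' Decade-level attributable burden (point estimates)
#'
#' Sums daily attributable deaths over each decade, split into heat (days
#' above the minimum-mortality temperature) and cold (days below), per GCM,
#' and averages across the ensemble. The attributable fraction is the
#' attributable number as a percentage of the decade's total expected
#' deaths (`baseline_deaths x days`).
#'
#' @param curve A [reduced_curve()] with `mmt` set.
#' @param series Long scenario tibble `date, gcm, scenario, temp_c`
#'   (typically bias-corrected; see [calibrate_ensemble()]).
#' @param baseline_deaths Average daily number of deaths.
#' @param decades Character vector of decade labels (`"1980s"`, ...,
#'   `"2090s"`); defaults to all decades fully covered by the series.
#' @param by_gcm Keep per-GCM rows instead of ensemble averages.
#' @return Tibble `scenario, decade, component (heat/cold/total), an,
#'   af_pct` (plus `gcm` if `by_gcm`).
#' @export
decade_burden <- function(curve, series, baseline_deaths, decades = NULL,
                          by_gcm = FALSE) {
  decades <- decades %||% covered_decades(series)
  tab <- burden_draw_table(curve, series, baseline_deaths, decades)
  tot <- tab |>
    dplyr::summarise(an = sum(.data$an), af_pct = sum(.data$af_pct),
                     .by = c("scenario", "gcm", "decade")) |>
    dplyr::mutate(component = "total")
  per_gcm <- dplyr::bind_rows(
    dplyr::select(tab, "scenario", "gcm", "decade", "component", "an", "af_pct"),
    dplyr::select(tot, "scenario", "gcm", "decade", "component", "an", "af_pct"))
  if (by_gcm) return(dplyr::arrange(per_gcm, .data$scenario, .data$gcm,
                                    .data$decade, .data$component))
  per_gcm |>
    dplyr::summarise(an = mean(.data$an), af_pct = mean(.data$af_pct),
                     .by = c("scenario", "decade", "component")) |>
    dplyr::arrange(.data$scenario, .data$decade, .data$component)
}

#' Decades fully covered by a scenario series
#'
#' @param series Long scenario tibble with a `date` column.
#' @return Character vector of decade labels.
#' @export
covered_decades <- function(series) {
  d <- lubridate::as_date(series$date)
  yrs <- lubridate::year(range(d))
  y0 <- ceiling(yrs[1] / 10) * 10
  starts <- seq(y0, yrs[2] - 9, by = 10)
  decade_label(starts[starts + 9 <= yrs[2]])
}

#' Monte Carlo empirical confidence intervals for decade burden
#'
#' Draws reduced-curve coefficients from their multivariate normal
#' sampling distribution (the minimum-mortality temperature is held at its
#' point estimate), recomputes each cell's attributable number for every
#' draw and GCM, and reports the 2.5th/97.5th percentiles. `"pooled"` mode
#' pools draws across GCMs (coefficient and climate-model spread enter the
#' interval together); `"ensemble_mean"` first averages each draw across
#' the ensemble.
#'
#' @inheritParams decade_burden
#' @param draws An [mc_draws()] object.
#' @param mode `"pooled"` (default) or `"ensemble_mean"`.
#' @return Tibble `scenario, decade, component, an, af_pct, eci_low,
#'   eci_high` (on the attributable-number scale; `af_eci_low/high` on the
#'   fraction scale).
#' @export
mc_eci <- function(curve, series, baseline_deaths, decades = NULL,
                   draws = mc_draws(), mode = c("pooled", "ensemble_mean")) {
  mode <- match.arg(mode)
  assert_that(inherits(draws, "mc_draws"), "`draws` must come from `mc_draws()`.")
  decades <- decades %||% covered_decades(series)
  eta_mat <- draw_eta(curve, draws)
  tab <- burden_draw_table(curve, series, baseline_deaths, decades, eta_mat)
  summarise_eci(tab, mode)
}

eci_bounds <- function(x) pctl(x, c(0.025, 0.975))

summarise_eci <- function(tab, mode) {
  tot <- tab |>
    dplyr::summarise(an = sum(.data$an), af_pct = sum(.data$af_pct),
                     .by = c("scenario", "gcm", "decade", "draw")) |>
    dplyr::mutate(component = "total")
  long <- dplyr::bind_rows(
    dplyr::select(tab, "scenario", "gcm", "decade", "draw", "component",
                  "an", "af_pct"),
    dplyr::select(tot, "scenario", "gcm", "decade", "draw", "component",
                  "an", "af_pct"))
  if (mode == "ensemble_mean") {
    long <- long |>
      dplyr::summarise(an = mean(.data$an), af_pct = mean(.data$af_pct),
                       .by = c("scenario", "decade", "draw", "component"))
  }
  point <- long |>
    dplyr::filter(.data$draw == 0L) |>
    dplyr::summarise(an = mean(.data$an), af_pct = mean(.data$af_pct),
                     .by = c("scenario", "decade", "component"))
  ints <- long |>
    dplyr::filter(.data$draw > 0L) |>
    dplyr::summarise(eci_low = eci_bounds(.data$an)[1],
                     eci_high = eci_bounds(.data$an)[2],
                     af_eci_low = eci_bounds(.data$af_pct)[1],
                     af_eci_high = eci_bounds(.data$af_pct)[2],
                     .by = c("scenario", "decade", "component"))
  out <- dplyr::left_join(point, ints,
                          by = c("scenario", "decade", "component"))
  if (!nrow(ints)) {
    out$eci_low <- out$an; out$eci_high <- out$an
    out$af_eci_low <- out$af_pct; out$af_eci_high <- out$af_pct
  }
  dplyr::arrange(out, .data$scenario, .data$decade, .data$component)
}

#' Differences in burden versus the historical baseline
#'
#' Subtracts the historical reference (the average over the 1980s-2000s
#' decades) from each scenario decade, per component, within every Monte
#' Carlo draw and GCM, then summarises. The net change is the sum of the
#' heat and cold differences (cold differences are negative under
#' warming). Operates on draw tables produced by [burden_draw_table()];
#' most users call [project_burden()] instead.
#'
#' @param cells Draw table for the scenario decades.
#' @param historical_cells Draw table for the historical decades, computed
#'   from the same curve, baseline deaths and draws.
#' @return Tibble `scenario, decade, component (heat/cold/net), d_an,
#'   d_af_pct, eci_low, eci_high, af_eci_low, af_eci_high`.
#' @export
difference_vs_historical <- function(cells, historical_cells) {
  needed <- c("scenario", "gcm", "decade", "draw", "component", "an", "af_pct")
  assert_that(all(needed %in% names(cells)) &&
                all(needed %in% names(historical_cells)),
              "`cells` and `historical_cells` must be draw tables (see `burden_draw_table()`).")
  hist_ref <- historical_cells |>
    dplyr::summarise(an_hist = mean(.data$an), af_hist = mean(.data$af_pct),
                     .by = c("scenario", "gcm", "draw", "component"))
  assert_that(nrow(hist_ref) > 0, "`historical_cells` is empty.")
  joined <- dplyr::inner_join(cells, hist_ref,
                              by = c("scenario", "gcm", "draw", "component"))
  assert_that(nrow(joined) == nrow(cells),
              "Cell keys do not match between scenario and historical tables.")
  diffs <- joined |>
    dplyr::mutate(d_an = .data$an - .data$an_hist,
                  d_af_pct = .data$af_pct - .data$af_hist)
  net <- diffs |>
    dplyr::summarise(d_an = sum(.data$d_an), d_af_pct = sum(.data$d_af_pct),
                     .by = c("scenario", "gcm", "decade", "draw")) |>
    dplyr::mutate(component = "net")
  long <- dplyr::bind_rows(
    dplyr::select(diffs, "scenario", "gcm", "decade", "draw", "component",
                  "d_an", "d_af_pct"),
    dplyr::select(net, "scenario", "gcm", "decade", "draw", "component",
                  "d_an", "d_af_pct"))
  point <- long |>
    dplyr::filter(.data$draw == 0L) |>
    dplyr::summarise(d_an = mean(.data$d_an), d_af_pct = mean(.data$d_af_pct),
                     .by = c("scenario", "decade", "component"))
  ints <- long |>
    dplyr::filter(.data$draw > 0L) |>
    dplyr::summarise(eci_low = eci_bounds(.data$d_an)[1],
                     eci_high = eci_bounds(.data$d_an)[2],
                     af_eci_low = eci_bounds(.data$d_af_pct)[1],
                     af_eci_high = eci_bounds(.data$d_af_pct)[2],
                     .by = c("scenario", "decade", "component"))
  out <- dplyr::left_join(point, ints,
                          by = c("scenario", "decade", "component"))
  if (!nrow(ints)) {
    out$eci_low <- out$d_an; out$eci_high <- out$d_an
    out$af_eci_low <- out$d_af_pct; out$af_eci_high <- out$d_af_pct
  }
  dplyr::arrange(out, .data$scenario, .data$decade, .data$component)
}

#' Project attributable burden across decades and scenarios
#'
#' End-to-end burden projection: decade-level heat/cold/total attributable
#' numbers and fractions with Monte Carlo empirical confidence intervals,
#' and the change of each scenario decade relative to the 1980-2009
#' historical baseline (average of the 1980s, 1990s and 2000s), with eCIs
#' propagated by differencing inside every draw.
#'
#' @inheritParams mc_eci
#' @param hist_decades Decades defining the historical baseline.
#' @param scenario_decades Decades to report; defaults to every covered
#'   decade from the 2010s on.
#' @return A list of class `burden_projection`: `burden` (absolute cells
#'   incl. historical decades), `differences`, and `settings`.
#' @export
project_burden <- function(curve, series, baseline_deaths,
                           scenario_decades = NULL,
                           hist_decades = c("1980s", "1990s", "2000s"),
                           draws = mc_draws(),
                           mode = c("pooled", "ensemble_mean")) {
  mode <- match.arg(mode)
  all_dec <- covered_decades(series)
  scenario_decades <- scenario_decades %||%
    setdiff(all_dec, c(hist_decades, decade_label(seq(1900, 1979, 10))))
  assert_that(all(hist_decades %in% all_dec),
              "The series does not cover the historical baseline decades.")
  eta_mat <- draw_eta(curve, draws)
  scen_tab <- burden_draw_table(curve, series, baseline_deaths,
                                scenario_decades, eta_mat)
  hist_tab <- burden_draw_table(curve, series, baseline_deaths,
                                hist_decades, eta_mat)
  structure(list(
    burden = summarise_eci(dplyr::bind_rows(hist_tab, scen_tab), mode),
    differences = difference_vs_historical(scen_tab, hist_tab),
    settings = list(hist_decades = hist_decades,
                    scenario_decades = scenario_decades,
                    n_sim = draws$n_sim, seed = draws$seed, mode = mode,
                    baseline_deaths = baseline_deaths, mmt = curve$mmt)
  ), class = "burden_projection")
}

#' @export
print.burden_projection <- function(x, ...) {
  cat("Attributable-burden projection\n")
  cat(sprintf("  decades: %s (baseline: %s)\n",
              paste(x$settings$scenario_decades, collapse = ", "),
              paste(x$settings$hist_decades, collapse = ", ")))
  cat(sprintf("  n_sim = %d, mode = %s, T_mm = %.1f degC\n",
              x$settings$n_sim, x$settings$mode, x$settings$mmt))
  print(x$burden, n = 10)
  invisible(x)
}

#' Write burden cells as tidy CSV
#'
#' One row per cell: `region,cause,scenario,decade,component,an,af_pct,
#' eci_low,eci_high`.
#'
#' @param cells Burden tibble (from [mc_eci()] or a `burden_projection`).
#' @param path File path.
#' @param region,cause Labels stamped on every row.
#' @return `cells`, invisibly.
#' @export
write_burden_csv <- function(cells, path, region = "region1",
                             cause = "neurodegenerative") {
  out <- dplyr::mutate(cells, region = region, cause = cause,
                       .before = 1)
  readr::write_csv(out, path)
  invisible(cells)
}
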