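# Desk-scale orchestration: simulate -> associate -> project, driven by a
# plain-text (YAML) config with one master seed. Sub-seeds are derived
# deterministically: weather seed+1, deaths seed+2, scenarios seed+101*i,
# Monte Carlo seed+7.

#' Build (or read) a pipeline run configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param weather_csv,deaths_csv,scenario_csv Input paths; defaults live
#'   under `out_dir` and are written by [simulate_inputs()].
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param baseline_rate Expected deaths/day of the synthetic generator and
#'   the projection baseline.
#' @param n_sim Monte Carlo draws for empirical CIs.
#' @param max_lag Maximum lag (days) of the cross-basis.
#' @param subgroup Optional filter expression (as a string, e.g.
#'   `"sex == 'female'"`) applied to the death records before fitting.
#' @param scenarios Scenario labels to simulate/use.
#' @param n_gcms Ensemble size of the synthetic scenario generator.
#' @param hist_decades,scenario_decades Decade labels for the projection.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "tempburden_run",
                       weather_csv = file.path(out_dir, "weather.csv"),
                       deaths_csv = file.path(out_dir, "deaths.csv"),
                       scenario_csv = file.path(out_dir, "scenarios.csv"),
                       seed = 1L, baseline_rate = 12,
                       n_sim = 1000L, max_lag = 14L,
                       subgroup = NULL,
                       scenarios = c("SSP126", "SSP245", "SSP585"),
                       n_gcms = 5L,
                       hist_decades = c("1980s", "1990s", "2000s"),
                       scenario_decades = NULL) {
  structure(list(out_dir = out_dir, weather_csv = weather_csv,
                 deaths_csv = deaths_csv, scenario_csv = scenario_csv,
                 seed = as.integer(seed), baseline_rate = baseline_rate,
                 n_sim = as.integer(n_sim), max_lag = as.integer(max_lag),
                 subgroup = subgroup, scenarios = scenarios,
                 n_gcms = as.integer(n_gcms),
                 hist_decades = hist_decades,
                 scenario_decades = scenario_decades),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file holding the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Simulate the full set of pipeline inputs
#'
#' Generates the observational weather series, the death records (from the
#' default inverted-J true surface), and one scenario ensemble per
#' configured scenario, and writes them to the configured CSV paths.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `weather`, `deaths`, `scenarios`,
#'   `surface`.
#' @export
simulate_inputs <- function(config) {
  assert_that(inherits(config, "run_config"),
              "`config` must be a `run_config`.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  weather <- simulate_weather(weather_params(seed = config$seed + 1L))
  surface <- default_true_surface(weather$temp_c, max_lag = config$max_lag)
  deaths <- simulate_deaths(weather, surface, config$baseline_rate,
                            seed = config$seed + 2L)
  scen_all <- ssp_scenarios(n_gcms = config$n_gcms, seed = config$seed)
  scen_all <- scen_all[intersect(names(scen_all), config$scenarios)]
  series <- dplyr::bind_rows(lapply(scen_all, function(p) {
    simulate_scenario_series(weather, p)
  }))
  write_weather_csv(weather, config$weather_csv)
  write_deaths_csv(deaths, config$deaths_csv)
  write_scenario_csv(series, config$scenario_csv)
  invisible(list(weather = weather, deaths = deaths, scenarios = series,
                 surface = surface))
}

#' Estimate the temperature-death association from the configured inputs
#'
#' Reads the weather and death CSVs, builds the cross-basis design and the
#' time-stratified case-crossover strata, fits the conditional logistic
#' model, reduces it to the overall cumulative curve, locates the
#' minimum-mortality temperature, and writes: the model artifact
#' (`model.json`), the exposure-response curve (`curve.csv`), the
#' lag-response curves at the 2.5th/97.5th percentiles (`lag_response.csv`)
#' and a one-row relative-risk table (`rr_table.csv`) with the MMT and the
#' cumulative RRs at those extremes.
#'
#' @param config A [run_config()].
#' @return A list of class `association_result`: `fit`, `curve`,
#'   `rr_table`, `weather`, `deaths`, `counts`.
#' @export
run_association <- function(config) {
  assert_that(inherits(config, "run_config"),
              "`config` must be a `run_config`.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  weather <- read_weather_csv(config$weather_csv)
  deaths <- read_deaths_csv(config$deaths_csv)
  if (!is.null(config$subgroup)) {
    deaths <- dplyr::filter(deaths, !!rlang::parse_expr(config$subgroup))
    assert_that(nrow(deaths) > 0, "The subgroup filter left no death records.")
  }

  spec <- default_crossbasis_spec(weather$temp_c, max_lag = config$max_lag)
  design <- build_design(weather, spec)
  strata <- build_strata(deaths)
  fit <- fit_clogit(strata, design)
  curve <- reduce_overall(fit, spec) |> find_mmt(weather$temp_c)

  pq <- pctl(weather$temp_c, c(0.025, 0.975))
  rr <- rr_at(curve, pq)
  rr_table <- tibble::tibble(
    cause = unique(deaths$cause)[1] %||% "all",
    region = unique(deaths$region)[1] %||% "region1",
    n_deaths = nrow(deaths),
    mmt = curve$mmt,
    p2.5_temp = pq[1], rr_p2.5 = rr$rr[1],
    rr_p2.5_low = rr$ci_low[1], rr_p2.5_high = rr$ci_high[1],
    p97.5_temp = pq[2], rr_p97.5 = rr$rr[2],
    rr_p97.5_low = rr$ci_low[2], rr_p97.5_high = rr$ci_high[2])

  readr::write_csv(tidy(curve), file.path(config$out_dir, "curve.csv"))
  lag_tab <- dplyr::bind_rows(
    dplyr::mutate(lag_response_at(fit, pq[1], curve$mmt, spec),
                  contrast = "p2.5"),
    dplyr::mutate(lag_response_at(fit, pq[2], curve$mmt, spec),
                  contrast = "p97.5"))
  readr::write_csv(lag_tab, file.path(config$out_dir, "lag_response.csv"))
  readr::write_csv(rr_table, file.path(config$out_dir, "rr_table.csv"))
  write_model_json(fit, curve, config,
                   file.path(config$out_dir, "model.json"))

  structure(list(fit = fit, curve = curve, rr_table = rr_table,
                 weather = weather, deaths = deaths,
                 counts = list(deaths = nrow(deaths),
                               strata_used = fit$n_strata,
                               strata_dropped = fit$n_dropped)),
            class = "association_result")
}

#' Project the death burden from a fitted association
#'
#' Reads the scenario ensemble CSV, bias-corrects every member against the
#' observed series, computes decade x scenario x component burden with
#' Monte Carlo empirical CIs and the differences versus the 1980-2009
#' historical baseline, and writes `burden.csv`, `differences.csv` and a
#' run manifest (`manifest.json`) recording seeds and the config hash.
#'
#' @param config A [run_config()].
#' @param association The [run_association()] result.
#' @return A `burden_projection` (see [project_burden()]).
#' @export
run_projection <- function(config, association) {
  assert_that(inherits(config, "run_config"),
              "`config` must be a `run_config`.")
  assert_that(inherits(association, "association_result"),
              "`association` must come from `run_association()`.")
  series <- read_scenario_csv(config$scenario_csv)
  series <- series[series$scenario %in% config$scenarios, ]
  assert_that(nrow(series) > 0, "No scenario rows match the configured scenarios.")
  corrected <- dplyr::bind_rows(lapply(
    split(series, series$scenario),
    function(g) calibrate_ensemble(g, association$weather)))

  baseline_deaths <- nrow(association$deaths) /
    nrow(association$weather)
  proj <- project_burden(association$curve, corrected, baseline_deaths,
                         scenario_decades = config$scenario_decades,
                         hist_decades = config$hist_decades,
                         draws = mc_draws(config$n_sim,
                                          seed = config$seed + 7L))
  write_burden_csv(proj$burden, file.path(config$out_dir, "burden.csv"),
                   region = association$rr_table$region,
                   cause = association$rr_table$cause)
  write_burden_csv(proj$differences,
                   file.path(config$out_dir, "differences.csv"),
                   region = association$rr_table$region,
                   cause = association$rr_table$cause)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("tempburden")),
    master_seed = config$seed,
    stage_seeds = list(weather = config$seed + 1L, deaths = config$seed + 2L,
                       monte_carlo = config$seed + 7L),
    n_sim = config$n_sim,
    config_hash = config_hash(config),
    counts = association$counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  proj
}

# Plain-text model artifact: coefficients, covariance, spec and counts.
write_model_json <- function(fit, curve, config, path) {
  spec <- fit$spec
  jsonlite::write_json(list(
    coef = as.list(fit$coef),
    vcov = fit$vcov,
    loglik = fit$loglik,
    converged = fit$converged,
    n_strata = fit$n_strata,
    n_dropped = fit$n_dropped,
    mmt = curve$mmt,
    reduced_coef = curve$eta,
    reduced_vcov = curve$vcov,
    exposure_knots = spec$exposure_spec$internal_knots,
    exposure_boundary = spec$exposure_spec$boundary_knots,
    lag_knots = spec$lag_spec$internal_knots,
    max_lag = spec$max_lag,
    seed = config$seed
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
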