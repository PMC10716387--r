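# Monthly additive empirical quantile mapping with trend preservation.
# Offsets are fitted on detrended series so the model's long-term warming
# signal is not absorbed into the correction.

qm_prob_grid <- function() seq(0.01, 0.99, by = 0.01)

# residuals of a linear-in-time fit, re-centred at the series mean, so
# detrended values keep their physical units
detrend_keep_mean <- function(values, dates) {
  t_num <- as.numeric(dates)
  fit <- stats::lm.fit(cbind(1, t_num), values)
  values - fit$fitted.values + mean(values)
}

#' Fit monthly quantile-mapping corrections
#'
#' For each calendar month, computes additive offsets
#' `observed quantile - modelled quantile` on a fixed probability grid
#' (0.01 to 0.99 by 0.01), after removing each series' linear trend over
#' the overlap period. Applying these offsets maps the model's
#' distribution onto the observed one while leaving the model's own trend
#' intact.
#'
#' @param obs Observed daily series (tibble with `date`, `temp_c`).
#' @param model_hist Modelled series for the same region; must cover the
#'   overlap period.
#' @param overlap Length-2 vector of dates bounding the calibration
#'   period; defaults to the intersection of the two series.
#' @return A tibble of class `qm_correction` with columns `month`, `prob`,
#'   `offset`.
#' @export
fit_correction <- function(obs, model_hist, overlap = NULL) {
  check_daily_series(obs, "obs")
  assert_that(is.data.frame(model_hist) &&
                all(c("date", "temp_c") %in% names(model_hist)),
              "`model_hist` must have `date` and `temp_c` columns.")
  obs_d <- lubridate::as_date(obs$date)
  mod_d <- lubridate::as_date(model_hist$date)
  if (is.null(overlap)) {
    overlap <- c(max(min(obs_d), min(mod_d)), min(max(obs_d), max(mod_d)))
  } else {
    overlap <- lubridate::as_date(overlap)
  }
  assert_that(overlap[1] < overlap[2],
              "The two series have no overlap period to calibrate on.")

  keep_o <- obs_d >= overlap[1] & obs_d <= overlap[2]
  keep_m <- mod_d >= overlap[1] & mod_d <= overlap[2]
  assert_that(sum(keep_o) > 0 && sum(keep_m) > 0,
              "The overlap period is not covered by both series.")

  o_val <- detrend_keep_mean(obs$temp_c[keep_o], obs_d[keep_o])
  m_val <- detrend_keep_mean(model_hist$temp_c[keep_m], mod_d[keep_m])
  o_mon <- lubridate::month(obs_d[keep_o])
  m_mon <- lubridate::month(mod_d[keep_m])

  probs <- qm_prob_grid()
  out <- purrr::map_dfr(1:12, function(m) {
    ov <- o_val[o_mon == m]; mv <- m_val[m_mon == m]
    assert_that(length(ov) >= 20 && length(mv) >= 20,
                sprintf("Fewer than 20 overlap days in calendar month %d.", m))
    tibble::tibble(month = m, prob = probs,
                   offset = pctl(ov, probs) - pctl(mv, probs))
  })
  class(out) <- c("qm_correction", class(out))
  out
}

#' Apply quantile-mapping corrections to a daily series
#'
#' Each day's value becomes `raw + offset(p)`, where `p` is the value's
#' quantile position within its calendar month's distribution -- computed
#' within the day's own decade, so a century-scale warming signal cannot
#' drag late-period days into the tail of a pooled distribution (the
#' decade-local grouping plays the role of detrending on the apply side) --
#' and `offset(p)` linearly interpolates the fitted monthly offsets
#' (constant beyond the 1st/99th percentile). Because the correction is a
#' bounded additive perturbation indexed by local rank, the series' own
#' long-term trend, day-to-day variability and within-month rank order are
#' preserved.
#'
#' @param series Daily series (tibble with `date`, `temp_c`) to correct,
#'   e.g. a single GCM's 1980-2099 series.
#' @param corrections A [fit_correction()] result.
#' @return The input tibble with `temp_c` replaced by the corrected values
#'   (original values kept in `temp_c_raw`).
#' @export
apply_correction <- function(series, corrections) {
  assert_that(inherits(corrections, "qm_correction"),
              "`corrections` must come from `fit_correction()`.")
  assert_that(is.data.frame(series) &&
                all(c("date", "temp_c") %in% names(series)),
              "`series` must have `date` and `temp_c` columns.")
  d <- lubridate::as_date(series$date)
  val <- detrend_keep_mean(series$temp_c, d)
  mon <- lubridate::month(d)
  dec <- lubridate::year(d) %/% 10L
  probs <- qm_prob_grid()

  corrected <- series$temp_c
  for (m in sort(unique(mon))) {
    off_m <- corrections$offset[corrections$month == m]
    assert_that(length(off_m) == length(probs),
                sprintf("`corrections` has no offsets for month %d.", m))
    # natural-spline interpolation of the offsets follows the curvature of
    # the quantile difference between grid nodes; constant beyond them
    off_fun <- stats::splinefun(probs, off_m, method = "natural")
    for (dc in unique(dec[mon == m])) {
      idx <- which(mon == m & dec == dc)
      # detrended quantile position, on the same convention the offsets
      # were fitted with (quantile type 7: rank r sits at (r-1)/(n-1));
      # the decade-local group keeps any non-linear century-scale signal
      # out of the within-month distribution
      p <- (rank(val[idx], ties.method = "average") - 1) / (length(idx) - 1)
      corr_val <- series$temp_c[idx] +
        off_fun(pmin(pmax(p, probs[1]), probs[length(probs)]))
      # detrended and raw ranks can disagree for near-ties; reassigning the
      # corrected values by raw rank keeps the mapping exactly monotone
      # without changing the corrected distribution
      corrected[idx] <- sort(corr_val)[rank(series$temp_c[idx],
                                            ties.method = "first")]
    }
  }
  out <- series
  out$temp_c_raw <- series$temp_c
  out$temp_c <- corrected
  out
}

#' Bias-correct a multi-GCM scenario ensemble
#'
#' Convenience wrapper: fits corrections per GCM against the observed
#' series over the historical overlap and applies them to each member's
#' full series.
#'
#' @param scenario_series Long tibble `date, gcm, scenario, temp_c`.
#' @param obs Observed daily series.
#' @param overlap Calibration period passed to [fit_correction()];
#'   defaults to the observed series' span.
#' @return The corrected long tibble (with `temp_c_raw`).
#' @export
calibrate_ensemble <- function(scenario_series, obs, overlap = NULL) {
  assert_that(all(c("date", "gcm", "temp_c") %in% names(scenario_series)),
              "`scenario_series` must have `date`, `gcm` and `temp_c` columns.")
  if (is.null(overlap)) {
    od <- lubridate::as_date(obs$date)
    overlap <- c(min(od), max(od))
  }
  scenario_series |>
    dplyr::group_by(.data$gcm) |>
    dplyr::group_modify(function(g, key) {
      corr <- fit_correction(obs, g, overlap = overlap)
      apply_correction(g, corr)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("date", "gcm")
}
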