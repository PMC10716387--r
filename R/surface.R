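#' Define a true exposure-lag-response surface
#'
#' The synthetic death generator draws daily counts whose log hazard ratio is
#' `sum_l lag_weights[l] * exposure_log_rr(T[t - l])` over lags 0..14. The
#' surface separates into a cumulative exposure-response function (log
#' relative risk versus temperature, zero at `reference_temp`) and a vector
#' of nonnegative lag weights summing to one, so the cumulative log RR
#' implied over the full lag window equals `exposure_log_rr` itself.
#'
#' @param exposure_log_rr Function mapping temperature (degrees C) to
#'   cumulative log relative risk; must return 0 at `reference_temp`.
#' @param lag_weights Numeric vector of length `max_lag + 1`, nonnegative,
#'   summing to 1 (tolerance 1e-9).
#' @param reference_temp Temperature at which the cumulative log RR is zero.
#' @param max_lag Maximum lag in days (default 14).
#'
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(exposure_log_rr, lag_weights, reference_temp,
                         max_lag = 14L) {
  assert_that(is.function(exposure_log_rr),
              "`exposure_log_rr` must be a function of temperature.")
  assert_that(is.numeric(lag_weights) && length(lag_weights) == max_lag + 1L,
              sprintf("`lag_weights` must have length %d.", max_lag + 1L))
  assert_that(all(lag_weights >= 0) && abs(sum(lag_weights) - 1) < 1e-9,
              "`lag_weights` must be nonnegative and sum to 1.")
  assert_scalar_number(reference_temp, "reference_temp")
  assert_that(abs(exposure_log_rr(reference_temp)) < 1e-9,
              "`exposure_log_rr(reference_temp)` must be 0.")
  structure(list(exposure_log_rr = exposure_log_rr,
                 lag_weights = as.numeric(lag_weights),
                 reference_temp = reference_temp,
                 max_lag = as.integer(max_lag)),
            class = "true_surface")
}

#' Lag-weight profiles for synthetic surfaces
#'
#' `"heat"` is front-loaded (exponential decay from lag 0, mimicking acute
#' heat effects), `"cold"` is back-loaded (bell around lag 6, mimicking
#' delayed cold effects), `"uniform"` spreads the effect evenly.
#'
#' @param pattern One of `"heat"`, `"cold"`, `"uniform"`.
#' @param max_lag Maximum lag in days.
#' @return Normalised weight vector of length `max_lag + 1`.
#' @export
lag_weight_profile <- function(pattern = c("heat", "cold", "uniform"),
                               max_lag = 14L) {
  pattern <- match.arg(pattern)
  l <- 0:max_lag
  w <- switch(pattern,
              heat = exp(-l / 2.5),
              cold = exp(-((l - 6)^2) / (2 * 2.5^2)),
              uniform = rep(1, length(l)))
  w / sum(w)
}

#' Default inverted-J synthetic truth
#'
#' Piecewise-quadratic cumulative exposure-response with its minimum at the
#' 75th percentile of the supplied temperature distribution, cumulative RR
#' `rr_cold` (default 2.0) at the 2.5th percentile and `rr_heat` (default
#' 1.3) at the 97.5th percentile -- an "inverted J" of the shape and size
#' typical of temperature-mortality curves, with a steeper cold arm.
#' Quadratic arms make the curve smooth at the reference, so the reference
#' is also the true minimum-mortality temperature.
#'
#' @param temps Numeric vector of observed daily temperatures used to set
#'   the anchoring percentiles.
#' @param rr_cold,rr_heat Cumulative relative risks at the 2.5th / 97.5th
#'   percentile relative to the reference.
#' @param lag_pattern Passed to [lag_weight_profile()].
#' @param max_lag Maximum lag in days.
#' @return A [true_surface()] object with attributes `p2.5`, `p75`, `p97.5`.
#' @export
default_true_surface <- function(temps, rr_cold = 2.0, rr_heat = 1.3,
                                 lag_pattern = "heat", max_lag = 14L) {
  assert_that(is.numeric(temps) && all(is.finite(temps)) && length(temps) > 10,
              "`temps` must be a finite numeric vector (an observed series).")
  q <- pctl(temps, c(0.025, 0.75, 0.975))
  p_cold <- q[1]; ref <- q[2]; p_heat <- q[3]
  log_cold <- log(rr_cold); log_heat <- log(rr_heat)
  f <- function(temp) {
    d <- temp - ref
    ifelse(d < 0,
           log_cold * (d / (p_cold - ref))^2,
           log_heat * (d / (p_heat - ref))^2)
  }
  out <- true_surface(f, lag_weight_profile(lag_pattern, max_lag), ref,
                      max_lag = max_lag)
  attr(out, "anchors") <- c(p2.5 = p_cold, p75 = ref, p97.5 = p_heat)
  out
}

#' Evaluate the cumulative log relative risk of a true surface
#'
#' @param surface A [true_surface()].
#' @param temp Temperatures (degrees C).
#' @return Cumulative log RR at `temp` relative to the surface's reference.
#' @export
surface_log_rr <- function(surface, temp) {
  assert_that(inherits(surface, "true_surface"),
              "`surface` must be a `true_surface`.")
  surface$exposure_log_rr(temp)
}
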