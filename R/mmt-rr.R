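#' Locate the minimum-mortality temperature
#'
#' Finds the temperature minimising the overall cumulative log relative
#' risk on a fixed 0.1 degree C grid over the 1st-99th percentile range of
#' the observed temperature distribution (configurable). Restricting the
#' search to the bulk of the distribution avoids extrapolation artefacts
#' from sparse extremes. Ties are broken toward the median temperature. A
#' minimum at either search bound is flagged as a boundary solution.
#'
#' @param curve A [reduced_curve()].
#' @param temps Observed temperature distribution defining the search
#'   range.
#' @param probs Percentile bounds of the search range.
#' @param grid_step Search grid resolution, degrees C.
#' @return The input curve with `mmt` set, `display_range` set to the
#'   search range, and attribute `mmt_boundary` (logical).
#' @export
find_mmt <- function(curve, temps, probs = c(0.01, 0.99), grid_step = 0.1) {
  assert_that(inherits(curve, "reduced_curve"),
              "`curve` must be a `reduced_curve`.")
  assert_that(is.numeric(temps) && all(is.finite(temps)) && length(temps) > 1,
              "`temps` must be a finite numeric vector.")
  rng <- pctl(temps, probs)
  grid <- seq(rng[1], rng[2], by = grid_step)
  # relative to any fixed reference; the argmin does not depend on it
  val <- drop(ns_basis(grid, curve$exposure_spec) %*% curve$eta)
  assert_that(all(is.finite(val)), "Curve values are non-finite on the search grid.")
  minima <- which(val <= min(val) + 1e-12)
  pick <- minima[which.min(abs(grid[minima] - median(temps)))]
  curve$mmt <- grid[pick]
  curve$display_range <- rng
  attr(curve, "mmt_boundary") <- pick == 1L || pick == length(grid)
  curve
}

#' Relative risk (with 95% CI) at given temperatures
#'
#' Cumulative relative risk versus the curve's minimum-mortality
#' temperature, with delta-method confidence intervals:
#' `exp(d.eta +/- 1.96 sqrt(d V d'))` for the basis contrast
#' `d = B_exp(T) - B_exp(T_mm)`. Temperatures beyond the spline boundary
#' are evaluated on the natural linear extension and flagged.
#'
#' @param curve A [reduced_curve()] with `mmt` set (see [find_mmt()]).
#' @param temp Temperatures (degrees C); vectorised.
#' @param conf_z Normal quantile of the interval (1.96 for 95%).
#' @return Tibble `temperature, rr, ci_low, ci_high, extrapolated`.
#' @export
rr_at <- function(curve, temp, conf_z = 1.96) {
  assert_that(inherits(curve, "reduced_curve"),
              "`curve` must be a `reduced_curve`.")
  assert_that(is.finite(curve$mmt),
              "`curve$mmt` is not set; call `find_mmt()` first.")
  B <- ns_basis(temp, curve$exposure_spec)
  D <- B - matrix(ns_basis(curve$mmt, curve$exposure_spec),
                  nrow(B), ncol(B), byrow = TRUE)
  log_rr <- drop(D %*% curve$eta)
  se <- sqrt(pmax(0, rowSums((D %*% curve$vcov) * D)))
  bk <- curve$exposure_spec$boundary_knots
  out <- tibble::tibble(
    temperature = as.numeric(temp),
    rr = exp(log_rr),
    ci_low = exp(log_rr - conf_z * se),
    ci_high = exp(log_rr + conf_z * se),
    extrapolated = temp < bk[1] | temp > bk[2]
  )
  if (any(out$extrapolated)) {
    warn("Some temperatures lie beyond the basis boundary; values use the natural linear extension.")
  }
  out
}

#' Lag-response curve at a given temperature
#'
#' Lag-specific relative risks comparing temperature `temp` to the
#' minimum-mortality temperature: the lag-`l` log RR is the bilinear form
#' `(B_exp(T) - B_exp(T_mm)) x B_lag(l)` applied to the cross-basis
#' coefficients, with delta-method CIs. The product of the lag-specific
#' RRs over lags `0..max_lag` equals the overall cumulative RR.
#'
#' @param fit A converged [fit_clogit()].
#' @param mmt Reference (minimum-mortality) temperature.
#' @param temp Single temperature to contrast against `mmt`.
#' @param spec The [crossbasis_spec()]; defaults to the fit's.
#' @param conf_z Normal quantile of the interval.
#' @return Tibble `lag, rr, ci_low, ci_high`.
#' @export
lag_response_at <- function(fit, temp, mmt, spec = NULL, conf_z = 1.96) {
  assert_that(inherits(fit, "cc_fit"), "`fit` must be a `cc_fit`.")
  assert_that(fit$converged, "The fit did not converge.")
  spec <- spec %||% fit$spec
  assert_scalar_number(temp, "temp")
  assert_scalar_number(mmt, "mmt")
  cb_names <- crossbasis_colnames(spec)
  theta <- fit$coef[cb_names]
  V <- fit$vcov[cb_names, cb_names, drop = FALSE]
  assert_that(!anyNA(theta) && !anyNA(V),
              "Cross-basis block is not fully identified.")
  dB <- ns_basis(temp, spec$exposure_spec) -
    ns_basis(mmt, spec$exposure_spec)                # 1 x ne
  Blag <- lag_basis_matrix(spec)                     # (L+1) x nl
  # exposure-major contrast for lag l: kron(dB, B_lag(l))
  C <- t(vapply(seq_len(nrow(Blag)), function(r) {
    as.numeric(t(outer(drop(dB), Blag[r, ])))
  }, numeric(length(theta))))
  log_rr <- drop(C %*% theta)
  se <- sqrt(pmax(0, rowSums((C %*% V) * C)))
  tibble::tibble(lag = 0:spec$max_lag,
                 rr = exp(log_rr),
                 ci_low = exp(log_rr - conf_z * se),
                 ci_high = exp(log_rr + conf_z * se))
}
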