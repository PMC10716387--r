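#' Construct a reduced overall cumulative exposure-response curve
#'
#' Low-level constructor pairing reduced exposure-dimension coefficients
#' with their covariance and spline spec. Most users obtain one via
#' [reduce_overall()]; the constructor is exported so curves can also be
#' built from externally supplied coefficients (e.g. synthetic truths in
#' simulation studies).
#'
#' @param eta Reduced coefficient vector (length = exposure basis
#'   dimension).
#' @param vcov Covariance matrix of `eta` (symmetric PSD).
#' @param exposure_spec The exposure [spline_spec()].
#' @param mmt Minimum-mortality temperature (may be `NA` until
#'   [find_mmt()] is called).
#' @param display_range Temperature interval used for tidy/plot exports.
#' @return An object of class `reduced_curve`.
#' @export
reduced_curve <- function(eta, vcov, exposure_spec, mmt = NA_real_,
                          display_range = exposure_spec$boundary_knots) {
  ne <- spline_dim(exposure_spec)
  assert_that(length(eta) == ne && all(is.finite(eta)),
              sprintf("`eta` must be a finite vector of length %d.", ne))
  assert_that(is.matrix(vcov) && all(dim(vcov) == ne) &&
                all(is.finite(vcov)) &&
                max(abs(vcov - t(vcov))) < 1e-8,
              "`vcov` must be a finite symmetric matrix matching `eta`.")
  ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8 * max(abs(ev), 1),
              "`vcov` must be positive semidefinite.")
  structure(list(eta = as.numeric(eta), vcov = (vcov + t(vcov)) / 2,
                 exposure_spec = exposure_spec, mmt = mmt,
                 display_range = as.numeric(display_range)),
            class = "reduced_curve")
}

# linear map from the cross-basis coefficient block to reduced exposure
# coefficients: eta_i = sum_j theta_(i,j) * s_j with s_j = sum_l B_lag_j(l)
reduction_map <- function(spec) {
  s <- colSums(lag_basis_matrix(spec))
  d <- crossbasis_dims(spec)
  A <- matrix(0, nrow = d["exposure"], ncol = d["exposure"] * d["lag"])
  for (i in seq_len(d["exposure"])) {
    A[i, (i - 1L) * d["lag"] + seq_len(d["lag"])] <- s
  }
  A
}

#' Reduce a fitted exposure-lag surface to the overall cumulative curve
#'
#' Sums the lag dimension out of the bi-dimensional cross-basis fit: with
#' `s_j = sum_{l=0..max_lag} B_lag_j(l)`, the reduced coefficients are
#' `eta_i = sum_j theta_(i,j) s_j` and the reduced covariance is the
#' corresponding linear transform of the cross-basis coefficient
#' covariance. The cumulative log relative risk at temperature `T` versus
#' reference `r` is `(B_exp(T) - B_exp(r)) %*% eta`.
#'
#' @param fit A converged [fit_clogit()] result.
#' @param spec The [crossbasis_spec()] used in the design; defaults to the
#'   spec recorded in the fit.
#' @return A [reduced_curve()] (without `mmt`; see [find_mmt()]).
#' @export
reduce_overall <- function(fit, spec = NULL) {
  assert_that(inherits(fit, "cc_fit"), "`fit` must be a `cc_fit`.")
  assert_that(fit$converged, "The fit did not converge; refusing to reduce it.")
  spec <- spec %||% fit$spec
  assert_that(inherits(spec, "crossbasis_spec"),
              "`spec` must be a `crossbasis_spec`.")
  cb_names <- crossbasis_colnames(spec)
  assert_that(all(cb_names %in% names(fit$coef)),
              "The fit does not contain the cross-basis block of `spec`.")
  theta <- fit$coef[cb_names]
  V <- fit$vcov[cb_names, cb_names, drop = FALSE]
  assert_that(!anyNA(theta) && !anyNA(V),
              "Cross-basis block is not fully identified; cannot reduce.")
  A <- reduction_map(spec)
  reduced_curve(drop(A %*% theta), A %*% V %*% t(A), spec$exposure_spec)
}

#' Cumulative log relative risk of a reduced curve
#'
#' @param curve A [reduced_curve()].
#' @param temp Temperatures (degrees C).
#' @param ref Reference temperature; defaults to the curve's
#'   minimum-mortality temperature.
#' @return Numeric vector of cumulative log RR values.
#' @export
cumulative_log_rr <- function(curve, temp, ref = curve$mmt) {
  assert_that(inherits(curve, "reduced_curve"),
              "`curve` must be a `reduced_curve`.")
  assert_that(is.finite(ref), "A finite reference temperature is required.")
  B <- ns_basis(temp, curve$exposure_spec)
  B0 <- ns_basis(ref, curve$exposure_spec)
  drop((B - matrix(B0, nrow(B), ncol(B), byrow = TRUE)) %*% curve$eta)
}

#' Tidy a reduced curve onto a temperature grid
#'
#' @param x A `reduced_curve` with `mmt` set.
#' @param n Number of grid points over the display range.
#' @param ... Unused.
#' @return Tibble `temperature, rr, ci_low, ci_high`.
#' @method tidy reduced_curve
#' @export
tidy.reduced_curve <- function(x, n = 200L, ...) {
  grid <- seq(x$display_range[1], x$display_range[2], length.out = n)
  rr_at(x, grid)
}
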