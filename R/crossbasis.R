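#' Cross-basis specification
#'
#' Combines an exposure-dimension spline (no intercept, so the cumulative
#' curve is zero at a reference) with a lag-dimension spline (with
#' intercept, so immediate lag-0 effects are representable) over lags
#' `0..max_lag`. The resulting bi-dimensional basis has
#' `dim(exposure) * dim(lag)` columns.
#'
#' @param exposure_spec [spline_spec()] for the temperature axis; must have
#'   `with_intercept = FALSE`.
#' @param lag_spec [spline_spec()] over the lag axis; must have
#'   `with_intercept = TRUE`.
#' @param max_lag Maximum lag in days (default 14).
#' @return An object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(exposure_spec, lag_spec, max_lag = 14L) {
  assert_that(inherits(exposure_spec, "spline_spec") &&
                !exposure_spec$with_intercept,
              "`exposure_spec` must be a `spline_spec` without intercept.")
  assert_that(inherits(lag_spec, "spline_spec") && lag_spec$with_intercept,
              "`lag_spec` must be a `spline_spec` with intercept.")
  assert_that(is.numeric(max_lag) && length(max_lag) == 1L && max_lag >= 1,
              "`max_lag` must be an integer >= 1.")
  structure(list(exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag)),
            class = "crossbasis_spec")
}

#' Default cross-basis for a temperature series
#'
#' Exposure dimension: natural cubic spline with internal knots at the
#' 10th, 75th and 90th percentiles of the observed distribution and
#' boundary knots at its range. Lag dimension: natural cubic spline over
#' lags 0..14 with three internal knots equally spaced on the log-lag
#' scale.
#'
#' @param temps Observed daily temperature series defining percentile knots
#'   and boundaries.
#' @param max_lag Maximum lag in days.
#' @param exposure_probs Percentile positions of the exposure knots.
#' @param n_lag_knots Number of internal log-spaced lag knots.
#' @return A [crossbasis_spec()].
#' @export
default_crossbasis_spec <- function(temps, max_lag = 14L,
                                    exposure_probs = c(0.10, 0.75, 0.90),
                                    n_lag_knots = 3L) {
  assert_that(is.numeric(temps) && all(is.finite(temps)) && length(temps) > 1,
              "`temps` must be a finite numeric vector.")
  crossbasis_spec(
    spline_spec(pctl(temps, exposure_probs), range(temps),
                with_intercept = FALSE),
    spline_spec(lag_knots_log(max_lag, n_lag_knots), c(0, max_lag),
                with_intercept = TRUE),
    max_lag = max_lag
  )
}

crossbasis_dims <- function(spec) {
  c(exposure = spline_dim(spec$exposure_spec),
    lag = spline_dim(spec$lag_spec))
}

# Lag basis evaluated at integer lags 0..max_lag; rows are lags.
lag_basis_matrix <- function(spec) {
  ns_basis(0:spec$max_lag, spec$lag_spec)
}

crossbasis_colnames <- function(spec) {
  d <- crossbasis_dims(spec)
  paste0("cb_e", rep(seq_len(d["exposure"]), each = d["lag"]),
         "_l", rep(seq_len(d["lag"]), times = d["exposure"]))
}

#' Build the cross-basis matrix for a daily temperature series
#'
#' Row `t`, column `(i, j)` holds
#' `sum_{l = 0..max_lag} B_exposure_i(T[t - l]) * B_lag_j(l)`; columns are
#' ordered exposure-major (`cb_e1_l1, cb_e1_l2, ...`). The first `max_lag`
#' rows lack a complete exposure history and are set to `NA` (flagged
#' unusable) rather than dropped, so row `t` always aligns with day `t`.
#'
#' @param temps Daily temperature vector, one value per consecutive day.
#' @param spec A [crossbasis_spec()].
#' @return A numeric matrix of class `crossbasis` with attributes `spec`
#'   and `usable` (logical row flags).
#' @export
build_crossbasis <- function(temps, spec) {
  assert_that(inherits(spec, "crossbasis_spec"),
              "`spec` must be a `crossbasis_spec`.")
  assert_that(is.numeric(temps) && all(is.finite(temps)),
              "`temps` must be numeric with no non-finite values.")
  L <- spec$max_lag
  n <- length(temps)
  assert_that(n > L,
              sprintf("`temps` must be longer than max_lag = %d days.", L))

  E <- ns_basis(temps, spec$exposure_spec)           # n x ne
  Blag <- lag_basis_matrix(spec)                     # (L+1) x nl
  ne <- ncol(E); nl <- ncol(Blag)
  cb <- matrix(0, nrow = n, ncol = ne * nl)
  for (l in 0:L) {
    rows <- (l + 1):n
    El <- E[rows - l, , drop = FALSE]
    # accumulate B_e_i(T[t-l]) * B_lag_j(l) into the (i,j) columns
    for (j in seq_len(nl)) {
      cols <- (seq_len(ne) - 1L) * nl + j
      cb[rows, cols] <- cb[rows, cols] + El * Blag[l + 1, j]
    }
  }
  usable <- c(rep(FALSE, L), rep(TRUE, n - L))
  cb[!usable, ] <- NA_real_
  colnames(cb) <- crossbasis_colnames(spec)
  structure(cb, spec = spec, usable = usable, class = c("crossbasis", "matrix"))
}
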