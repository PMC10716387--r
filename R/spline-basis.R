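#' Natural cubic spline specification
#'
#' Knot layout for a restricted (natural) cubic spline basis: linear beyond
#' the boundary knots, continuous second derivative, and zero second
#' derivative at the boundaries. Basis dimension is
#' `length(internal_knots) + 1`, plus one if `with_intercept`.
#'
#' @param internal_knots Strictly increasing knots strictly inside the
#'   boundary interval; may be empty.
#' @param boundary_knots Length-2 increasing vector.
#' @param with_intercept Should the basis span constants? The exposure
#'   dimension of a cross-basis uses `FALSE` (so the curve is identified
#'   relative to a reference temperature); the lag dimension uses `TRUE`.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(internal_knots, boundary_knots,
                        with_intercept = FALSE) {
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  assert_that(length(boundary_knots) == 2L &&
                all(is.finite(boundary_knots)) &&
                boundary_knots[1] < boundary_knots[2],
              "`boundary_knots` must be two increasing finite numbers.")
  if (length(internal_knots)) {
    assert_that(all(is.finite(internal_knots)) &&
                  !is.unsorted(internal_knots, strictly = TRUE),
                "`internal_knots` must be finite and strictly increasing.")
    assert_that(all(internal_knots > boundary_knots[1]) &&
                  all(internal_knots < boundary_knots[2]),
                "`internal_knots` must lie strictly inside the boundary knots.")
  }
  structure(list(internal_knots = internal_knots,
                 boundary_knots = boundary_knots,
                 with_intercept = isTRUE(with_intercept)),
            class = "spline_spec")
}

spline_dim <- function(spec) {
  length(spec$internal_knots) + 1L + as.integer(spec$with_intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Thin wrapper around [splines::ns()] pinned to a [spline_spec()], so the
#' same basis can be rebuilt exactly at prediction time.
#'
#' @param x Numeric vector (all values must be finite); values beyond the
#'   boundary knots are evaluated on the natural linear extension.
#' @param spec A [spline_spec()].
#' @return A numeric matrix with `length(x)` rows and [spline_spec()]
#'   dimension columns.
#' @export
ns_basis <- function(x, spec) {
  assert_that(inherits(spec, "spline_spec"),
              "`spec` must be a `spline_spec`.")
  assert_that(is.numeric(x) && all(is.finite(x)),
              "`x` must be numeric with no non-finite values.")
  b <- splines::ns(x,
                   knots = if (length(spec$internal_knots)) spec$internal_knots,
                   Boundary.knots = spec$boundary_knots,
                   intercept = spec$with_intercept)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Lag knots equally spaced on the log scale
#'
#' Returns `n_knots` values whose logarithms are equally spaced strictly
#' between `log(1)` and `log(max_lag)`; the standard placement for the lag
#' dimension of a distributed-lag basis (lag 0 cannot sit on a log grid).
#'
#' @param max_lag Maximum lag in days (>= 1).
#' @param n_knots Number of internal knots (>= 1).
#' @return Numeric vector of knots in lag units (days).
#' @examples
#' lag_knots_log(14, 3)
#' @export
lag_knots_log <- function(max_lag, n_knots = 3L) {
  assert_scalar_number(max_lag, "max_lag", lower = 1)
  assert_that(is.numeric(n_knots) && length(n_knots) == 1L && n_knots >= 1,
              "`n_knots` must be an integer >= 1.")
  lg <- seq(0, log(max_lag), length.out = n_knots + 2L)
  exp(lg[-c(1L, n_knots + 2L)])
}
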