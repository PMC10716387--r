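#' Build the day-level design table for the case-crossover fit
#'
#' Evaluates, for every day of the weather series, the temperature
#' cross-basis (lags `0..max_lag`), the holiday indicator, and a natural
#' cubic spline of relative humidity with `humidity_df` degrees of freedom.
#' Column layout is fixed: cross-basis block (`cb_*`), `holiday`, humidity
#' block (`rh_*`). Days without a complete lag history are flagged
#' `usable = FALSE`.
#'
#' @param weather Daily weather tibble with `date`, `temp_c`, `rh_pct`,
#'   `holiday`.
#' @param spec A [crossbasis_spec()]; defaults to
#'   [default_crossbasis_spec()] on the observed temperatures.
#' @param humidity_df Degrees of freedom of the humidity spline (internal
#'   knots at equally spaced quantiles, as in [splines::ns()]).
#' @return A tibble (class `cc_design`) with columns `date`, `usable`, the
#'   covariate columns, and the cross-basis spec in attribute `spec`.
#' @export
build_design <- function(weather, spec = NULL, humidity_df = 3L) {
  dates <- check_daily_series(weather)
  assert_that(all(c("rh_pct", "holiday") %in% names(weather)),
              "`weather` must have `rh_pct` and `holiday` columns.")
  spec <- spec %||% default_crossbasis_spec(weather$temp_c)
  cb <- build_crossbasis(weather$temp_c, spec)

  rh <- weather$rh_pct
  assert_that(all(is.finite(rh)), "`rh_pct` contains non-finite values.")
  rh_basis <- splines::ns(rh, df = humidity_df)
  rh_m <- matrix(as.numeric(rh_basis), nrow = length(rh))
  colnames(rh_m) <- paste0("rh_", seq_len(ncol(rh_m)))

  out <- tibble::tibble(date = dates, usable = attr(cb, "usable"))
  out <- dplyr::bind_cols(out, tibble::as_tibble(unclass(cb)),
                          holiday = as.numeric(weather$holiday),
                          tibble::as_tibble(rh_m))
  attr(out, "spec") <- spec
  class(out) <- c("cc_design", class(out))
  out
}

design_covariate_names <- function(design) {
  setdiff(names(design), c("date", "usable"))
}
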