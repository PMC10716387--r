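# Internal validation helpers shared across modules.

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, call = NULL)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  assert_that(ok, sprintf("`%s` must be a finite number in %s%s, %s%s.",
                          name,
                          if (strict_lower) "(" else "[", format(lower),
                          format(upper), if (strict_upper) ")" else "]"))
}

as_date_scalar <- function(x, name) {
  out <- tryCatch(lubridate::as_date(x), warning = function(w) NA)
  assert_that(length(out) == 1L && !is.na(out),
              sprintf("`%s` must be a single parseable date.", name))
  out
}

#' @keywords internal
check_daily_series <- function(weather, arg = "weather") {
  assert_that(is.data.frame(weather) &&
                all(c("date", "temp_c") %in% names(weather)),
              sprintf("`%s` must be a data frame with columns `date` and `temp_c`.", arg))
  assert_that(all(is.finite(weather$temp_c)),
              sprintf("`%s$temp_c` contains non-finite values.", arg))
  d <- lubridate::as_date(weather$date)
  assert_that(!anyNA(d), sprintf("`%s$date` contains unparseable dates.", arg))
  assert_that(!anyDuplicated(d) && all(diff(as.integer(d)) == 1L),
              sprintf("`%s` must cover consecutive calendar days without gaps or duplicates.", arg))
  invisible(d)
}

# Percentiles throughout the package use linear interpolation between order
# statistics (stats::quantile type 7) so knot locations are bit-reproducible.
pctl <- function(x, p) unname(quantile(x, probs = p, type = 7, names = FALSE))

decade_label <- function(year) paste0(year - year %% 10L, "s")

decade_start <- function(label) {
  assert_that(all(grepl("^[0-9]{4}s$", label)),
              "Decade labels must look like \"2090s\".")
  as.integer(sub("s$", "", label))
}
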