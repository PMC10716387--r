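#' Build time-stratified case-crossover strata
#'
#' One stratum per death record. Control days are all other dates in the
#' same calendar month and year sharing the case day's day of week, so each
#' stratum has 3 or 4 controls and seasonality and day-of-week patterns are
#' removed by design.
#'
#' @param deaths Either a death-record tibble with a `date` column (one
#'   stratum per row) or a vector of death dates.
#' @return A long tibble with columns `stratum` (integer, one per death),
#'   `date` and `is_case`; case rows carry the death date.
#' @examples
#' build_strata(as.Date(c("2015-07-15", "2015-07-15", "2015-12-01")))
#' @export
build_strata <- function(deaths) {
  dates <- if (is.data.frame(deaths)) {
    assert_that("date" %in% names(deaths), "`deaths` must have a `date` column.")
    deaths$date
  } else deaths
  dates <- lubridate::as_date(dates)
  assert_that(!anyNA(dates), "Death dates must all be parseable.")
  if (length(dates) == 0L) {
    return(tibble::tibble(stratum = integer(), date = lubridate::as_date(character()),
                          is_case = logical()))
  }

  # referent sets depend only on the case date; compute one per unique date
  uniq <- unique(dates)
  ref_sets <- lapply(uniq, function(d) {
    month_days <- seq(lubridate::floor_date(d, "month"),
                      lubridate::ceiling_date(d, "month") - 1, by = "day")
    month_days[lubridate::wday(month_days) == lubridate::wday(d)]
  })
  idx <- match(dates, uniq)
  nref <- lengths(ref_sets)[idx]
  ref_dates <- lubridate::as_date(unlist(ref_sets[idx], use.names = FALSE))
  tibble::tibble(stratum = rep(seq_along(dates), nref),
                 date = ref_dates,
                 is_case = ref_dates == rep(dates, nref))
}
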