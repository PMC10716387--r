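# ggplot2 displays for the main result types.

#' Plot an overall cumulative exposure-response curve
#'
#' Relative risk versus temperature with its 95% confidence band, a
#' dashed reference line at RR = 1 and a vertical line at the
#' minimum-mortality temperature.
#'
#' @param object A `reduced_curve` with `mmt` set.
#' @param n Grid points across the display range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reduced_curve
#' @export
autoplot.reduced_curve <- function(object, n = 200L, ...) {
  df <- tidy(object, n = n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mmt, linetype = "dotted") +
    ggplot2::labs(x = "Daily mean temperature (°C)",
                  y = "Cumulative relative risk (lag 0-14)") +
    ggplot2::theme_minimal()
}

#' Plot a lag-response curve
#'
#' @param lag_tab Tibble from [lag_response_at()].
#' @return A ggplot object.
#' @export
plot_lag_response <- function(lag_tab) {
  ggplot2::ggplot(lag_tab, ggplot2::aes(x = .data$lag, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Lag (days)", y = "Relative risk") +
    ggplot2::theme_minimal()
}

#' Plot projected attributable fractions by decade
#'
#' Heat and cold attributable fractions per decade and scenario, with
#' empirical confidence bands.
#'
#' @param object A `burden_projection`.
#' @param what `"burden"` (absolute AFs) or `"differences"` (change vs the
#'   historical baseline).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_projection
#' @export
autoplot.burden_projection <- function(object,
                                       what = c("burden", "differences"),
                                       ...) {
  what <- match.arg(what)
  df <- object[[what]]
  ycol <- if (what == "burden") "af_pct" else "d_af_pct"
  df <- df[df$component != if (what == "burden") "total" else "net", ]
  df$decade_num <- decade_start(df$decade)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decade_num,
                                   y = .data[[ycol]],
                                   colour = .data$component,
                                   fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$af_eci_low,
                                      ymax = .data$af_eci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Decade",
                  y = if (what == "burden") "Attributable fraction (%)"
                      else "Change in attributable fraction (%)") +
    ggplot2::theme_minimal()
}
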