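#' Plot the distribution of site-specific trends
#'
#' Histogram of site slopes per nutrient with the median marked; the
#' standard view of how deepening and shoaling sites balance.
#'
#' @param object A `nutricline_trends` tibble from [fit_site_trends()].
#' @param binwidth Histogram bin width, m/y.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nutricline_trends <- function(object, binwidth = 0.25, ...) {
  med <- object |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(median = median(.data$slope))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$median),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$nutrient), ncol = 1) +
    ggplot2::labs(x = "site trend (m y⁻¹)", y = "sites")
}

#' Plot a scrambled-year null distribution
#'
#' Null medians as a histogram with the observed median overlaid; the
#' empirical p-value is the two-sided tail mass beyond the observed value.
#'
#' @param object An `mtorp` object from [scramble_years()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtorp <- function(object, ...) {
  d <- tibble::tibble(median = object$medians)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_median,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "null median trend (m y⁻¹)", y = "randomizations",
      title = sprintf("MToRP null: observed median %.3f, p = %.3g",
                      object$observed_median, object$p_value)
    )
}

#' Plot a bootstrap median distribution
#'
#' @param object A `median_trend_summary`.
#' @param ... Unused.
#' @return A ggplot of the bootstrap medians with the point estimate and
#'   CI bounds.
#' @export
autoplot.median_trend_summary <- function(object, ...) {
  d <- tibble::tibble(median = object$boot_medians)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$median, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap median trend (m y⁻¹)",
                  y = "resamples")
}

#' Plot the annual series for one site
#'
#' Annual mean depths against year with the OLS fit, depth axis reversed
#' (deeper is down).
#'
#' @param series Site-annual series tibble.
#' @param lat_bin,lon_bin Site to plot.
#' @return A ggplot.
#' @export
plot_site_series <- function(series, lat_bin, lon_bin) {
  d <- series[series$lat_bin == lat_bin & series$lon_bin == lon_bin, ]
  if (nrow(d) == 0) abort("no annual points for that site")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$mean_depth,
                                  colour = .data$nutrient)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "year", y = "annual mean nutricline depth (m)",
                  title = sprintf("site (%d, %d)", lat_bin, lon_bin))
}
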