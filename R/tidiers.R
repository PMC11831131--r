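#' Tidy a median-trend summary
#'
#' @param x A `median_trend_summary` from [median_with_bootstrap_ci()].
#' @param ... Unused.
#' @return One-row tibble: `median`, `ci_low`, `ci_high`, `n_sites`,
#'   `n_bootstrap`, `seed`.
#' @export
tidy.median_trend_summary <- function(x, ...) {
  tibble::tibble(median = x$median, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_sites = x$n_sites, n_bootstrap = x$n_bootstrap,
                 seed = x$seed)
}

#' @rdname tidy.median_trend_summary
#' @export
glance.median_trend_summary <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, n_bootstrap = x$n_bootstrap,
                 conf = x$conf, ci_width = x$ci_high - x$ci_low)
}

#' Tidy a scrambled-year null distribution
#'
#' @param x An `mtorp` object from [scramble_years()].
#' @param ... Unused.
#' @return One-row tibble with the observed median, the empirical p-value,
#'   and null-distribution quantiles.
#' @export
tidy.mtorp <- function(x, ...) {
  q <- quantile(x$medians, c(0.025, 0.5, 0.975))
  tibble::tibble(
    observed_median = x$observed_median, p_value = x$p_value,
    null_q025 = unname(q[1]), null_median = unname(q[2]),
    null_q975 = unname(q[3]),
    n_randomizations = x$n_randomizations, scope = x$scope
  )
}

#' @rdname tidy.mtorp
#' @export
glance.mtorp <- function(x, ...) {
  tibble::tibble(n_randomizations = x$n_randomizations, scope = x$scope,
                 p_floor = 1 / (x$n_randomizations + 1))
}

#' Tidy climatology-sampling simulations
#'
#' @param x A `clim_sim` from [simulate_climatology_sampling()].
#' @param ... Unused.
#' @return One row per nutrient summarising the distribution of
#'   per-population median trends and trend IQRs, with Monte-Carlo
#'   standard errors.
#' @export
tidy.clim_sim <- function(x, ...) {
  x$populations |>
    dplyr::filter(!is.na(.data$median_trend)) |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(
      mean_median = mean(.data$median_trend),
      se_median = sd(.data$median_trend) / sqrt(dplyr::n()),
      mean_iqr = mean(.data$iqr_trend),
      mean_var = mean(.data$var_trend),
      n_populations = dplyr::n()
    )
}
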