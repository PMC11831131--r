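#' Map coordinates to 1-degree sites
#'
#' Rounds each coordinate to the nearest integer degree, half away from
#' zero, after normalising longitudes to \[-180, 180). A rounded longitude
#' of 180 wraps to -180, so every valid coordinate maps to exactly one site
#' with `lat_bin` in \[-90, 90\] and `lon_bin` in \[-180, 179\].
#'
#' @param latitude,longitude Numeric vectors of decimal degrees; latitude
#'   must lie in \[-90, 90\].
#' @return A tibble with integer columns `lat_bin`, `lon_bin`.
#' @examples
#' assign_site(33.4, -120.6)   # (33, -121)
#' assign_site(-0.5, 179.7)    # (-1, -180)
#' @export
assign_site <- function(latitude, longitude) {
  if (any(is.na(latitude) | is.na(longitude))) {
    abort("missing coordinates")
  }
  if (any(latitude < -90 | latitude > 90)) {
    abort("latitude outside [-90, 90]")
  }
  lon <- ((longitude + 180) %% 360) - 180
  lat_bin <- round_half_away(latitude)
  lon_bin <- round_half_away(lon)
  lon_bin[lon_bin >= 180] <- -180
  tibble::tibble(lat_bin = as.integer(lat_bin), lon_bin = as.integer(lon_bin))
}

#' Annually averaged nutricline depths per site
#'
#' Assigns each record to its 1-degree site and averages the defined
#' crossing depths per (site, nutrient, calendar year). Records without a
#' defined depth (status `never_reached` or `insufficient_data`) are
#' excluded before averaging. If the records carry a `depth_raw_m` column
#' (produced by [seasonal_anomaly()]), its annual mean is carried along as
#' `mean_depth_raw` so that eligibility filters can act on uncorrected
#' depths; otherwise `mean_depth_raw` equals `mean_depth`. A `sigma` column,
#' if present, is averaged into `mean_sigma`.
#'
#' @param records Nutricline record tibble.
#' @return A site-annual series tibble: `lat_bin`, `lon_bin`, `nutrient`,
#'   `year`, `mean_depth`, `mean_depth_raw`, `n_casts` (plus `mean_sigma`,
#'   `spec_id` where applicable), sorted by site and year.
#' @export
annual_average <- function(records) {
  x <- records |>
    dplyr::filter(.data$status %in% c("crossed", "surface_saturated"),
                  !is.na(.data$depth_m))
  if (!"depth_raw_m" %in% names(x)) x$depth_raw_m <- x$depth_m
  x <- dplyr::bind_cols(x, assign_site(x$latitude, x$longitude))
  grp <- c("lat_bin", "lon_bin", "nutrient", "year",
           intersect("spec_id", names(x)))
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_depth = mean(.data$depth_m),
      mean_depth_raw = mean(.data$depth_raw_m),
      mean_sigma = if ("sigma" %in% names(x)) {
        mean(.data$sigma, na.rm = TRUE)
      } else NA_real_,
      n_casts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lat_bin, .data$lon_bin, .data$nutrient, .data$year)
  out$mean_sigma[is.nan(out$mean_sigma)] <- NA_real_
  out
}

#' Trend-eligibility filter for site-annual series
#'
#' Keeps only annual points strictly deeper than `min_depth` metres and only
#' sites whose latitude lies within `lat_range` (inclusive): the defaults
#' restrict trends to nutricline depths deeper than 50 m between 45S and
#' 45N, confining the analysis to nutrient-limited waters and damping mixed
#' layer variability. The depth cut acts on `mean_depth_raw`, so
#' seasonal-anomaly series are filtered on their uncorrected depths.
#' Raising `min_depth` can only shrink the retained set.
#'
#' @param series Site-annual series tibble from [annual_average()].
#' @param min_depth Strict lower bound on annual mean depth, m.
#' @param lat_range Length-2 inclusive latitude range, degrees.
#' @return Filtered series tibble.
#' @export
filter_trend_eligible <- function(series, min_depth = 50,
                                  lat_range = c(-45, 45)) {
  series |>
    dplyr::filter(
      .data$mean_depth_raw > min_depth,
      .data$lat_bin >= lat_range[1], .data$lat_bin <= lat_range[2]
    )
}
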