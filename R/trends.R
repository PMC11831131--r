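#' Global regression of annual nutricline depth on year
#'
#' Pools all eligible annual points across sites, per nutrient, and fits
#' ordinary least squares of mean depth on calendar year (centred at its
#' mean, which changes the intercept's meaning but not the slope). The
#' p-value is the two-sided t-test on the slope.
#'
#' @param series Site-annual series tibble (already filtered with
#'   [filter_trend_eligible()]).
#' @return One row per nutrient: `nutrient`, `slope` (m/y), `slope_se`,
#'   `p_value`, `intercept` (depth at the mean year), `n_points`.
#' @export
fit_global_regression <- function(series) {
  series |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        abort(paste0("fewer than 3 annual points for ", key$nutrient))
      }
      fit <- lm(mean_depth ~ I(year - mean(year)), data = d)
      sm <- suppressWarnings(summary(fit))  # degenerate fits warn
      s <- sm$coefficients
      pv <- s[2, 4]
      # perfect fits have (numerically) zero residual variance; the t-test
      # degenerates there
      scale <- abs(mean(d$mean_depth)) + 1
      if (!is.finite(pv) || sm$sigma < 1e-8 * scale) {
        pv <- if (abs(s[2, 1]) < 1e-8 * scale) 1 else 0
      }
      tibble::tibble(
        slope = s[2, 1], slope_se = s[2, 2], p_value = pv,
        intercept = s[1, 1], n_points = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Site-specific nutricline depth trends
#'
#' For every site with annual means in two or more distinct years, fits OLS
#' of annual mean depth on year and returns the slope in m/y. Sites with a
#' single year are skipped; their count is attached as attribute
#' `n_skipped`. The value column fitted is `mean_depth` by default; pass
#' `value = "mean_sigma"` to fit density-at-nutricline trends instead.
#'
#' @param series Site-annual series tibble.
#' @param value Name of the column to regress on year.
#' @param quantity Label for the fitted quantity, recorded in the result
#'   (defaults to the nutrient's depth trend).
#' @return A `nutricline_trends` tibble: `lat_bin`, `lon_bin`, `nutrient`,
#'   `quantity`, `slope`, `intercept`, `n_years`.
#' @export
fit_site_trends <- function(series, value = "mean_depth", quantity = "depth") {
  x <- series[!is.na(series[[value]]), ]
  gcols <- c("lat_bin", "lon_bin", "nutrient", intersect("spec_id", names(x)))
  x$.g <- do.call(paste, c(unname(x[gcols]), sep = "/"))
  g <- match(x$.g, unique(x$.g))
  x <- x[order(g), ]; g <- sort(g)
  fit <- group_ols(g, x$year - mean(x$year), x[[value]])
  keep_rows <- !duplicated(g)
  out <- x[keep_rows, gcols]
  out$quantity <- quantity
  out$slope <- fit$slope
  out$intercept <- fit$intercept
  ny <- tapply(x$year, g, function(y) length(unique(y)))
  out$n_years <- as.integer(ny)
  n_skipped <- sum(is.na(out$slope))
  out <- out[!is.na(out$slope), ]
  out <- tibble::as_tibble(out)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("nutricline_trends", class(out))
  out
}

#' Median trend with percentile bootstrap confidence interval
#'
#' The central summary statistic of the analysis: the median of the
#' site-specific slopes, with a 95% CI obtained from the 2.5th and 97.5th
#' percentiles of medians over `n_bootstrap` resamples of sites drawn with
#' replacement (the site is the exchangeable unit). Reproducible given
#' `seed`.
#'
#' @param trends A `nutricline_trends` tibble (or numeric vector of slopes).
#' @param n_bootstrap Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A `median_trend_summary` object; see [tidy()] for a one-row
#'   tibble view.
#' @export
median_with_bootstrap_ci <- function(trends, n_bootstrap = 10000,
                                     seed = 1L, conf = 0.95) {
  slopes <- if (is.numeric(trends)) trends else trends$slope
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 2) abort("need at least 2 site trends")
  n <- length(slopes)
  boot <- with_seed(seed, {
    m <- matrix(sample(slopes, n * n_bootstrap, replace = TRUE),
                nrow = n, ncol = n_bootstrap)
    apply(m, 2, median)
  })
  a <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(a, 1 - a), type = 7))
  structure(
    list(median = median(slopes), ci_low = ci[1], ci_high = ci[2],
         n_sites = n, n_bootstrap = n_bootstrap, seed = seed, conf = conf,
         boot_medians = boot),
    class = "median_trend_summary"
  )
}

#' @export
print.median_trend_summary <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Median trend %.*g  [%.*g, %.*g] (%d%% bootstrap CI, %d resamples, n = %d sites)\n",
    digits, x$median, digits, x$ci_low, digits, x$ci_high,
    round(100 * x$conf), x$n_bootstrap, x$n_sites
  ))
  invisible(x)
}

#' Seasonal-anomaly correction of nutricline records
#'
#' Replaces each record's depth by its anomaly relative to the monthly
#' climatological nutricline depth at the record's site and month, removing
#' the seasonal cycle that irregular sampling would otherwise alias into
#' trends. The uncorrected depth is kept as `depth_raw_m`, and downstream
#' eligibility filtering acts on it (an anomaly near zero is not a shallow
#' nutricline). Records at site-months absent from the climatology are
#' dropped; their count is attached as attribute `n_dropped`.
#'
#' @param records Nutricline record tibble.
#' @param clim A `monthly_climatology` with nutricline depths.
#' @return Records with `depth_m` holding anomalies (m) and `depth_raw_m`
#'   the raw depths.
#' @export
seasonal_anomaly <- function(records, clim) {
  site <- assign_site(records$latitude, records$longitude)
  cd <- clim_lookup(clim, site$lat_bin, site$lon_bin,
                    records$month, records$nutrient)
  defined <- records$status %in% c("crossed", "surface_saturated")
  keep <- !defined | !is.na(cd)
  out <- records[keep, ]
  out$depth_raw_m <- out$depth_m
  out$depth_m <- out$depth_m - cd[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Paired nitracline-minus-phosphacline residual trends
#'
#' For every cast where both the nitracline and the phosphacline are
#' defined, forms the difference Z_NO3 - Z_PO4, averages it annually per
#' site, and fits site trends of the difference. A negative median trend of
#' this paired residual means the phosphacline is deepening faster than the
#' nitracline within the same casts, which controls for sampling
#' differences between the two nutrients. Eligibility requires both annual
#' mean depths to pass the `min_depth` cut and the site to lie within
#' `lat_range`.
#'
#' @param records Nutricline record tibble holding both nutrients at one
#'   threshold spec.
#' @param min_depth,lat_range As in [filter_trend_eligible()].
#' @return A `nutricline_trends` tibble with `quantity = "ZNO3_minus_ZPO4"`.
#' @export
paired_residual_trend <- function(records, min_depth = 50,
                                  lat_range = c(-45, 45)) {
  if ("spec_id" %in% names(records) &&
      length(unique(records$spec_id)) > 1) {
    abort("records mix several threshold specs; filter to one spec_id first")
  }
  wide <- records |>
    dplyr::filter(.data$status %in% c("crossed", "surface_saturated")) |>
    dplyr::select("cast_id", "nutrient", "depth_m", "latitude", "longitude",
                  "year") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "depth_m") |>
    dplyr::filter(!is.na(.data$nitrate), !is.na(.data$phosphate))
  wide <- dplyr::bind_cols(wide,
                           assign_site(wide$latitude, wide$longitude))
  ann <- wide |>
    dplyr::group_by(.data$lat_bin, .data$lon_bin, .data$year) |>
    dplyr::summarise(
      mean_diff = mean(.data$nitrate - .data$phosphate),
      mean_no3 = mean(.data$nitrate),
      mean_po4 = mean(.data$phosphate),
      n_casts = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(
      .data$mean_no3 > min_depth, .data$mean_po4 > min_depth,
      .data$lat_bin >= lat_range[1], .data$lat_bin <= lat_range[2]
    ) |>
    dplyr::mutate(nutrient = "paired", mean_depth = .data$mean_diff,
                  mean_depth_raw = .data$mean_diff)
  fit_site_trends(ann, quantity = "ZNO3_minus_ZPO4")
}

#' Residual phosphacline trend relative to the 1:1 line
#'
#' Measures how much faster the phosphacline deepens than the nitracline as
#' the signed orthogonal distance of the point (T_NO3, T_PO4) from the line
#' T_PO4 = T_NO3: (T_PO4 - T_NO3)/sqrt(2), positive when the phosphacline
#' deepens faster. Antisymmetric in its arguments and zero on the line.
#'
#' @param t_no3,t_po4 Nitracline and phosphacline depth trends, m/y
#'   (vectorised).
#' @return Signed orthogonal distance, m/y.
#' @examples
#' residual_tpo4(0, 1)  # 1/sqrt(2)
#' @export
residual_tpo4 <- function(t_no3, t_po4) {
  stopifnot(is.finite(t_no3), is.finite(t_po4))
  (t_po4 - t_no3) / sqrt(2)
}

#' Exact sign test on site trends
#'
#' Two-sided exact binomial test of whether positive and negative slopes are
#' equally likely; zero slopes are dropped. A nonparametric check that the
#' median trend differs from zero.
#'
#' @param trends `nutricline_trends` tibble or numeric slopes.
#' @return One-row tibble: `p_value`, `n_positive`, `n_negative`, `n_zero`.
#'   `p_value` is `NA` when every slope is zero.
#' @export
sign_test <- function(trends) {
  slopes <- if (is.numeric(trends)) trends else trends$slope
  slopes <- slopes[!is.na(slopes)]
  n_pos <- sum(slopes > 0); n_neg <- sum(slopes < 0)
  n_zero <- sum(slopes == 0)
  p <- if (n_pos + n_neg == 0) {
    warn("all slopes are zero; sign test undefined")
    NA_real_
  } else {
    binom.test(n_pos, n_pos + n_neg, p = 0.5)$p.value
  }
  tibble::tibble(p_value = p, n_positive = n_pos, n_negative = n_neg,
                 n_zero = n_zero)
}

#' Kruskal-Wallis rank test between groups of trends
#'
#' Tie-corrected rank-based H statistic with a chi-squared p-value,
#' comparing two or more groups of site slopes (e.g. the nitracline vs the
#' phosphacline trend populations).
#'
#' @param groups A named list of numeric slope vectors, each of length >= 2.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) {
    abort("every group needs at least 2 values")
  }
  kt <- kruskal.test(groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Median trends of density at the nutricline
#'
#' Runs the standard aggregation/trend/median machinery on the potential
#' density at each record's crossing depth instead of the depth itself. If
#' nutriclines track fixed density surfaces these trends are zero; nonzero
#' values mean the nutricline is migrating across isopycnals, implicating
#' biology rather than physics. Records must carry a `sigma` column (see
#' [add_density_at_nutricline()]); eligibility still uses the raw depth.
#'
#' @param records Nutricline record tibble with `sigma`.
#' @param min_depth,lat_range As in [filter_trend_eligible()].
#' @param n_bootstrap,seed Bootstrap settings for the median CI.
#' @return One row per nutrient: median density trend (kg m^-3 y^-1) with
#'   CI; attribute `trends` holds the per-site slopes and attribute
#'   `n_missing_sigma` the records without density. Zero rows when no
#'   density could be computed.
#' @export
density_trends <- function(records, min_depth = 50, lat_range = c(-45, 45),
                           n_bootstrap = 10000, seed = 1L) {
  if (!"sigma" %in% names(records)) abort("records carry no 'sigma' column")
  n_missing <- sum(is.na(records$sigma))
  ann <- annual_average(records) |>
    filter_trend_eligible(min_depth = min_depth, lat_range = lat_range)
  ann <- ann[!is.na(ann$mean_sigma), ]
  tr <- if (nrow(ann) > 0) {
    fit_site_trends(ann, value = "mean_sigma", quantity = "density_at_Z")
  } else {
    tibble::tibble(nutrient = character(), slope = double())
  }
  if (nrow(tr) == 0) {
    out <- tibble::tibble(nutrient = character(), median = double(),
                          ci_low = double(), ci_high = double(),
                          n_sites = integer())
    attr(out, "trends") <- tr
    attr(out, "n_missing_sigma") <- n_missing
    return(out)
  }
  out <- tr |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        return(tibble::tibble(median = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, n_sites = nrow(d)))
      }
      s <- median_with_bootstrap_ci(d$slope, n_bootstrap = n_bootstrap,
                                    seed = seed)
      tibble::tibble(median = s$median, ci_low = s$ci_low,
                     ci_high = s$ci_high, n_sites = s$n_sites)
    }) |>
    dplyr::ungroup()
  attr(out, "trends") <- tr
  attr(out, "n_missing_sigma") <- n_missing
  out
}

#' Region specifications for regional median trends
#'
#' A region is a named union of latitude/longitude boxes (one row per box;
#' several rows may share a `region` name, e.g. a basin spanning the
#' dateline). `regions_hemispheres()` returns the southern/northern split
#' within the 45S-45N analysis band.
#'
#' @param region Character vector of region names.
#' @param lat_min,lat_max,lon_min,lon_max Box edges, degrees (inclusive).
#' @return A tibble of boxes.
#' @export
region_spec <- function(region, lat_min, lat_max, lon_min = -180,
                        lon_max = 179) {
  out <- tibble::tibble(region = region, lat_min = lat_min,
                        lat_max = lat_max, lon_min = lon_min,
                        lon_max = lon_max)
  if (any(out$lat_min > out$lat_max) || any(out$lon_min > out$lon_max)) {
    abort("empty region box")
  }
  out
}

#' @rdname region_spec
#' @export
regions_hemispheres <- function() {
  region_spec(c("southern", "northern"), lat_min = c(-45, 0),
              lat_max = c(-1, 45))
}

#' Regional median trends
#'
#' Bootstrap median trend per region. Regions with fewer than 2 member
#' sites are flagged `insufficient` and carry no median.
#'
#' @param trends `nutricline_trends` tibble.
#' @param regions Region boxes from [region_spec()].
#' @param n_bootstrap,seed Bootstrap settings.
#' @return Tibble: one row per (region, nutrient) with `median`, `ci_low`,
#'   `ci_high`, `n_sites`, `insufficient`.
#' @export
regional_medians <- function(trends, regions, n_bootstrap = 10000,
                             seed = 1L) {
  purrr::map(unique(regions$region), function(rg) {
    boxes <- regions[regions$region == rg, ]
    inside <- purrr::reduce(
      purrr::pmap(boxes, function(region, lat_min, lat_max, lon_min, lon_max) {
        trends$lat_bin >= lat_min & trends$lat_bin <= lat_max &
          trends$lon_bin >= lon_min & trends$lon_bin <= lon_max
      }),
      `|`
    )
    trends[inside, ] |>
      dplyr::group_by(.data$nutrient) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 2) {
          return(tibble::tibble(median = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_, n_sites = nrow(d),
                                insufficient = TRUE))
        }
        s <- median_with_bootstrap_ci(d$slope, n_bootstrap = n_bootstrap,
                                      seed = seed)
        tibble::tibble(median = s$median, ci_low = s$ci_low,
                       ci_high = s$ci_high, n_sites = s$n_sites,
                       insufficient = FALSE)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(region = rg, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Drop physically infeasible extreme trends
#'
#' Removes site trends outside a feasibility interval (what long
#' time-series suggest nutricline depths can actually do); the number
#' removed is attached as attribute `n_removed`. The median is robust to
#' symmetric trimming, so this is a robustness check rather than a
#' correction.
#'
#' @param trends `nutricline_trends` tibble.
#' @param bounds Length-2 interval in m/y (closed).
#' @return Filtered trends with attribute `n_removed`.
#' @export
filter_extreme_trends <- function(trends, bounds = c(-Inf, Inf)) {
  stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  keep <- trends$slope >= bounds[1] & trends$slope <= bounds[2]
  out <- trends[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(trends)
  out
}

#' Deep-water concentration-bias diagnostic
#'
#' If analytical methods drifted over the decades, apparent nutricline
#' trends could be measurement artifacts. Below ~1000 m, concentrations
#' should be climatologically stable, so the trend of (observed minus
#' climatological) concentration there should be zero. Observed profiles
#' are interpolated to the climatology's standard depths below `min_depth`,
#' the climatological concentration at the same (site, month, depth) is
#' subtracted, and the pooled anomalies are regressed on year per nutrient.
#'
#' @param casts Bottle tibble.
#' @param clim A `monthly_climatology` with concentration profiles.
#' @param min_depth Only standard depths strictly below this are used, m.
#' @return One row per nutrient: `slope` (umol kg^-1 y^-1), `slope_se`,
#'   `p_value`, `n_anomalies`. Zero rows if no cast reaches below
#'   `min_depth`.
#' @export
deep_anomaly_trend <- function(casts, clim, min_depth = 1000) {
  if (is.null(clim$profiles)) abort("climatology has no concentration profiles")
  site <- assign_site(casts$latitude, casts$longitude)
  x <- dplyr::bind_cols(casts, site) |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  month = as.integer(format(.data$date, "%m")))
  prof <- clim$profiles |> dplyr::filter(.data$depth_m > min_depth)
  if (nrow(prof) == 0) return(empty_deep_result())
  std_depths <- sort(unique(prof$depth_m))

  anoms <- purrr::map(c("nitrate", "phosphate"), function(nu) {
    col <- nutrient_column(nu)
    obs <- x[!is.na(x[[col]]), c("cast_id", "lat_bin", "lon_bin", "year",
                                 "month", "depth_m", col)]
    names(obs)[7] <- "conc"
    deep_ids <- unique(obs$cast_id[obs$depth_m > min_depth])
    obs <- obs[obs$cast_id %in% deep_ids, ]
    if (nrow(obs) == 0) return(NULL)
    interp <- obs |>
      dplyr::group_by(.data$cast_id) |>
      dplyr::group_modify(function(d, key) {
        zin <- std_depths[std_depths >= min(d$depth_m) &
                            std_depths <= max(d$depth_m)]
        if (length(zin) == 0 || nrow(d) < 2) return(tibble::tibble())
        tibble::tibble(
          lat_bin = d$lat_bin[1], lon_bin = d$lon_bin[1],
          year = d$year[1], month = d$month[1], depth_m = zin,
          conc = approx(d$depth_m, d$conc, xout = zin, ties = mean)$y
        )
      }) |>
      dplyr::ungroup()
    if (nrow(interp) == 0) return(NULL)
    interp |>
      dplyr::mutate(nutrient = nu) |>
      dplyr::inner_join(
        prof |> dplyr::filter(.data$nutrient == nu),
        by = c("lat_bin", "lon_bin", "month", "nutrient", "depth_m")
      ) |>
      dplyr::mutate(anomaly = .data$conc - .data$concentration)
  }) |>
    purrr::list_rbind()

  if (is.null(anoms) || nrow(anoms) == 0) return(empty_deep_result())
  anoms |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || length(unique(d$year)) < 2) {
        return(tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                              p_value = NA_real_, n_anomalies = nrow(d)))
      }
      fit <- lm(anomaly ~ I(year - mean(year)), data = d)
      s <- suppressWarnings(summary(fit))$coefficients
      pv <- s[2, 4]
      if (!is.finite(pv)) pv <- if (abs(s[2, 1]) < 1e-12) 1 else 0
      tibble::tibble(slope = s[2, 1], slope_se = s[2, 2], p_value = pv,
                     n_anomalies = nrow(d))
    }) |>
    dplyr::ungroup()
}

empty_deep_result <- function() {
  tibble::tibble(nutrient = character(), slope = double(),
                 slope_se = double(), p_value = double(),
                 n_anomalies = integer())
}
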