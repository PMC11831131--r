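#' Configuration of a synthetic cruise archive
#'
#' Defines a world of 1-degree sites, each with a baseline nutricline
#' depth, a shared seasonal cycle, and per-site linear depth trends drawn
#' from configurable normal distributions, sampled by cruise-like casts at
#' irregular dates with bottle-level noise. The true crossing depth at site
#' s, time t, month m is
#' `Z_s(t, m) = Z0_s + A cos(2 pi (m - phase)/12) + b_s (t - t0)`,
#' with `b_s` drawn per nutrient. Each cast's concentration profile is a
#' logistic saturation curve positioned so that its interpolated threshold
#' crossing equals `Z_s` exactly, giving a closed-form ground truth for
#' every cast; the generator emits that truth as a sidecar table.
#'
#' Defaults emulate a five-decade archive (1972-2022) of subtropical sites
#' whose trend distributions carry a nitracline shoaling tendency
#' (mean -0.63, SD 1.5 m/y) and a phosphacline deepening tendency
#' (mean 0.20, SD 1.0 m/y) — the distributions that, replayed through
#' seasonal sampling, reproduce observed-archive-like medians and
#' variances. Bottle noise defaults are small analytical-replication
#' errors; the larger literature uncertainties (0.8/0.1 umol/kg) are
#' injected separately via [inject_measurement_error()] when studying
#' error sensitivity.
#'
#' @param n_sites Number of distinct 1-degree sites.
#' @param lat_range,lon_range Integer degree ranges sites are drawn from.
#' @param years Inclusive year span `c(first, last)`.
#' @param casts_per_site_year Poisson mean number of casts per site-year.
#' @param month_weights 12 sampling weights over calendar months.
#' @param baseline_depth_range Range (m) the per-site mean nutricline depth
#'   `Z0_s` is drawn from, uniformly.
#' @param seasonal_amplitude Seasonal amplitude A, m.
#' @param seasonal_phase Month of the seasonal maximum depth.
#' @param trend_dist_no3,trend_dist_po4 [trend_distribution()]s the
#'   per-site slopes are drawn from. Either may be a single number for a
#'   fixed slope at all sites.
#' @param redfield_coupled If `TRUE`, phosphate is nitrate/16 exactly at
#'   every bottle (shared crossing depth and noise); trends then come from
#'   `trend_dist_no3` alone.
#' @param deep_concentration Deep-water nitrate asymptote, umol/kg.
#' @param transition_width Logistic nutricline width w, m. Together with
#'   the default 15 m bottle spacing through the nutricline zone this keeps
#'   the piecewise-linear interpolation error of the crossing below about
#'   0.5 m.
#' @param threshold_no3 Nitrate threshold (umol/kg) the true `Z_s` refers
#'   to; phosphate uses threshold/16 on a profile scaled by 1/16.
#' @param bottle_depths Standard bottle depths, m.
#' @param noise An [error_model()] for bottle-level noise (its seed is
#'   ignored; the archive seed governs).
#' @param deep_drift Named vector `c(nitrate=, phosphate=)`, umol/kg/y of
#'   concentration drift added below 1000 m (a measurement-bias scenario).
#' @param ts_profile Two-layer temperature/salinity column parameters
#'   (logistic transition): `surface_t`, `deep_t`, `surface_s`, `deep_s`,
#'   `pycnocline_depth`, `pycnocline_width`.
#' @param seed Integer seed; the whole archive is a deterministic function
#'   of the config.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world <- function(n_sites = 300,
                            lat_range = c(-45, 45),
                            lon_range = c(-180, 179),
                            years = c(1972, 2022),
                            casts_per_site_year = 2,
                            month_weights = rep(1, 12),
                            baseline_depth_range = c(80, 160),
                            seasonal_amplitude = 20,
                            seasonal_phase = 2,
                            trend_dist_no3 = trend_distribution(-0.63, 1.5),
                            trend_dist_po4 = trend_distribution(0.20, 1.0),
                            redfield_coupled = FALSE,
                            deep_concentration = 35,
                            transition_width = 50,
                            threshold_no3 = 3,
                            bottle_depths = c(5, 15, seq(30, 300, by = 15),
                                              350, 400, 500, 750, 1000,
                                              1250, 1500, 2000),
                            noise = error_model(0.1, 0.01),
                            deep_drift = c(nitrate = 0, phosphate = 0),
                            ts_profile = list(surface_t = 24, deep_t = 4,
                                              surface_s = 35.5, deep_s = 34.7,
                                              pycnocline_depth = 120,
                                              pycnocline_width = 80),
                            seed = 1L) {
  stopifnot(
    n_sites > 0, years[2] >= years[1] + 1, casts_per_site_year > 0,
    length(month_weights) == 12, all(month_weights >= 0),
    sum(month_weights) > 0, transition_width > 0,
    baseline_depth_range[1] > 0, deep_concentration > threshold_no3,
    threshold_no3 > 0, all(diff(bottle_depths) > 0)
  )
  for (nm in c("trend_dist_no3", "trend_dist_po4")) {
    v <- get(nm)
    if (is.numeric(v) && length(v) == 1) {
      assign(nm, trend_distribution(v, 0))
    } else if (!inherits(v, "trend_distribution")) {
      abort(paste0(nm, " must be a trend_distribution() or a single slope"))
    }
  }
  structure(
    list(
      n_sites = n_sites, lat_range = lat_range, lon_range = lon_range,
      years = years, casts_per_site_year = casts_per_site_year,
      month_weights = month_weights,
      baseline_depth_range = baseline_depth_range,
      seasonal_amplitude = seasonal_amplitude,
      seasonal_phase = seasonal_phase,
      trend_dist_no3 = trend_dist_no3, trend_dist_po4 = trend_dist_po4,
      redfield_coupled = redfield_coupled,
      deep_concentration = deep_concentration,
      transition_width = transition_width, threshold_no3 = threshold_no3,
      bottle_depths = bottle_depths, noise = noise,
      deep_drift = deep_drift, ts_profile = ts_profile, seed = seed
    ),
    class = "synthetic_world_config"
  )
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Nitrate concentration at depth z for true crossing depth zc: a logistic
# saturation positioned so C(zc) = threshold exactly.
profile_conc <- function(z, zc, c_deep, w, threshold) {
  z0 <- zc - w * logit(threshold / c_deep)
  c_deep * logistic((z - z0) / w)
}

ts_at_depth <- function(z, p) {
  f <- logistic((z - p$pycnocline_depth) / p$pycnocline_width)
  list(t = p$surface_t + (p$deep_t - p$surface_t) * f,
       s = p$surface_s + (p$deep_s - p$surface_s) * f)
}

draw_sites <- function(config) {
  lats <- seq(config$lat_range[1], config$lat_range[2])
  lons <- seq(config$lon_range[1], config$lon_range[2])
  cells <- tidyr::expand_grid(lat_bin = lats, lon_bin = lons)
  if (nrow(cells) < config$n_sites) abort("more sites than grid cells")
  cells <- cells[sample.int(nrow(cells), config$n_sites), ]
  cells$z0 <- runif(config$n_sites, config$baseline_depth_range[1],
                    config$baseline_depth_range[2])
  cells$b_no3 <- rnorm(config$n_sites, config$trend_dist_no3$mean,
                       config$trend_dist_no3$sd)
  cells$b_po4 <- if (config$redfield_coupled) {
    cells$b_no3
  } else {
    rnorm(config$n_sites, config$trend_dist_po4$mean,
          config$trend_dist_po4$sd)
  }
  cells
}

#' Generate a synthetic cruise archive with ground truth
#'
#' Realises the world described by a [synthetic_world()] config: draws
#' sites, per-site baseline depths and trends, cast dates, and bottle
#' concentrations, and returns both the bottle table (canonical schema)
#' and a ground-truth table keyed by `cast_id` carrying the analytic
#' crossing depths and the drawn slopes — so tests never re-derive truth
#' from generator internals. Deterministic given the config.
#'
#' @param config A `synthetic_world_config`.
#' @return List with `casts` (bottle tibble), `truth` (per-cast analytic
#'   `true_z_no3`, `true_z_po4`, per-site `b_no3`, `b_po4`, `z0`), and
#'   `sites` (one row per site).
#' @export
generate_archive <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  with_seed(config$seed, {
    sites <- draw_sites(config)
    yrs <- seq(config$years[1], config$years[2])
    t0 <- mean(range(yrs)) + 0.5  # centre of the decimal-year span

    counts <- rpois(nrow(sites) * length(yrs), config$casts_per_site_year)
    grid <- tidyr::expand_grid(site = seq_len(nrow(sites)), year = yrs)
    grid$n <- counts
    ev <- grid[rep(seq_len(nrow(grid)), grid$n), c("site", "year")]
    n_ev <- nrow(ev)
    ev$month <- sample.int(12, n_ev, replace = TRUE,
                           prob = config$month_weights)
    ev$day <- sample.int(28, n_ev, replace = TRUE)
    ev$cast_id <- sprintf("syn%06d", seq_len(n_ev))
    ev$lat_bin <- sites$lat_bin[ev$site]
    ev$lon_bin <- sites$lon_bin[ev$site]
    ev$latitude <- ev$lat_bin + runif(n_ev, -0.49, 0.49)
    ev$longitude <- ev$lon_bin + runif(n_ev, -0.49, 0.49)
    ev$t <- decimal_year(ev$year, ev$month)

    seas <- config$seasonal_amplitude *
      cos(2 * pi * (ev$month - config$seasonal_phase) / 12)
    ev$true_z_no3 <- sites$z0[ev$site] + seas +
      sites$b_no3[ev$site] * (ev$t - t0)
    ev$true_z_po4 <- if (config$redfield_coupled) {
      ev$true_z_no3
    } else {
      sites$z0[ev$site] + seas + sites$b_po4[ev$site] * (ev$t - t0)
    }

    zb <- config$bottle_depths
    nb <- length(zb)
    bot <- ev[rep(seq_len(n_ev), each = nb), ]
    bot$depth_m <- rep(zb, times = n_ev)

    no3 <- profile_conc(bot$depth_m, bot$true_z_no3,
                        config$deep_concentration, config$transition_width,
                        config$threshold_no3)
    deep <- bot$depth_m > 1000
    no3[deep] <- no3[deep] +
      config$deep_drift[["nitrate"]] * (bot$t[deep] - t0)
    if (config$noise$nitrate_sd > 0) {
      no3 <- no3 + rnorm(length(no3), 0, config$noise$nitrate_sd)
    }
    no3 <- pmax(no3, 0)

    po4 <- if (config$redfield_coupled) {
      no3 / 16
    } else {
      p <- profile_conc(bot$depth_m, bot$true_z_po4,
                        config$deep_concentration, config$transition_width,
                        config$threshold_no3) / 16
      p[deep] <- p[deep] +
        config$deep_drift[["phosphate"]] * (bot$t[deep] - t0)
      if (config$noise$phosphate_sd > 0) {
        p <- p + rnorm(length(p), 0, config$noise$phosphate_sd)
      }
      pmax(p, 0)
    }

    ts <- ts_at_depth(bot$depth_m, config$ts_profile)

    casts <- tibble::tibble(
      cast_id = bot$cast_id,
      date = as.Date(sprintf("%d-%02d-%02d", bot$year, bot$month, bot$day)),
      latitude = bot$latitude, longitude = bot$longitude,
      depth_m = bot$depth_m,
      nitrate_umol_kg = no3, phosphate_umol_kg = po4,
      temperature_c = ts$t, salinity_psu = ts$s,
      qc_flag = "good"
    )
    truth <- tibble::tibble(
      cast_id = ev$cast_id, lat_bin = ev$lat_bin, lon_bin = ev$lon_bin,
      year = ev$year, month = ev$month, t = ev$t,
      true_z_no3 = ev$true_z_no3, true_z_po4 = ev$true_z_po4,
      b_no3 = sites$b_no3[ev$site], b_po4 = sites$b_po4[ev$site],
      z0 = sites$z0[ev$site]
    )
    list(casts = casts, truth = truth,
         sites = tibble::as_tibble(sites), t0 = t0)
  })
}

#' Analytic monthly climatology of a synthetic world
#'
#' The trend-free (`b = 0`, `t = t0`) seasonal state of the same world:
#' per (site, month) nutricline depths
#' `Z0_s + A cos(2 pi (m - phase)/12)` for both nutrients, and noise-free
#' concentration profiles at the configured bottle depths. By construction
#' it has no long-term change, making it the reference for
#' [seasonal_anomaly()], [simulate_climatology_sampling()], and
#' [deep_anomaly_trend()].
#'
#' @param config A `synthetic_world_config` (the site draw uses the config
#'   seed, so archive and climatology share sites).
#' @return A `monthly_climatology`.
#' @export
generate_climatology <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  sites <- with_seed(config$seed, draw_sites(config))
  sm <- tidyr::expand_grid(site = seq_len(nrow(sites)), month = 1:12)
  sm$lat_bin <- sites$lat_bin[sm$site]
  sm$lon_bin <- sites$lon_bin[sm$site]
  sm$z <- sites$z0[sm$site] + config$seasonal_amplitude *
    cos(2 * pi * (sm$month - config$seasonal_phase) / 12)
  depths <- purrr::map(c("nitrate", "phosphate"), function(nu) {
    tibble::tibble(lat_bin = sm$lat_bin, lon_bin = sm$lon_bin,
                   month = sm$month, nutrient = nu, clim_depth = sm$z)
  }) |>
    purrr::list_rbind()

  zb <- config$bottle_depths
  prof_base <- sm[rep(seq_len(nrow(sm)), each = length(zb)), ]
  prof_base$depth_m <- rep(zb, times = nrow(sm))
  cn <- profile_conc(prof_base$depth_m, prof_base$z,
                     config$deep_concentration, config$transition_width,
                     config$threshold_no3)
  profiles <- dplyr::bind_rows(
    tibble::tibble(lat_bin = prof_base$lat_bin, lon_bin = prof_base$lon_bin,
                   month = prof_base$month, nutrient = "nitrate",
                   depth_m = prof_base$depth_m, concentration = cn),
    tibble::tibble(lat_bin = prof_base$lat_bin, lon_bin = prof_base$lon_bin,
                   month = prof_base$month, nutrient = "phosphate",
                   depth_m = prof_base$depth_m, concentration = cn / 16)
  )
  new_monthly_climatology(depths = depths, profiles = profiles)
}
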