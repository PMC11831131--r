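#' Measurement-error model for nutrient concentrations
#'
#' Zero-mean normal perturbations added per bottle and nutrient, emulating
#' laboratory uncertainty. The defaults (0.8 umol/kg for nitrate, 0.1
#' umol/kg for phosphate, i.e. 800 and 100 nmol/kg) reflect reported
#' analytical uncertainty of standard autoanalyser methods.
#'
#' @param nitrate_sd,phosphate_sd Standard deviations, umol/kg (>= 0).
#' @param seed Integer seed.
#' @return An `error_model` list.
#' @export
error_model <- function(nitrate_sd = 0.8, phosphate_sd = 0.1, seed = 1L) {
  stopifnot(nitrate_sd >= 0, phosphate_sd >= 0)
  structure(list(nitrate_sd = nitrate_sd, phosphate_sd = phosphate_sd,
                 seed = seed),
            class = "error_model")
}

#' Normal distribution of site-level trends
#'
#' @param mean,sd Mean and standard deviation, m/y (`sd >= 0`).
#' @return A `trend_distribution` list.
#' @export
trend_distribution <- function(mean, sd) {
  stopifnot(sd >= 0)
  structure(list(mean = mean, sd = sd), class = "trend_distribution")
}

#' Inject measurement error into bottle concentrations
#'
#' Adds independent zero-mean normal noise to every non-missing nitrate and
#' phosphate value; perturbed concentrations that land below zero are
#' clamped to 0 (a concentration cannot be negative). The perturbation acts
#' on concentrations, not depths, so rerunning the nutricline pipeline on
#' the result propagates the error through interpolation exactly as real
#' analytical error would.
#'
#' @param casts Bottle tibble.
#' @param model An [error_model()].
#' @return Perturbed bottle tibble.
#' @export
inject_measurement_error <- function(casts, model = error_model()) {
  with_seed(model$seed, {
    for (spec in list(c("nitrate_umol_kg", "nitrate_sd"),
                      c("phosphate_umol_kg", "phosphate_sd"))) {
      col <- spec[1]; sdv <- model[[spec[2]]]
      if (sdv > 0) {
        ok <- !is.na(casts[[col]])
        casts[[col]][ok] <- pmax(0, casts[[col]][ok] + rnorm(sum(ok), 0, sdv))
      }
    }
    casts
  })
}

#' Scrambled-year null distribution of the median trend (MToRP)
#'
#' Destroys temporal order by randomly permuting the year labels of each
#' site's annual depths (by default within site, preserving each site's
#' multiset of depths and years exactly; `scope = "global"` permutes years
#' across the pooled annual points instead). Site trends are refitted per
#' randomization and the median recorded, giving the null distribution of
#' median trends of random populations. The two-sided empirical p-value for
#' the observed median uses the add-one correction
#' p = (1 + #\{|m*| >= |m_obs|\}) / (n + 1), so it is bounded below by
#' 1/(n+1).
#'
#' @param series Trend-eligible site-annual series (single nutrient or
#'   already grouped upstream).
#' @param n_randomizations Number of randomizations (default 10,000).
#' @param seed Integer seed.
#' @param scope `"site"` (within-site permutation, the stricter null) or
#'   `"global"`.
#' @return An `mtorp` object: `medians`, `n_randomizations`,
#'   `observed_median`, `p_value`, `scope`, `seed`.
#' @export
scramble_years <- function(series, n_randomizations = 10000, seed = 1L,
                           scope = c("site", "global")) {
  scope <- match.arg(scope)
  gcols <- c("lat_bin", "lon_bin", "nutrient",
             intersect("spec_id", names(series)))
  key <- do.call(paste, c(unname(series[gcols]), sep = "/"))
  g <- match(key, unique(key))
  o <- order(g); x <- series[o, ]; g <- g[o]
  k <- max(g)
  yr <- x$year - mean(x$year)
  dep <- x$mean_depth

  obs <- group_ols(g, yr, dep, k)
  observed_median <- median(obs$slope, na.rm = TRUE)

  n <- tabulate(g, k)
  sx <- rowsum_vec(yr, g, k)
  sy <- rowsum_vec(dep, g, k)
  fittable <- n >= 2

  medians <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) {
      if (scope == "site") {
        xp <- permute_within(yr, g)
        denom <- obs$denom          # year multiset per site unchanged
        sxp <- sx
      } else {
        xp <- yr[sample.int(length(yr))]
        sxp <- rowsum_vec(xp, g, k)
        denom <- rowsum_vec(xp * xp, g, k) - sxp^2 / n
      }
      sxy <- rowsum_vec(xp * dep, g, k)
      sl <- (sxy - sxp * sy / n) / denom
      median(sl[fittable & denom > 0])
    }, numeric(1))
  })

  p <- (1 + sum(abs(medians) >= abs(observed_median))) /
    (n_randomizations + 1)
  structure(
    list(medians = medians, n_randomizations = n_randomizations,
         observed_median = observed_median, p_value = p, scope = scope,
         seed = seed),
    class = "mtorp"
  )
}

#' @export
print.mtorp <- function(x, digits = 3, ...) {
  cat(sprintf(
    "MToRP null (%s scramble, %d randomizations)\n  observed median %.*g, two-sided p = %.2g\n",
    x$scope, x$n_randomizations, digits, x$observed_median, x$p_value
  ))
  invisible(x)
}

#' Simulate sampling schedules on a fixed monthly climatology
#'
#' Takes the (site, date) sampling events of an archive and replays them
#' against a climatology with no long-term change: the pseudo-depth at
#' (site, date) is the climatological nutricline depth for (site, month),
#' plus an optional imposed trend term b_s (t - t0). `imposed` may be
#' `NULL` (pure seasonality, the null), a fixed slope in m/y applied at all
#' sites, or a [trend_distribution()] drawn per site per population. Random
#' populations are constructed by permuting the month labels across
#' sampling events (preserving the archive's overall monthly sampling
#' distribution while breaking the site-month pairing); set
#' `randomize_months = FALSE` with `n_populations = 1` for the
#' deterministic replay of the actual dates. Each population is pushed
#' through the full aggregation/filter/trend pipeline and the median,
#' interquartile range and variance of its site trends recorded. Under the
#' null the medians scatter around zero; with an imposed trend the median
#' shifts to match it, while the spread quantifies how much trend variance
#' seasonality in the sampling schedule generates.
#'
#' @param clim A `monthly_climatology` with nutricline depths.
#' @param schedule Tibble of sampling events: `lat_bin`, `lon_bin`, `date`
#'   (or `year` + `month`). Events at sites missing from the climatology
#'   are dropped and counted (`$n_dropped`).
#' @param imposed `NULL`, a single numeric slope, or a
#'   [trend_distribution()].
#' @param n_populations Number of pseudo-archives.
#' @param seed Integer seed.
#' @param nutrients Nutrients to simulate.
#' @param min_depth,lat_range Eligibility filters applied to pseudo-depths.
#' @param randomize_months Permute event months per population (default).
#' @return A `clim_sim` object whose `$populations` tibble has one row per
#'   (population, nutrient): `median_trend`, `iqr_trend`, `var_trend`,
#'   `n_sites`.
#' @export
simulate_climatology_sampling <- function(clim, schedule, imposed = NULL,
                                          n_populations = 10000, seed = 1L,
                                          nutrients = c("nitrate", "phosphate"),
                                          min_depth = 50,
                                          lat_range = c(-45, 45),
                                          randomize_months = TRUE) {
  if (!is.null(imposed) && !inherits(imposed, "trend_distribution") &&
      !(is.numeric(imposed) && length(imposed) == 1)) {
    abort("imposed must be NULL, a single slope, or a trend_distribution()")
  }
  if (is.null(clim$depths)) abort("climatology has no nutricline-depth field")
  if (!all(c("year", "month") %in% names(schedule))) {
    schedule$year <- as.integer(format(schedule$date, "%Y"))
    schedule$month <- as.integer(format(schedule$date, "%m"))
  }
  schedule <- schedule |>
    dplyr::filter(.data$lat_bin >= lat_range[1],
                  .data$lat_bin <= lat_range[2])
  if (nrow(schedule) == 0) abort("no schedule events within lat_range")

  # per-nutrient (site x month) depth matrices for fast per-population lookup
  site_key <- paste(schedule$lat_bin, schedule$lon_bin, sep = "/")
  lookup <- purrr::map(nutrients, function(nu) {
    d <- clim$depths[clim$depths$nutrient == nu, ]
    ckey <- paste(d$lat_bin, d$lon_bin, sep = "/")
    usite <- unique(ckey)
    M <- matrix(NA_real_, nrow = length(usite), ncol = 12,
                dimnames = list(usite, NULL))
    M[cbind(match(ckey, usite), d$month)] <- d$clim_depth
    list(M = M, event_site = match(site_key, usite))
  })
  names(lookup) <- nutrients
  resolvable <- purrr::reduce(
    purrr::map(lookup, ~ !is.na(.x$event_site)), `&`
  )
  n_dropped <- sum(!resolvable)
  schedule <- schedule[resolvable, ]
  if (nrow(schedule) == 0) abort("no schedule events resolve in the climatology")
  for (nu in nutrients) {
    lookup[[nu]]$event_site <- lookup[[nu]]$event_site[resolvable]
  }

  n_ev <- nrow(schedule)
  t0 <- mean(decimal_year(schedule$year, schedule$month))
  # the site set indexing imposed-trend draws (shared across nutrients)
  s <- match(site_key[resolvable], unique(site_key[resolvable]))
  n_site <- max(s)
  # fixed annual grouping per (site, year); depths vary per population
  ann_key <- paste(s, schedule$year, sep = "/")
  a <- match(ann_key, unique(ann_key))
  o <- order(a)
  schedule <- schedule[o, ]; a <- a[o]; s <- s[o]
  for (nu in nutrients) {
    lookup[[nu]]$event_site <- lookup[[nu]]$event_site[o]
  }
  k_ann <- max(a)
  first_of_ann <- !duplicated(a)
  ann_site <- s[first_of_ann]
  ann_year <- schedule$year[first_of_ann]

  seeds <- derive_seeds(seed, n_populations)
  pops <- purrr::map(seq_len(n_populations), function(i) {
    with_seed(seeds[i], {
      months <- if (randomize_months) {
        schedule$month[sample.int(n_ev)]
      } else {
        schedule$month
      }
      tt <- decimal_year(schedule$year, months)
      b <- if (is.null(imposed)) {
        numeric(n_site)
      } else if (inherits(imposed, "trend_distribution")) {
        rnorm(n_site, imposed$mean, imposed$sd)
      } else {
        rep(imposed, n_site)
      }
      purrr::map(nutrients, function(nu) {
        depth <- lookup[[nu]]$M[cbind(lookup[[nu]]$event_site, months)] +
          b[s] * (tt - t0)
        ok <- !is.na(depth)
        ann_n <- rowsum_vec(ok + 0, a, k_ann)
        ann_depth <- rowsum_vec(ifelse(ok, depth, 0), a, k_ann) / ann_n
        sel <- !is.na(ann_depth) & ann_depth > min_depth
        if (sum(sel) < 2) {
          return(tibble::tibble(population = i, nutrient = nu,
                                median_trend = NA_real_, iqr_trend = NA_real_,
                                var_trend = NA_real_, n_sites = 0L))
        }
        gg <- match(ann_site[sel], unique(ann_site[sel]))
        oo <- order(gg)
        fit <- group_ols(gg[oo], ann_year[sel][oo] - mean(ann_year[sel]),
                         ann_depth[sel][oo])
        sl <- fit$slope[!is.na(fit$slope)]
        if (length(sl) < 2) {
          return(tibble::tibble(population = i, nutrient = nu,
                                median_trend = NA_real_, iqr_trend = NA_real_,
                                var_trend = NA_real_, n_sites = length(sl)))
        }
        tibble::tibble(
          population = i, nutrient = nu,
          median_trend = median(sl),
          iqr_trend = unname(diff(quantile(sl, c(0.25, 0.75)))),
          var_trend = var(sl), n_sites = length(sl)
        )
      }) |>
        purrr::list_rbind()
    })
  }) |>
    purrr::list_rbind()

  structure(
    list(populations = pops, imposed = imposed,
         n_populations = n_populations, seed = seed, n_dropped = n_dropped),
    class = "clim_sim"
  )
}

#' @export
print.clim_sim <- function(x, ...) {
  cat(sprintf("<clim_sim> %d populations\n", x$n_populations))
  s <- x$populations |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(mean_median = mean(.data$median_trend, na.rm = TRUE),
                     mean_iqr = mean(.data$iqr_trend, na.rm = TRUE))
  print(s)
  invisible(x)
}

#' Match an imposed trend distribution to observed statistics
#'
#' Searches a grid of (mean, sd) trend distributions for the one whose
#' climatology-sampling simulations best reproduce the observed median
#' trend and the observed variance of site trends. The loss at each grid
#' point is the sum of squared standardized errors (each discrepancy
#' divided by the Monte-Carlo standard error of the simulated summary), so
#' both targets are on comparable scales; ties break toward smaller sd.
#' Grid search is used deliberately: the objective is a noisy simulation
#' output, and replication over a transparent grid is more robust than
#' gradient steps.
#'
#' @param observed_median Observed median site trend, m/y.
#' @param observed_variance Observed variance of site trends, (m/y)^2.
#' @param clim,schedule,n_populations,seed,nutrient,min_depth,lat_range
#'   Passed to [simulate_climatology_sampling()] (single nutrient).
#' @param grid List with numeric vectors `mean` and `sd` defining the
#'   search grid.
#' @return The best-fitting [trend_distribution()], with attributes
#'   `search` (the full grid results tibble) and `boundary` (`TRUE`, with a
#'   warning, when the optimum sits on the grid edge).
#' @export
match_trend_distribution <- function(observed_median, observed_variance,
                                     clim, schedule,
                                     grid = list(mean = seq(-1, 1, by = 0.25),
                                                 sd = seq(0, 2, by = 0.5)),
                                     n_populations = 200, seed = 1L,
                                     nutrient = "nitrate",
                                     min_depth = 50, lat_range = c(-45, 45)) {
  cells <- tidyr::expand_grid(mean = grid$mean, sd = grid$sd)
  if (nrow(cells) < 2) abort("grid must contain at least 2 cells")
  seeds <- derive_seeds(seed, nrow(cells))
  res <- purrr::pmap(list(cells$mean, cells$sd, seeds),
    function(m, sdv, sd_i) {
      sim <- simulate_climatology_sampling(
        clim, schedule, imposed = trend_distribution(m, sdv),
        n_populations = n_populations, seed = sd_i, nutrients = nutrient,
        min_depth = min_depth, lat_range = lat_range
      )
      p <- sim$populations
      med <- p$median_trend[!is.na(p$median_trend)]
      vtr <- p$var_trend[!is.na(p$var_trend)]
      tibble::tibble(
        mean = m, sd = sdv,
        sim_median = mean(med), sim_variance = mean(vtr),
        se_median = sd(med) / sqrt(length(med)),
        se_variance = sd(vtr) / sqrt(length(vtr))
      )
    }) |>
    purrr::list_rbind()
  # standardize both discrepancies on a scale common to all cells (the
  # median Monte-Carlo SE), so noisier cells are not rewarded
  sc_med <- max(median(res$se_median), 1e-12)
  sc_var <- max(median(res$se_variance), 1e-12)
  res$loss <- ((res$sim_median - observed_median) / sc_med)^2 +
    ((res$sim_variance - observed_variance) / sc_var)^2
  res <- res[order(res$loss, res$sd), ]   # ties toward smaller sd
  best <- res[1, ]
  boundary <-
    (length(unique(grid$mean)) > 1 && best$mean %in% range(grid$mean)) ||
    (length(unique(grid$sd)) > 1 && best$sd %in% range(grid$sd))
  if (boundary) {
    warn("optimum lies on the grid boundary; widen the grid")
  }
  out <- trend_distribution(best$mean, best$sd)
  attr(out, "search") <- res
  attr(out, "boundary") <- boundary
  out
}
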