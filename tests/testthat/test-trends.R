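test_that("global regression recovers a two-point line and flat data", {
  ser <- dplyr::bind_rows(
    make_series(2000, 100),
    make_series(2010, 110, lat_bin = 11L),
    make_series(2005, 105, lat_bin = 12L)
  )
  fit <- fit_global_regression(ser)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$n_points, 3)

  flat <- make_series(2000:2009, rep(120, 10))
  f2 <- fit_global_regression(flat)
  expect_equal(f2$slope, 0, tolerance = 1e-10)
  expect_equal(f2$p_value, 1, tolerance = 1e-6)

  expect_error(fit_global_regression(make_series(2000:2001, c(1, 2))),
               "fewer than 3")
})

test_that("site trends are per-site OLS slopes with a two-year minimum", {
  ser <- dplyr::bind_rows(
    make_series(c(2000, 2010), c(100, 120)),            # slope 2
    make_series(2005, 100, lat_bin = 20L),              # single year: skipped
    make_series(c(2000, 2005, 2010), c(90, 100, 110), lat_bin = 30L)
  )
  tr <- fit_site_trends(ser)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$slope[tr$lat_bin == 10], 2.0)
  expect_equal(tr$slope[tr$lat_bin == 30], 2.0)
  expect_equal(attr(tr, "n_skipped"), 1)
  # collinear points: residuals are exactly zero
  expect_equal(tr$n_years[tr$lat_bin == 30], 3L)
})

test_that("closed-form grouped slopes agree with lm()", {
  set.seed(21)
  ser <- purrr::map(1:15, function(i) {
    yrs <- sort(sample(1990:2020, sample(3:8, 1)))
    make_series(yrs, 100 + rnorm(length(yrs), 0, 15), lat_bin = i)
  }) |> purrr::list_rbind()
  tr <- fit_site_trends(ser)
  byhand <- vapply(1:15, function(i) {
    d <- ser[ser$lat_bin == i, ]
    unname(coef(lm(mean_depth ~ year, data = d))[2])
  }, numeric(1))
  expect_equal(tr$slope, byhand[tr$lat_bin])
})

test_that("bootstrap median CI honours degenerate and exact cases", {
  s <- median_with_bootstrap_ci(rep(0.7, 10), n_bootstrap = 200, seed = 1)
  expect_equal(s$median, 0.7)
  expect_equal(c(s$ci_low, s$ci_high), c(0.7, 0.7))
  expect_equal(median_with_bootstrap_ci(c(-1, 0, 1), 100, seed = 1)$median, 0)
  expect_error(median_with_bootstrap_ci(numeric(0)), "at least 2")
})

test_that("bootstrap CI width matches median sampling theory within 1.5x", {
  set.seed(99)
  slopes <- rnorm(1600, 0.35, 1.0)
  s <- median_with_bootstrap_ci(slopes, n_bootstrap = 2000, seed = 5)
  theory <- 2 * 1.96 * 1.2533 / sqrt(1600)  # asymptotic sd of a normal median
  width <- s$ci_high - s$ci_low
  expect_gt(width, theory / 1.5)
  expect_lt(width, theory * 1.5)
})

test_that("bootstrap CI contains the median and ignores input order", {
  set.seed(17)
  slopes <- rnorm(101, 0.2, 1)
  a <- median_with_bootstrap_ci(slopes, 500, seed = 3)
  expect_lte(a$ci_low, a$median)
  expect_gte(a$ci_high, a$median)
  b <- median_with_bootstrap_ci(rev(slopes), 500, seed = 3)
  expect_equal(b$median, a$median)
  expect_equal(c(b$ci_low, b$ci_high), c(a$ci_low, a$ci_high),
               tolerance = 0.05)
  expect_equal(tidy(a)$median, a$median)
})

test_that("seasonal anomalies subtract the monthly climatological depth", {
  rec <- tibble::tibble(
    cast_id = "c1", nutrient = "nitrate", threshold = 3, spec_id = "N3",
    depth_m = 120, status = "crossed", latitude = 10.2, longitude = 20.1,
    year = 2000L, month = 7L
  )
  clim <- make_depth_clim(tibble::tibble(
    lat_bin = 10L, lon_bin = 20L, month = 7L, nutrient = "nitrate",
    clim_depth = 100
  ))
  out <- seasonal_anomaly(rec, clim)
  expect_equal(out$depth_m, 20)
  expect_equal(out$depth_raw_m, 120)

  # unmapped site: dropped and counted
  rec2 <- dplyr::mutate(rec, latitude = 50.2)
  out2 <- seasonal_anomaly(rec2, clim)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped"), 1)
})

test_that("anomaly trends recover a constructed linear drift exactly", {
  # observed depth = climatology + b (t - t0): anomalies are the pure trend
  clim_depths <- tidyr::expand_grid(month = 1:12) |>
    dplyr::mutate(lat_bin = 10L, lon_bin = 20L, nutrient = "nitrate",
                  clim_depth = 100 + 15 * cos(2 * pi * (month - 2) / 12))
  clim <- make_depth_clim(clim_depths)
  b <- 0.8
  set.seed(4)
  rec <- purrr::map(1995:2015, function(y) {
    m <- sample.int(12, 3, replace = TRUE)
    tibble::tibble(
      cast_id = paste0("c", y, "-", seq_along(m)),
      nutrient = "nitrate", threshold = 3, spec_id = "N3",
      depth_m = 100 + 15 * cos(2 * pi * (m - 2) / 12) + b * (y - 2005),
      status = "crossed", latitude = 10.1, longitude = 19.9,
      year = y, month = m
    )
  }) |> purrr::list_rbind()
  ann <- seasonal_anomaly(rec, clim) |> annual_average()
  tr <- fit_site_trends(ann)
  expect_equal(tr$slope, b, tolerance = 1e-6)
})

test_that("paired residual trends act on per-cast depth differences", {
  mk <- function(year, zno3, zpo4) {
    tibble::tibble(
      cast_id = paste0("c", year), nutrient = c("nitrate", "phosphate"),
      threshold = c(3, 3 / 16), spec_id = "N3",
      depth_m = c(zno3, zpo4), status = "crossed",
      latitude = 10, longitude = 20, year = year, month = 6L
    )
  }
  # phosphacline deepens 0.5 m/y, nitracline flat
  rec <- purrr::map(2000:2019,
                    ~ mk(.x, 130, 100 + 0.5 * (.x - 2000))) |>
    purrr::list_rbind()
  tr <- paired_residual_trend(rec)
  expect_equal(tr$quantity, "ZNO3_minus_ZPO4")
  expect_equal(tr$slope, -0.5, tolerance = 1e-8)

  # a cast with an undefined phosphacline is excluded from pairing
  rec2 <- dplyr::bind_rows(
    rec,
    tibble::tibble(cast_id = "solo", nutrient = "nitrate", threshold = 3,
                   spec_id = "N3", depth_m = 500, status = "crossed",
                   latitude = 10, longitude = 20, year = 2019L, month = 6L)
  )
  expect_equal(paired_residual_trend(rec2)$slope, tr$slope)
})

test_that("residual T_PO4 is the signed orthogonal distance from the 1:1 line", {
  expect_equal(residual_tpo4(0, 1), 1 / sqrt(2))
  expect_equal(residual_tpo4(1, 0), -1 / sqrt(2))
  for (c0 in c(-3, 0, 0.47)) expect_equal(residual_tpo4(c0, c0), 0)
  set.seed(8)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(residual_tpo4(a, b), -residual_tpo4(b, a))
})

test_that("sign test matches exact binomial enumeration", {
  expect_equal(sign_test(c(1, 1, 1, 1))$p_value, 2 * (1 / 2)^4)
  expect_equal(sign_test(c(1, -1))$p_value, 1)
  expect_equal(sign_test(rep(1, 20))$p_value, 2 * (1 / 2)^20)
  st <- sign_test(c(1, 1, -1, 0))
  expect_equal(st$n_zero, 1)
  expect_warning(out <- sign_test(c(0, 0)), "zero")
  expect_true(is.na(out$p_value))
})

test_that("Kruskal-Wallis wrapper reproduces a hand-rank computation", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  # ranks 1..6, no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  rbar <- c(2, 5); H <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(kw$statistic, H)
  expect_equal(kruskal_wallis(list(x = 1:4, y = 1:4))$statistic, 0)
  expect_error(kruskal_wallis(list(x = 1, y = 1:3)), "at least 2")
})

test_that("regional medians reduce to the global median for one region", {
  set.seed(2)
  tr <- fit_site_trends(purrr::map(1:20, function(i) {
    make_series(2000:2005, 100 + rnorm(6, 0, 10), lat_bin = i - 10L)
  }) |> purrr::list_rbind())
  all_region <- region_spec("all", -90, 90)
  rm <- regional_medians(tr, all_region, n_bootstrap = 200, seed = 1)
  expect_equal(rm$median, median(tr$slope))
  expect_false(rm$insufficient)

  empty <- regional_medians(tr, region_spec("arctic", 70, 89),
                            n_bootstrap = 200, seed = 1)
  expect_true(empty$insufficient)
  expect_true(is.na(empty$median))
})

test_that("hemispheric split recovers distinct imposed regional trends", {
  set.seed(31)
  south <- purrr::map(1:40, function(i) {
    make_series(2000:2010, 100 + 0.6 * (0:10) + rnorm(11, 0, 2),
                lat_bin = -sample(1:45, 1), lon_bin = i)
  })
  north <- purrr::map(1:40, function(i) {
    make_series(2000:2010, 100 + 0.1 * (0:10) + rnorm(11, 0, 2),
                lat_bin = sample(0:45, 1), lon_bin = i)
  })
  tr <- fit_site_trends(purrr::list_rbind(c(south, north)))
  rm <- regional_medians(tr, regions_hemispheres(),
                         n_bootstrap = 500, seed = 2)
  s <- rm[rm$region == "southern", ]; n <- rm[rm$region == "northern", ]
  expect_true(s$ci_low <= 0.6 && 0.6 <= s$ci_high)
  expect_true(n$ci_low <= 0.1 && 0.1 <= n$ci_high)
})

test_that("extreme-trend filtering removes outliers and leaves the median", {
  tr <- fit_site_trends(purrr::map(1:9, function(i) {
    make_series(c(2000, 2010), c(100, 100 + 10 * (i - 5)), lat_bin = i)
  }) |> purrr::list_rbind())
  filt <- filter_extreme_trends(tr, c(-5, 5))
  expect_equal(attr(filt, "n_removed"), 0)
  filt2 <- filter_extreme_trends(tr, c(-3.5, 3.5))
  expect_equal(attr(filt2, "n_removed"), 2)  # symmetric outliers
  expect_equal(median(filt2$slope), median(tr$slope))
  expect_equal(nrow(filter_extreme_trends(tr, c(-Inf, Inf))), nrow(tr))
})

test_that("density trends are zero when the nutricline rides an isopycnal", {
  # static stratified column, flat nutricline: sigma at Z constant in time
  grid <- tidyr::expand_grid(y = 2000:2010, lon = c(-150, -140, -130))
  casts <- purrr::pmap(grid, function(y, lon) {
    make_cast(seq(0, 400, by = 50), nitrate = seq(0, 16, by = 2),
              temperature = seq(20, 5, length.out = 9),
              salinity = 35, cast_id = paste0("c", y, lon), longitude = lon,
              date = as.Date(sprintf("%d-06-15", y)))
  }) |> purrr::list_rbind()
  rec <- compute_nutriclines(casts, nutrients = "nitrate") |>
    add_density_at_nutricline(casts)
  dt <- density_trends(rec, n_bootstrap = 200, seed = 1)
  expect_equal(dt$median, 0, tolerance = 1e-10)
})

test_that("a nutricline migrating into denser water shows the analytic rate", {
  # linear T(z): sigma(z) linear; Z deepens at b m/y =>
  # sigma trend = b * dsigma/dz
  b <- 2
  grid <- tidyr::expand_grid(y = 2000:2010, lon = c(-150, -140, -130))
  casts <- purrr::pmap(grid, function(y, lon) {
    zc <- 100 + b * (y - 2000)
    conc <- approx(c(0, zc, 400), c(0, 3, 12), xout = seq(0, 400, 25))$y
    make_cast(seq(0, 400, 25), nitrate = conc,
              temperature = 25 - 0.05 * seq(0, 400, 25),
              salinity = 35, cast_id = paste0("c", y, lon), longitude = lon,
              date = as.Date(sprintf("%d-06-15", y)))
  }) |> purrr::list_rbind()
  rec <- compute_nutriclines(casts, nutrients = "nitrate") |>
    add_density_at_nutricline(casts)
  dt <- density_trends(rec, n_bootstrap = 200, seed = 1)
  dsigma_dz <- 1025 * 2e-4 * 0.05
  expect_equal(dt$median, b * dsigma_dz, tolerance = 0.1)
})

test_that("density trends without any T/S report an explicit empty result", {
  casts <- purrr::map(2000:2004, function(y) {
    make_cast(c(0, 100, 250), nitrate = c(0, 3, 9),
              cast_id = paste0("c", y),
              date = as.Date(sprintf("%d-06-15", y)))
  }) |> purrr::list_rbind()
  rec <- compute_nutriclines(casts, nutrients = "nitrate",
                             control = ctl_open) |>
    add_density_at_nutricline(casts)
  dt <- density_trends(rec, n_bootstrap = 100, seed = 1)
  expect_equal(nrow(dt), 0)
  expect_equal(attr(dt, "n_missing_sigma"), nrow(rec))
})

test_that("deep anomalies vanish when observations equal the climatology", {
  w <- synthetic_world(n_sites = 6, years = c(1995, 2005),
                       noise = error_model(0, 0), seasonal_amplitude = 0,
                       trend_dist_no3 = 0, trend_dist_po4 = 0, seed = 12)
  arc <- generate_archive(w)
  clim <- generate_climatology(w)
  dt <- deep_anomaly_trend(arc$casts, clim)
  expect_equal(nrow(dt), 2)
  expect_equal(dt$slope, c(0, 0), tolerance = 1e-8)

  shallow <- arc$casts[arc$casts$depth_m < 900, ]
  expect_equal(nrow(deep_anomaly_trend(shallow, clim)), 0)
})
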