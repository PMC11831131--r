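test_that("interpolated first crossing matches the worked example and oracle", {
  cast <- make_cast(c(0, 50, 100), nitrate = c(0.5, 1.0, 5.0))
  rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
  expect_equal(rec$status, "crossed")
  expect_equal(rec$depth_m, 75.0)
  expect_equal(rec$depth_m,
               oracle_crossing(cast$depth_m, cast$nitrate_umol_kg, 3),
               tolerance = 0.01 / 75)
})

test_that("profiles that never reach the threshold have no depth", {
  cast <- make_cast(c(0, 50, 100), nitrate = c(0.1, 0.5, 2.0))
  rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
  expect_equal(rec$status, "never_reached")
  expect_true(is.na(rec$depth_m))
})

test_that("threshold met at the shallowest sample is surface saturation", {
  cast <- make_cast(c(5, 50, 100), nitrate = c(4.0, 6.0, 10.0))
  rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
  expect_equal(rec$status, "surface_saturated")
  expect_equal(rec$depth_m, 5)
})

test_that("crossing agrees with the dense-grid oracle on random profiles", {
  set.seed(42)
  for (i in 1:200) {
    depths <- sort(runif(sample(4:12, 1), 0, 400))
    conc <- cumsum(abs(rnorm(length(depths), 1, 2)))  # ragged increasing
    if (runif(1) < 0.3) conc <- conc + 5 * sin(depths / 40)  # non-monotone
    cast <- make_cast(depths, nitrate = conc)
    rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
    ora <- oracle_crossing(depths, conc, 3)
    if (rec$status == "crossed") {
      expect_equal(rec$depth_m, ora, tolerance = 0.011 / max(ora, 1))
    } else if (rec$status == "never_reached") {
      expect_true(is.na(ora))
    } else if (rec$status == "surface_saturated") {
      expect_equal(ora, depths[1])
    }
  }
})

test_that("first crossing from the surface governs on non-monotonic profiles", {
  # dips back below threshold at depth; the shallow crossing must win
  cast <- make_cast(c(0, 40, 80, 120, 160),
                    nitrate = c(1, 5, 2, 1, 6))
  rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
  expect_equal(rec$depth_m, 40 * (3 - 1) / (5 - 1))
})

test_that("larger thresholds cross deeper on monotone profiles", {
  cast <- make_cast(seq(0, 300, by = 25),
                    nitrate = seq(0, 12, length.out = 13),
                    phosphate = seq(0, 12, length.out = 13) / 16)
  specs <- list(redfield_thresholds(1), redfield_thresholds(3),
                redfield_thresholds(5))
  rec <- compute_nutriclines(cast, thresholds = specs, control = ctl_open)
  z <- rec$depth_m[rec$nutrient == "nitrate"]
  expect_equal(length(z), 3)
  expect_true(all(diff(z[order(c(1, 3, 5))]) > 0))
})

test_that("depth translation shifts a crossed nutricline by the same amount", {
  set.seed(7)
  for (i in 1:20) {
    depths <- sort(runif(6, 0, 300))
    conc <- sort(runif(6, 0, 10))
    cast <- make_cast(depths, nitrate = conc)
    shifted <- make_cast(depths + 37, nitrate = conc)
    a <- compute_nutricline(cast, "nitrate", control = ctl_open)
    b <- compute_nutricline(shifted, "nitrate", control = ctl_open)
    if (a$status == "crossed") {
      expect_equal(b$depth_m, a$depth_m + 37)
    }
  }
})

test_that("Redfield-proportioned phosphate gives exactly equal crossing depths", {
  set.seed(11)
  for (i in 1:50) {
    depths <- sort(runif(8, 0, 400))
    no3 <- cumsum(abs(rnorm(8, 1, 1)))
    cast <- make_cast(depths, nitrate = no3, phosphate = no3 / 16)
    rec <- compute_nutriclines(cast, control = ctl_open)
    zn <- rec[rec$nutrient == "nitrate", ]
    zp <- rec[rec$nutrient == "phosphate", ]
    expect_identical(zp$status, zn$status)
    if (zn$status == "crossed") expect_identical(zp$depth_m, zn$depth_m)
  }
})

test_that("missing bottles are skipped, not treated as zero", {
  cast <- make_cast(c(0, 50, 100, 150),
                    nitrate = c(0.5, NA, 1.0, 5.0))
  rec <- compute_nutricline(cast, "nitrate", control = ctl_open)
  # bracket is (100 m, 1.0) -> (150 m, 5.0)
  expect_equal(rec$depth_m, 100 + 50 * (3 - 1) / (5 - 1))
})

test_that("nutrients are independent and sparse profiles are flagged", {
  cast <- make_cast(c(0, 50, 100, 250), nitrate = c(0.5, 1, 5, 9))
  rec <- compute_nutriclines(cast, control = ctl_open)
  expect_equal(rec$status[rec$nutrient == "nitrate"], "crossed")
  expect_equal(rec$status[rec$nutrient == "phosphate"], "insufficient_data")
  expect_true(is.na(rec$depth_m[rec$nutrient == "phosphate"]))

  one <- make_cast(100, nitrate = 5)
  expect_equal(compute_nutricline(one, "nitrate", control = ctl_open)$status,
               "insufficient_data")
  expect_error(compute_nutricline(cast, "silicate"), "unknown nutrient|arg")
})

test_that("the QC window rejects truncated casts under default control", {
  shallow <- make_cast(c(0, 50, 100), nitrate = c(0.5, 1.0, 5.0))
  rec <- compute_nutricline(shallow, "nitrate")  # deepest 100 m < 200 m
  expect_equal(rec$status, "insufficient_data")
  deep <- make_cast(c(0, 50, 100, 250), nitrate = c(0.5, 1.0, 5.0, 9))
  expect_equal(compute_nutricline(deep, "nitrate")$status, "crossed")
})

test_that("density is depth-independent in a homogeneous column", {
  cast <- make_cast(c(0, 100, 300), nitrate = 1,
                    temperature = 10, salinity = 35)
  d <- density_at_depth(cast, tibble::tibble(cast_id = "c1",
                                             depth_m = c(30, 200)))
  expect_equal(d$sigma[1], d$sigma[2])
  expect_equal(d$sigma[1], eos_linear()(10, 35))
})

test_that("density is never extrapolated outside the T/S span", {
  cast <- make_cast(c(50, 100), nitrate = 1, temperature = c(20, 10),
                    salinity = c(35, 34.8))
  d <- density_at_depth(cast, tibble::tibble(cast_id = "c1",
                                             depth_m = c(10, 75, 200)))
  expect_true(is.na(d$sigma[1]))
  expect_false(is.na(d$sigma[2]))
  expect_true(is.na(d$sigma[3]))
})

test_that("two-layer column yields the deep layer's density below the interface", {
  cast <- make_cast(c(0, 99, 101, 400), nitrate = 1,
                    temperature = c(20, 20, 5, 5),
                    salinity = c(35.5, 35.5, 34.7, 34.7))
  d <- density_at_depth(cast, tibble::tibble(cast_id = "c1", depth_m = 250))
  expect_equal(d$sigma, eos_linear()(5, 34.7))  # direct EOS call on layer 2
})

test_that("a pluggable equation of state is honoured", {
  cast <- make_cast(c(0, 200), nitrate = 1, temperature = c(20, 10),
                    salinity = 35)
  hook <- function(temperature, salinity) temperature * 0 + 99
  d <- density_at_depth(cast, tibble::tibble(cast_id = "c1", depth_m = 100),
                        eos = hook)
  expect_equal(d$sigma, 99)
})
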