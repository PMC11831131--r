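# In-code fixtures: tiny bottle tables in the canonical schema.

make_cast <- function(depths, nitrate = NA_real_, phosphate = NA_real_,
                      temperature = NA_real_, salinity = NA_real_,
                      cast_id = "c1", date = as.Date("2001-06-15"),
                      latitude = 30, longitude = -150) {
  tibble::tibble(
    cast_id = cast_id, date = date,
    latitude = latitude, longitude = longitude,
    depth_m = depths,
    nitrate_umol_kg = rep_len(nitrate, length(depths)),
    phosphate_umol_kg = rep_len(phosphate, length(depths)),
    temperature_c = rep_len(temperature, length(depths)),
    salinity_psu = rep_len(salinity, length(depths)),
    qc_flag = "good"
  )
}

# QC window disabled: lets tests exercise short illustrative profiles.
ctl_open <- nutriclinr::nutricline_control(min_samples = 2,
                                           window_max_depth = 500,
                                           min_deepest = 0)

# Independent crossing oracle: evaluate the piecewise-linear profile on a
# 0.01 m grid and return the first grid depth at/above the threshold.
oracle_crossing <- function(depths, conc, threshold, dz = 0.01) {
  ok <- !is.na(conc)
  depths <- depths[ok]; conc <- conc[ok]
  if (length(depths) < 2) return(NA_real_)
  grid <- seq(min(depths), max(depths), by = dz)
  cg <- approx(depths, conc, xout = grid, ties = mean)$y
  hit <- which(cg >= threshold)
  if (length(hit) == 0) return(NA_real_)
  grid[hit[1]]
}

# Minimal site-annual series builder for trend tests.
make_series <- function(years, depths, lat_bin = 10, lon_bin = 20,
                        nutrient = "nitrate", n_casts = 1) {
  tibble::tibble(
    lat_bin = lat_bin, lon_bin = lon_bin, nutrient = nutrient,
    year = years, mean_depth = depths, mean_depth_raw = depths,
    mean_sigma = NA_real_, n_casts = n_casts
  )
}

# Climatology from explicit site-month depths.
make_depth_clim <- function(df) {
  nutriclinr:::new_monthly_climatology(depths = df)
}
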