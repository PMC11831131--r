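#' Threshold concentrations defining the nutricline
#'
#' The nutricline is the depth at which a nutrient first reaches a
#' well-detected threshold concentration. `redfield_thresholds()` builds a
#' nitrate/phosphate pair in Redfield proportion (N:P = 16:1), the default
#' definition used throughout: a nitrate threshold of 3 umol/kg pairs with a
#' phosphate threshold of 3/16 umol/kg. `threshold_spec()` allows arbitrary
#' pairs for sensitivity analyses.
#'
#' @param nitrate Nitrate threshold, umol/kg (> 0).
#' @param phosphate Phosphate threshold, umol/kg (> 0).
#' @param id Short label carried into result tables; defaults to e.g. `"N3"`
#'   for a Redfield pair at 3 umol/kg nitrate.
#' @return A `threshold_spec` list with elements `nitrate`, `phosphate`,
#'   `id`, `redfield`.
#' @examples
#' redfield_thresholds(3)   # nitrate 3, phosphate 3/16
#' threshold_spec(nitrate = 3, phosphate = 0.2)
#' @export
redfield_thresholds <- function(nitrate = 3, id = paste0("N", format(nitrate))) {
  threshold_spec(nitrate = nitrate, phosphate = nitrate / 16, id = id)
}

#' @rdname redfield_thresholds
#' @export
threshold_spec <- function(nitrate, phosphate, id = paste0("N", format(nitrate))) {
  stopifnot(is.numeric(nitrate), nitrate > 0,
            is.numeric(phosphate), phosphate > 0)
  structure(
    list(nitrate = nitrate, phosphate = phosphate, id = id,
         redfield = isTRUE(all.equal(phosphate, nitrate / 16))),
    class = "threshold_spec"
  )
}

#' Quality-control window for nutricline eligibility
#'
#' A cast only yields a defined crossing when its profile actually resolves
#' the crossing. By default a cast is eligible for a nutrient when it has at
#' least `min_samples` non-missing values of that nutrient within the upper
#' `window_max_depth` metres and its deepest non-missing sample reaches
#' `min_deepest` metres; truncated casts otherwise produce spurious shallow
#' crossings. Set `min_samples = 2, min_deepest = 0` to disable the window
#' (two non-missing samples is the hard interpolation minimum).
#'
#' @param min_samples Minimum non-missing samples in the window (>= 2).
#' @param window_max_depth Window bottom, m.
#' @param min_deepest Minimum depth (m) the deepest non-missing sample must
#'   reach.
#' @return A `nutricline_control` list.
#' @export
nutricline_control <- function(min_samples = 3, window_max_depth = 500,
                               min_deepest = 200) {
  stopifnot(min_samples >= 2, window_max_depth > 0, min_deepest >= 0)
  structure(list(min_samples = min_samples,
                 window_max_depth = window_max_depth,
                 min_deepest = min_deepest),
            class = "nutricline_control")
}

nutrient_column <- function(nutrient) {
  switch(nutrient,
    nitrate = "nitrate_umol_kg",
    phosphate = "phosphate_umol_kg",
    abort(paste0("unknown nutrient: ", nutrient))
  )
}

# Vectorised first-crossing scan for one nutrient and one threshold over a
# whole bottle table. Returns one row per cast.
crossing_scan <- function(casts, nutrient, threshold, control) {
  col <- nutrient_column(nutrient)
  meta <- casts |>
    dplyr::distinct(.data$cast_id, .keep_all = TRUE) |>
    dplyr::transmute(
      .data$cast_id,
      latitude = .data$latitude, longitude = .data$longitude,
      date = .data$date,
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    )

  x <- casts[!is.na(casts[[col]]), c("cast_id", "depth_m", col)]
  names(x)[3] <- "conc"
  x <- x[order(x$cast_id, x$depth_m), ]

  id <- x$cast_id
  # per-cast eligibility under the QC window
  n_window <- rowsum((x$depth_m <= control$window_max_depth) + 0, id)
  deepest <- tapply(x$depth_m, id, max)
  eligible_ids <- rownames(n_window)[
    n_window[, 1] >= max(control$min_samples, 2) &
      deepest[rownames(n_window)] >= control$min_deepest
  ]

  first_row <- !duplicated(id)
  ge <- x$conc >= threshold
  idx_ge <- which(ge)
  idx_first <- idx_ge[!duplicated(id[idx_ge])]  # first crossing row per cast

  res <- tibble::tibble(cast_id = unique(id), depth = NA_real_,
                        status = "never_reached")
  hit_id <- id[idx_first]
  at_top <- first_row[idx_first]

  # surface-saturated: threshold already met at the shallowest sample
  sat <- idx_first[at_top]
  res$status[match(id[sat], res$cast_id)] <- "surface_saturated"
  res$depth[match(id[sat], res$cast_id)] <- x$depth_m[sat]

  # interior crossing: linear interpolation between the bracketing samples,
  # skipping missing values (already removed above)
  cr <- idx_first[!at_top]
  if (length(cr) > 0) {
    d1 <- x$depth_m[cr - 1L]; d2 <- x$depth_m[cr]
    c1 <- x$conc[cr - 1L];    c2 <- x$conc[cr]
    zc <- d1 + (threshold - c1) / (c2 - c1) * (d2 - d1)
    res$status[match(id[cr], res$cast_id)] <- "crossed"
    res$depth[match(id[cr], res$cast_id)] <- zc
  }

  ineligible <- !(res$cast_id %in% eligible_ids)
  res$status[ineligible] <- "insufficient_data"
  res$depth[ineligible] <- NA_real_

  # casts with zero non-missing samples never entered x
  all_ids <- unique(casts$cast_id)
  absent <- setdiff(all_ids, res$cast_id)
  if (length(absent) > 0) {
    res <- dplyr::bind_rows(
      res,
      tibble::tibble(cast_id = absent, depth = NA_real_,
                     status = "insufficient_data")
    )
  }

  dplyr::left_join(res, meta, by = "cast_id") |>
    dplyr::transmute(
      .data$cast_id, nutrient = nutrient, threshold = threshold,
      depth_m = .data$depth, status = .data$status,
      .data$latitude, .data$longitude, .data$year, .data$month
    )
}

#' Locate nutricline depths by threshold crossing
#'
#' For each cast and nutrient, scans the depth-sorted profile from the
#' shallowest sample downward and returns the depth of the first crossing of
#' the threshold concentration, obtained by linear interpolation between the
#' bracketing bottles (missing bottles are skipped, so the bracket uses the
#' nearest non-missing neighbours). If the shallowest sample already meets
#' the threshold the cast is `surface_saturated` and carries the shallowest
#' sample depth; if no sample reaches the threshold it is `never_reached`;
#' casts failing the QC window are `insufficient_data`. A depth is defined
#' iff the status is `crossed` or `surface_saturated`.
#'
#' @param casts Bottle tibble in the canonical schema (see [read_casts()]).
#' @param thresholds A [threshold_spec()] or list of them; one record per
#'   (cast, nutrient, spec) is returned.
#' @param nutrients Which nutrients to scan.
#' @param control QC window, see [nutricline_control()].
#' @return A tibble of nutricline records: `cast_id`, `nutrient`,
#'   `threshold`, `spec_id`, `depth_m`, `status`, `latitude`, `longitude`,
#'   `year`, `month`.
#' @examples
#' casts <- tibble::tibble(
#'   cast_id = "c1", date = as.Date("2001-06-15"),
#'   latitude = 30, longitude = -150,
#'   depth_m = c(0, 50, 100),
#'   nitrate_umol_kg = c(0.5, 1, 5), phosphate_umol_kg = c(0.5, 1, 5) / 16,
#'   temperature_c = NA_real_, salinity_psu = NA_real_, qc_flag = "good"
#' )
#' compute_nutriclines(casts,
#'   control = nutricline_control(min_samples = 2, min_deepest = 0))
#' @export
compute_nutriclines <- function(casts,
                                thresholds = redfield_thresholds(3),
                                nutrients = c("nitrate", "phosphate"),
                                control = nutricline_control()) {
  stopifnot(nrow(casts) > 0)
  if (inherits(thresholds, "threshold_spec")) thresholds <- list(thresholds)
  nutrients <- match.arg(nutrients, several.ok = TRUE)
  out <- purrr::map(thresholds, function(spec) {
    purrr::map(nutrients, function(nu) {
      crossing_scan(casts, nu, spec[[nu]], control) |>
        dplyr::mutate(spec_id = spec$id, .after = "threshold")
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  class(out) <- c("nutricline_records", class(out))
  out
}

#' @rdname compute_nutriclines
#' @param cast Bottle tibble holding a single cast.
#' @param nutrient Single nutrient id, `"nitrate"` or `"phosphate"`.
#' @param spec A single [threshold_spec()].
#' @export
compute_nutricline <- function(cast, nutrient, spec = redfield_thresholds(3),
                               control = nutricline_control()) {
  stopifnot(length(unique(cast$cast_id)) == 1)
  compute_nutriclines(cast, thresholds = spec, nutrients = nutrient,
                      control = control)
}

#' Linear equation of state for seawater density
#'
#' Density hooks take vectors of in-situ temperature (deg C) and practical
#' salinity and return a potential density anomaly (kg/m^3, referenced to
#' the surface). The built-in hook is the linear equation of state
#' rho = rho0 (1 - alpha (T - T0) + beta (S - S0)); any function with the
#' same signature (e.g. a TEOS-10 sigma-theta implementation) can be passed
#' wherever an `eos` argument appears.
#'
#' @param rho0 Reference density, kg/m^3.
#' @param alpha Thermal expansion coefficient, 1/K.
#' @param beta Haline contraction coefficient, 1/(g/kg).
#' @param t0,s0 Reference temperature and salinity.
#' @return A function `(temperature, salinity) -> sigma` (kg/m^3, anomaly
#'   relative to 1000).
#' @export
eos_linear <- function(rho0 = 1025, alpha = 2e-4, beta = 7.6e-4,
                       t0 = 10, s0 = 35) {
  function(temperature, salinity) {
    rho0 * (1 - alpha * (temperature - t0) + beta * (salinity - s0)) - 1000
  }
}

#' Seawater density at given depths within casts
#'
#' Interpolates temperature and salinity linearly to the requested depth
#' within each cast and evaluates the equation of state there. No
#' extrapolation: a depth above the shallowest or below the deepest T/S
#' sample, or a cast with fewer than two complete T/S samples, yields `NA`.
#'
#' @param casts Bottle tibble in the canonical schema.
#' @param at Tibble with columns `cast_id` and `depth_m` giving the target
#'   depths (e.g. nutricline records).
#' @param eos Equation-of-state hook, see [eos_linear()].
#' @return `at` with an added `sigma` column (kg/m^3).
#' @export
density_at_depth <- function(casts, at, eos = eos_linear()) {
  ts <- casts |>
    dplyr::filter(!is.na(.data$temperature_c), !is.na(.data$salinity_psu)) |>
    dplyr::arrange(.data$cast_id, .data$depth_m)
  ts_split <- split(ts[c("depth_m", "temperature_c", "salinity_psu")], ts$cast_id)
  sigma <- purrr::map2_dbl(at$cast_id, at$depth_m, function(id, z) {
    p <- ts_split[[id]]
    if (is.null(p) || nrow(p) < 2 || is.na(z)) return(NA_real_)
    if (z < min(p$depth_m) || z > max(p$depth_m)) return(NA_real_)
    tt <- approx(p$depth_m, p$temperature_c, xout = z, ties = mean)$y
    ss <- approx(p$depth_m, p$salinity_psu, xout = z, ties = mean)$y
    eos(tt, ss)
  })
  dplyr::mutate(at, sigma = sigma)
}

#' Attach density at the nutricline to nutricline records
#'
#' Convenience wrapper: evaluates [density_at_depth()] at each record's
#' crossing depth.
#'
#' @param records Nutricline record tibble from [compute_nutriclines()].
#' @param casts The bottle tibble the records came from.
#' @param eos Equation-of-state hook.
#' @return `records` with an added `sigma` column.
#' @export
add_density_at_nutricline <- function(records, casts, eos = eos_linear()) {
  density_at_depth(casts, records, eos = eos)
}
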