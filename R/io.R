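#' Column mapping and unit options for reading bottle-cast tables
#'
#' Cruise archives arrive with many column dialects. `cast_format()` maps the
#' file's columns onto the canonical schema used throughout the package and
#' records unit conventions. The canonical schema is one row per bottle with
#' columns `cast_id`, `date` (ISO 8601), `latitude`, `longitude`, `depth_m`,
#' `nitrate_umol_kg`, `phosphate_umol_kg`, `temperature_c`, `salinity_psu`,
#' `qc_flag`; empty cells are missing.
#'
#' @param columns Named character vector mapping canonical column names to
#'   the names used in the file. Only names that differ need to be given.
#' @param conc_unit Unit of the nutrient columns: `"umol_kg"` (canonical) or
#'   `"umol_l"`, converted by dividing by a nominal density of 1.025 kg/L.
#' @param depth_from_pressure If `TRUE`, the depth column holds pressure in
#'   dbar and is converted via `pressure_to_depth`.
#' @param pressure_to_depth Conversion hook, a function of (pressure_dbar,
#'   latitude) returning depth in m. The default assumes 1 dbar = 1 m.
#' @param keep_questionable Retain samples flagged `questionable`
#'   (default `TRUE`); samples flagged `bad` are always excluded.
#' @param qc_mapping Named character vector mapping raw flag values to the
#'   canonical categories `good`, `questionable`, `bad`. Unmapped values are
#'   treated as `good` (archives differ in flag vocabularies; the mapping is
#'   a declared convention, not inferred).
#' @return A `cast_format` list to pass to [read_casts()].
#' @export
cast_format <- function(columns = character(),
                        conc_unit = c("umol_kg", "umol_l"),
                        depth_from_pressure = FALSE,
                        pressure_to_depth = function(p, lat) p,
                        keep_questionable = TRUE,
                        qc_mapping = c(
                          "2" = "good", "0" = "good", "good" = "good",
                          "3" = "questionable", "questionable" = "questionable",
                          "4" = "bad", "9" = "bad", "bad" = "bad"
                        )) {
  conc_unit <- match.arg(conc_unit)
  structure(
    list(
      columns = columns, conc_unit = conc_unit,
      depth_from_pressure = depth_from_pressure,
      pressure_to_depth = pressure_to_depth,
      keep_questionable = keep_questionable,
      qc_mapping = qc_mapping
    ),
    class = "cast_format"
  )
}

canonical_cols <- c(
  "cast_id", "date", "latitude", "longitude", "depth_m",
  "nitrate_umol_kg", "phosphate_umol_kg",
  "temperature_c", "salinity_psu", "qc_flag"
)
required_cols <- c("cast_id", "date", "latitude", "longitude", "depth_m")

#' Read and validate a bottle-cast table
#'
#' Reads a delimited cast table, maps it onto the canonical schema, applies
#' the validation rules, and returns a tibble of bottles (one row per
#' bottle, casts identified by `cast_id`) sorted by cast and depth.
#'
#' Validation, in order: rows with unparseable dates or coordinates outside
#' latitude \[-90, 90\] are dropped; longitudes are normalised to
#' \[-180, 180); rows flagged `bad` (and, optionally, `questionable`) are
#' dropped; rows with missing or negative depth are dropped; negative
#' nutrient concentrations (below-detection artifacts) are set missing
#' rather than zero, so they do not bias interpolation; duplicate depths
#' within a cast are averaged into a single bottle. Every drop or edit is
#' counted in the ingest report attached as attribute `"ingest_report"`
#' (see [ingest_report()]), and kept + dropped row counts conserve.
#'
#' @param path Path to a CSV file in the canonical schema or a dialect
#'   described by `format`.
#' @param format A [cast_format()] describing column names and units.
#' @return A tibble of validated bottles with attribute `ingest_report`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "cast_id,date,latitude,longitude,depth_m,nitrate_umol_kg,phosphate_umol_kg",
#'   "c1,2001-06-15,30.2,-150.8,10,0.1,0.01",
#'   "c1,2001-06-15,30.2,-150.8,100,5.2,0.33"
#' ), f)
#' casts <- read_casts(f)
#' ingest_report(casts)
#' @export
read_casts <- function(path, format = cast_format()) {
  if (!file.exists(path)) {
    abort(paste0("cast file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  # apply the column mapping (canonical name -> file name)
  for (canon in names(format$columns)) {
    file_col <- format$columns[[canon]]
    if (!file_col %in% names(raw)) {
      abort(paste0("mapped column not in file: ", file_col, " (for ", canon, ")"))
    }
    names(raw)[names(raw) == file_col] <- canon
  }
  missing_req <- setdiff(required_cols, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0(
      "required columns missing from ", path, ": ",
      paste(missing_req, collapse = ", "),
      "; present: ", paste(names(raw), collapse = ", ")
    ))
  }
  for (col in setdiff(canonical_cols, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[canonical_cols]

  n_input <- nrow(raw)
  report <- list()

  num <- function(x) suppressWarnings(as.numeric(x))
  x <- tibble::tibble(
    cast_id = raw$cast_id,
    date = suppressWarnings(readr::parse_date(raw$date)),
    latitude = num(raw$latitude),
    longitude = num(raw$longitude),
    depth_m = num(raw$depth_m),
    nitrate_umol_kg = num(raw$nitrate_umol_kg),
    phosphate_umol_kg = num(raw$phosphate_umol_kg),
    temperature_c = num(raw$temperature_c),
    salinity_psu = num(raw$salinity_psu),
    qc_flag = raw$qc_flag
  )

  if (format$depth_from_pressure) {
    x$depth_m <- format$pressure_to_depth(x$depth_m, x$latitude)
  }
  if (format$conc_unit == "umol_l") {
    x$nitrate_umol_kg <- x$nitrate_umol_kg / 1.025
    x$phosphate_umol_kg <- x$phosphate_umol_kg / 1.025
  }

  # canonical qc categories; unmapped flags pass as good
  flag <- unname(format$qc_mapping[x$qc_flag])
  flag[is.na(flag)] <- "good"
  x$qc_flag <- flag

  drop <- function(x, bad, rule) {
    report[[rule]] <<- (report[[rule]] %||% 0L) + sum(bad)
    x[!bad, , drop = FALSE]
  }
  x <- drop(x, is.na(x$date), "unparseable_date")
  x <- drop(x, is.na(x$cast_id) | x$cast_id == "", "missing_cast_id")
  x <- drop(x, is.na(x$latitude) | is.na(x$longitude) |
              x$latitude < -90 | x$latitude > 90, "invalid_coordinates")
  x$longitude <- ((x$longitude + 180) %% 360) - 180
  x <- drop(x, x$qc_flag == "bad", "bad_flag")
  if (!format$keep_questionable) {
    x <- drop(x, x$qc_flag == "questionable", "questionable_flag")
  }
  x <- drop(x, is.na(x$depth_m) | x$depth_m < 0, "invalid_depth")

  neg_n <- !is.na(x$nitrate_umol_kg) & x$nitrate_umol_kg < 0
  neg_p <- !is.na(x$phosphate_umol_kg) & x$phosphate_umol_kg < 0
  report[["negative_concentration"]] <- sum(neg_n) + sum(neg_p)
  x$nitrate_umol_kg[neg_n] <- NA_real_
  x$phosphate_umol_kg[neg_p] <- NA_real_

  # collapse duplicate depths within a cast by averaging the measurements
  n_before <- nrow(x)
  x <- x |>
    dplyr::group_by(.data$cast_id, .data$depth_m) |>
    dplyr::summarise(
      date = dplyr::first(.data$date),
      latitude = dplyr::first(.data$latitude),
      longitude = dplyr::first(.data$longitude),
      dplyr::across(
        c("nitrate_umol_kg", "phosphate_umol_kg",
          "temperature_c", "salinity_psu"),
        ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)
      ),
      qc_flag = if (any(.data$qc_flag == "questionable")) "questionable" else "good",
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(canonical_cols)) |>
    dplyr::arrange(.data$cast_id, .data$depth_m)
  report[["duplicate_depth_merged"]] <- n_before - nrow(x)

  report[["rows_input"]] <- n_input
  report[["rows_kept"]] <- nrow(x)
  attr(x, "ingest_report") <- report
  x
}

#' Retrieve the ingest report from a cast table
#'
#' @param casts A bottle tibble returned by [read_casts()].
#' @return Named list of per-rule drop/edit counts plus input and kept row
#'   totals.
#' @export
ingest_report <- function(casts) {
  attr(casts, "ingest_report")
}

#' Write a cast table, or its ingest report, to disk
#'
#' `write_casts()` writes the canonical CSV dialect; reading it back with
#' [read_casts()] reproduces the same bottles (ingestion is idempotent).
#' `write_ingest_report()` writes the per-rule counts as JSON.
#'
#' @param casts A bottle tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_casts <- function(casts, path) {
  readr::write_csv(casts[canonical_cols], path, na = "")
  invisible(path)
}

#' @rdname write_casts
#' @export
write_ingest_report <- function(casts, path) {
  rep <- ingest_report(casts) %||% list()
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a gridded monthly climatology from long-format CSV
#'
#' The climatology dialect is a long CSV with columns `lat_bin`, `lon_bin`,
#' `month`, `nutrient`, `field`, `depth_m`, `value`. Rows with
#' `field = "nutricline_depth"` carry a scalar mean nutricline depth (m;
#' `depth_m` empty); rows with `field = "concentration"` carry a mean
#' concentration (umol/kg) at the standard depth `depth_m`. Either field may
#' be absent. A climatology holding concentration profiles supports the
#' deep-water bias diagnostic ([deep_anomaly_trend()]); one holding
#' nutricline depths supports [seasonal_anomaly()] and
#' [simulate_climatology_sampling()].
#'
#' @param path CSV path. (NetCDF grids should be exported to this long
#'   format; the reader is CSV-only.)
#' @return A `monthly_climatology` object with elements `depths` and
#'   `profiles` (tibbles or `NULL`).
#' @export
read_climatology <- function(path) {
  if (!file.exists(path)) abort(paste0("climatology file not found: ", path))
  if (grepl("\\.nc$", path)) {
    abort("NetCDF climatologies are not supported; export to the long-format CSV dialect (see ?read_climatology)")
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"month" %in% names(x)) abort("climatology file has no 'month' column")
  need <- c("lat_bin", "lon_bin", "month", "nutrient", "field", "value")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("climatology columns missing: ", paste(missing, collapse = ", ")))
  }
  if (!all(x$month %in% 1:12)) abort("climatology 'month' values must be 1-12")
  depths <- x |>
    dplyr::filter(.data$field == "nutricline_depth") |>
    dplyr::select("lat_bin", "lon_bin", "month", "nutrient",
                  clim_depth = "value")
  profiles <- x |>
    dplyr::filter(.data$field == "concentration") |>
    dplyr::select("lat_bin", "lon_bin", "month", "nutrient", "depth_m",
                  concentration = "value") |>
    dplyr::arrange(.data$lat_bin, .data$lon_bin, .data$nutrient,
                   .data$month, .data$depth_m)
  new_monthly_climatology(
    depths = if (nrow(depths) > 0) depths else NULL,
    profiles = if (nrow(profiles) > 0) profiles else NULL
  )
}

new_monthly_climatology <- function(depths = NULL, profiles = NULL) {
  structure(list(depths = depths, profiles = profiles),
            class = "monthly_climatology")
}

#' @export
print.monthly_climatology <- function(x, ...) {
  cat("<monthly_climatology>\n")
  if (!is.null(x$depths)) {
    cat("  nutricline depths:", nrow(x$depths), "site-month values\n")
  }
  if (!is.null(x$profiles)) {
    cat("  concentration profiles:", nrow(x$profiles), "site-month-depth values\n")
  }
  invisible(x)
}

#' Write a monthly climatology to the long-format CSV dialect
#'
#' @param clim A `monthly_climatology`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climatology <- function(clim, path) {
  parts <- list()
  if (!is.null(clim$depths)) {
    parts$d <- clim$depths |>
      dplyr::mutate(field = "nutricline_depth", depth_m = NA_real_) |>
      dplyr::rename(value = "clim_depth")
  }
  if (!is.null(clim$profiles)) {
    parts$p <- clim$profiles |>
      dplyr::mutate(field = "concentration") |>
      dplyr::rename(value = "concentration")
  }
  if (length(parts) == 0) abort("empty climatology")
  out <- dplyr::bind_rows(parts) |>
    dplyr::select("lat_bin", "lon_bin", "month", "nutrient", "field",
                  "depth_m", "value")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Look up climatological nutricline depth at a site and month
#'
#' Missing grid cells resolve to `NA`, never to zero.
#'
#' @param clim A `monthly_climatology` with a `depths` component.
#' @param lat_bin,lon_bin,month,nutrient Vectors (recycled) identifying the
#'   lookups.
#' @return Numeric vector of climatological depths (m), `NA` where the cell
#'   is absent.
#' @export
clim_lookup <- function(clim, lat_bin, lon_bin, month, nutrient) {
  if (is.null(clim$depths)) abort("climatology has no nutricline-depth field")
  q <- tibble::tibble(lat_bin = lat_bin, lon_bin = lon_bin,
                      month = month, nutrient = nutrient)
  dplyr::left_join(q, clim$depths,
                   by = c("lat_bin", "lon_bin", "month", "nutrient"))$clim_depth
}
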