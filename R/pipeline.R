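#' Assemble a pipeline configuration
#'
#' The whole analysis can be driven by a single configuration: either a
#' YAML file path or a nested list with the same structure. Recognised
#' entries (all optional, with the package defaults shown by
#' `pipeline_config()`): `input$casts`, `input$climatology` (paths; omitted
#' when the `simulate` stage generates them), `thresholds` (list of
#' `nitrate` values, `redfield = TRUE` pairs phosphate at /16), `filters`
#' (`min_depth`, `lat_range`, `trend_bounds`), `counts` (`n_bootstrap`,
#' `n_randomizations`), `error` (`nitrate_sd`, `phosphate_sd`), `simulate`
#' (arguments for [synthetic_world()]), `seed`, and `output_dir`.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    input = list(casts = NULL, climatology = NULL),
    thresholds = list(nitrate = 3, redfield = TRUE),
    filters = list(min_depth = 50, lat_range = c(-45, 45),
                   trend_bounds = c(-Inf, Inf)),
    counts = list(n_bootstrap = 10000, n_randomizations = 10000),
    error = list(nitrate_sd = 0.8, phosphate_sd = 0.1),
    qc = list(min_samples = 3, window_max_depth = 500, min_deepest = 200),
    simulate = list(),
    seed = 1L,
    output_dir = "nutriclinr-output"
  )
  cfg <- utils::modifyList(defaults, config)
  with(cfg, stopifnot(
    counts$n_bootstrap > 0, counts$n_randomizations > 0,
    filters$min_depth >= 0, length(filters$lat_range) == 2,
    error$nitrate_sd >= 0, error$phosphate_sd >= 0
  ))
  for (p in Filter(Negate(is.null), cfg$input)) {
    if (!file.exists(p)) abort(paste0("configured input does not exist: ", p))
  }
  structure(cfg, class = "pipeline_config")
}

stage_outputs <- list(
  simulate = c("casts.csv", "truth.csv", "climatology.csv"),
  nutricline = "records.csv",
  aggregate = "series.csv",
  trends = c("site_trends.csv", "summaries.json"),
  nulls = "nulls.json",
  report = "manifest.json"
)

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (synthetic archive + climatology),
#' `nutricline` (threshold crossings), `aggregate` (site-annual series with
#' eligibility filters), `trends` (site trends, global regressions, median
#' summaries), `nulls` (scrambled-year MToRP), and `report` (manifest),
#' writing every artifact as CSV/JSON under `config$output_dir` together
#' with a machine-readable `manifest.json` (config hash, seed, package
#' version, per-stage row counts and status). A stage whose input artifact
#' is missing fails with an error naming it; when a stage fails, downstream
#' stages are skipped and the manifest records the failure.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param stages Character subset of stages to run, in pipeline order.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "nutricline", "aggregate",
                                    "trends", "nulls", "report")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "output_dir")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("nutriclinr")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  failed <- FALSE

  need <- function(f) {
    p <- out(f)
    if (!file.exists(p)) {
      abort(paste0("missing upstream artifact: ", p,
                   " (run the producing stage first)"))
    }
    p
  }
  thresholds <- if (isTRUE(config$thresholds$redfield)) {
    purrr::map(config$thresholds$nitrate, redfield_thresholds)
  } else {
    purrr::map(config$thresholds$nitrate,
               ~ threshold_spec(.x, config$thresholds$phosphate))
  }
  control <- do.call(nutricline_control, config$qc)

  run_stage <- function(name, fn) {
    if (!(name %in% stages) || failed) {
      if (name %in% stages && failed) {
        manifest$stages[[name]] <<- list(status = "skipped")
      }
      return(invisible(NULL))
    }
    res <- tryCatch(
      list(status = "ok", counts = fn()),
      error = function(e) {
        failed <<- TRUE
        inform(paste0("stage '", name, "' failed: ", conditionMessage(e)))
        list(status = "failed", error = conditionMessage(e))
      }
    )
    manifest$stages[[name]] <<- res
  }

  run_stage("simulate", function() {
    cfg <- config$simulate
    cfg$seed <- cfg$seed %||% config$seed
    world <- do.call(synthetic_world, cfg)
    arc <- generate_archive(world)
    write_casts(arc$casts, out("casts.csv"))
    readr::write_csv(arc$truth, out("truth.csv"))
    write_climatology(generate_climatology(world), out("climatology.csv"))
    list(casts = nrow(arc$casts), truth = nrow(arc$truth))
  })

  run_stage("nutricline", function() {
    path <- config$input$casts %||% need("casts.csv")
    casts <- read_casts(path)
    rec <- compute_nutriclines(casts, thresholds = thresholds,
                               control = control)
    readr::write_csv(rec, out("records.csv"))
    list(records = nrow(rec))
  })

  run_stage("aggregate", function() {
    rec <- readr::read_csv(need("records.csv"), show_col_types = FALSE)
    ser <- annual_average(rec) |>
      filter_trend_eligible(min_depth = config$filters$min_depth,
                            lat_range = config$filters$lat_range)
    readr::write_csv(ser, out("series.csv"))
    list(series = nrow(ser))
  })

  run_stage("trends", function() {
    ser <- readr::read_csv(need("series.csv"), show_col_types = FALSE)
    tr <- fit_site_trends(ser) |>
      filter_extreme_trends(config$filters$trend_bounds)
    readr::write_csv(tr, out("site_trends.csv"))
    summaries <- list(
      global_regression = fit_global_regression(ser),
      medians = tr |>
        dplyr::group_by(.data$nutrient,
                        dplyr::across(dplyr::any_of("spec_id"))) |>
        dplyr::group_modify(~ tidy(median_with_bootstrap_ci(
          .x$slope, n_bootstrap = config$counts$n_bootstrap,
          seed = config$seed
        ))) |>
        dplyr::ungroup(),
      sign_tests = tr |>
        dplyr::group_by(.data$nutrient,
                        dplyr::across(dplyr::any_of("spec_id"))) |>
        dplyr::group_modify(~ sign_test(.x$slope)) |>
        dplyr::ungroup()
    )
    jsonlite::write_json(summaries, out("summaries.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(site_trends = nrow(tr))
  })

  run_stage("nulls", function() {
    ser <- readr::read_csv(need("series.csv"), show_col_types = FALSE)
    nulls <- ser |>
      dplyr::group_by(.data$nutrient,
                      dplyr::across(dplyr::any_of("spec_id"))) |>
      dplyr::group_modify(function(d, key) {
        m <- scramble_years(
          dplyr::mutate(d, nutrient = "x"),
          n_randomizations = config$counts$n_randomizations,
          seed = config$seed
        )
        tibble::tibble(observed_median = m$observed_median,
                       p_value = m$p_value,
                       n_randomizations = m$n_randomizations)
      }) |>
      dplyr::ungroup()
    jsonlite::write_json(nulls, out("nulls.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(nulls = nrow(nulls))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if ("report" %in% stages) {
    manifest$stages$report <- list(status = if (failed) "skipped" else "ok")
  }
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
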