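#' Load and validate a run configuration
#'
#' A run is fully reproducible from its YAML configuration plus the seed it
#' names. Two modes exist: `"simulate"` runs the full
#' simulate-process-align-fit-quantify pipeline; `"worked_example"` feeds
#' printed apparent concentrations straight into the co-dilution and
#' aggregation stages (the demo configuration shipped under
#' `inst/extdata/` reproduces the 6 ppm example that way).
#'
#' Unknown fields are rejected by name, so typos never pass silently.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with defaults filled in.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname load_run_config
#' @param config A named list as read from YAML.
#' @export
validate_run_config <- function(config) {
  known <- list(
    seed = NULL, mode = NULL, contaminant = NULL, reference = NULL,
    simulation = c("n_animals", "calibration_dilutions_log10",
                   "sample_dilutions_log10", "true_fraction_log10",
                   "noise_sd", "gain_sdlog"),
    analysis = c("window_halfwidth", "detection_mult", "search_window",
                 "mask_from"),
    worked_example = NULL
  )
  bad <- setdiff(names(config), names(known))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (section in c("simulation", "analysis")) {
    bad <- setdiff(names(config[[section]]), known[[section]])
    if (length(bad)) {
      stop("unknown config field(s): ",
           paste(paste0(section, ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  defaults <- list(
    seed = 1L,
    mode = "simulate",
    contaminant = "ethyl_acetate",
    reference = "ethyl_butyrate",
    simulation = list(
      n_animals = 3L,
      calibration_dilutions_log10 = seq(-10, -2),
      sample_dilutions_log10 = c(-2, -1),
      true_fraction_log10 = -5.2,
      noise_sd = 0.006,
      gain_sdlog = 0.2
    ),
    analysis = list(window_halfwidth = 10, detection_mult = 2,
                    search_window = 30, mask_from = "metadata"),
    worked_example = NULL
  )
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!out$mode %in% c("simulate", "worked_example")) {
    stop("mode must be 'simulate' or 'worked_example'", call. = FALSE)
  }
  if (out$mode == "worked_example") {
    if (is.null(out$worked_example) || length(out$worked_example) == 0L) {
      stop("worked_example mode needs a worked_example measurement list",
           call. = FALSE)
    }
    for (m in out$worked_example) {
      if (!all(c("apparent_c", "sample_dilution") %in% names(m))) {
        stop("each worked_example entry needs apparent_c and sample_dilution",
             call. = FALSE)
      }
    }
  }
  structure(out, class = "run_config")
}

#' Run the configured pipeline
#'
#' Executes every stage the configuration asks for and returns a plain,
#' JSON-serializable report: configuration echo, alignment offset,
#' calibration dose-response table and logistic parameters, per-dilution
#' measurements, the aggregate impurity estimate on all three scales, and
#' flags. The same config and seed always produce the identical report.
#'
#' @param config A `run_config` from [load_run_config()] /
#'   [validate_run_config()].
#' @return A named list (the report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "worked_example") {
    meas <- tibble::tibble(
      apparent_c = purrr::map_dbl(config$worked_example, "apparent_c"),
      sample_dilution = purrr::map_dbl(config$worked_example,
                                       "sample_dilution")
    ) |>
      dplyr::mutate(
        relative_fraction_log10 = relative_fraction(.data$apparent_c,
                                                    .data$sample_dilution)
      )
    est <- aggregate_impurity(meas)
    return(list(
      mode = "worked_example",
      measurements = as.data.frame(meas),
      estimate = estimate_fields(est),
      verdict = "quantified"
    ))
  }

  lib <- substance_library()
  if (!config$contaminant %in% names(lib)) {
    stop("unknown contaminant: ", config$contaminant, call. = FALSE)
  }
  if (!config$reference %in% names(lib)) {
    stop("unknown reference: ", config$reference, call. = FALSE)
  }
  sim <- config$simulation
  trials <- simulate_experiment(
    n_animals = sim$n_animals,
    calibration_dilutions = 10^sim$calibration_dilutions_log10,
    sample_dilutions = 10^sim$sample_dilutions_log10,
    fraction = 10^sim$true_fraction_log10,
    library = lib,
    noise_sd = sim$noise_sd,
    gain_sdlog = sim$gain_sdlog,
    seed = config$seed
  )
  an <- config$analysis
  report <- quantify_impurity(
    trials, lib[[config$contaminant]], lib[[config$reference]],
    window_halfwidth = an$window_halfwidth,
    detection_mult = an$detection_mult,
    search_window = an$search_window,
    mask_from = an$mask_from
  )
  list(
    mode = "simulate",
    seed = config$seed,
    contaminant = config$contaminant,
    reference = config$reference,
    true_fraction_log10 = sim$true_fraction_log10,
    alignment_offset_s = report$alignment$offset,
    rt_check_s = report$rt_check,
    reference_amplitudes = as.data.frame(report$reference_amplitudes),
    calibration = as.data.frame(report$calibration),
    fit = list(Rmax = report$fit$Rmax, EC50 = report$fit$EC50,
               h = report$fit$h, rss = report$fit$rss),
    noise_sd = report$noise_sd,
    measurements = as.data.frame(report$measurements),
    estimate = if (is.null(report$estimate)) NULL
               else estimate_fields(report$estimate),
    verdict = report$verdict,
    dilution_spread_log10 = report$dilution_spread_log10
  )
}

#' @keywords internal
estimate_fields <- function(est) {
  list(
    fraction = est$fraction,
    fraction_log10 = est$fraction_log10,
    ppm = est$ppm,
    percent = est$percent,
    display_fraction_log10 = est$display$fraction_log10,
    display_ppm = est$display$ppm,
    display_percent = est$display$percent
  )
}

#' Write and re-read a pipeline report
#'
#' Reports are JSON. Writing goes through a temporary file renamed into
#' place, so a failed (partial) write never clobbers a complete report.
#'
#' @param report A report list from [run_pipeline()].
#' @param path Output path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   report list.
#' @export
write_report <- function(report, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.part")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
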