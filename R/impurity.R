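#' Average several traces sample-by-sample
#'
#' Traces must share one time grid (the across-animal mean of aligned
#' trials).
#'
#' @param traces List of `ca_trace` objects on identical grids.
#' @return A `ca_trace` holding the pointwise mean.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (nrow(tr) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop("traces must share one time grid", call. = FALSE)
    }
  }
  vals <- rowMeans(do.call(cbind, purrr::map(traces, "value")))
  set_trace_values(traces[[1]], vals)
}

#' Apparent concentration of a contaminant from its response
#'
#' Inverts the calibration curve for a measured normalized response, with
#' detection guards: responses below `detection_mult` times the noise SD
#' are flagged `"not_detected"` (no concentration is reported), responses
#' at or above `saturation_frac * Rmax` are flagged `"saturated"` and later
#' excluded from aggregation rather than clipped.
#'
#' @param fit A `logistic_fit` calibration.
#' @param response Measured normalized amplitude.
#' @param noise_sd Noise SD of the measurement, normalized units.
#' @param detection_mult Detection threshold in noise SDs (default 2).
#' @param saturation_frac Fraction of `Rmax` treated as saturated.
#' @return A one-row tibble: `response`, `apparent_c` (log10 dilution, `NA`
#'   when flagged), `flag` (`"ok"`, `"not_detected"`, `"saturated"`).
#' @export
apparent_concentration <- function(fit, response, noise_sd = 0,
                                   detection_mult = 2,
                                   saturation_frac = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  flag <- dplyr::case_when(
    response <= 0 | response < detection_mult * noise_sd ~ "not_detected",
    response >= saturation_frac * fit$Rmax ~ "saturated",
    TRUE ~ "ok"
  )
  apparent_c <- ifelse(flag == "ok",
                       purrr::map_dbl(response, function(r) {
                         if (r <= 0 || r >= fit$Rmax) return(NA_real_)
                         invert_logistic(fit, r)
                       }),
                       NA_real_)
  tibble::tibble(response = response, apparent_c = apparent_c, flag = flag)
}

#' Relative contaminant fraction from an apparent concentration
#'
#' A contaminant co-dilutes with its sample, so its relative fraction in
#' the neat sample is the apparent delivered concentration divided by the
#' sample dilution -- a subtraction on the log10 axis.
#'
#' @param apparent_c Apparent contaminant concentration, log10 dilution.
#' @param sample_dilution Sample dilution, log10 (e.g. -2).
#' @return Relative fraction, log10 (negative for a trace contaminant).
#' @export
#' @examples
#' relative_fraction(-7.4, -2) # -5.4
#' relative_fraction(-6.1, -1) # -5.1
relative_fraction <- function(apparent_c, sample_dilution) {
  apparent_c - sample_dilution
}

#' Aggregate per-dilution impurity measurements
#'
#' The aggregate fraction is the arithmetic mean of the linear per-dilution
#' fractions `10^relative_fraction_log10`, reported on all three scales
#' (log10, ppm, percent; `ppm = fraction * 1e6`, `percent = fraction *
#' 100`). Display values round the log10 fraction to one decimal and
#' ppm/percent to one significant figure; full-precision values are always
#' retained.
#'
#' @param measurements A data frame with a `relative_fraction_log10` column
#'   (rows flagged other than `"ok"` in a `flag` column are excluded), or a
#'   bare numeric vector of log10 fractions.
#' @return An object of class `impurity_estimate`.
#' @export
#' @examples
#' est <- aggregate_impurity(c(-5.4, -5.1))
#' est$display$fraction_log10 # -5.2
#' est$display$ppm            # 6
aggregate_impurity <- function(measurements) {
  if (is.numeric(measurements)) {
    measurements <- tibble::tibble(relative_fraction_log10 = measurements)
  }
  stopifnot("relative_fraction_log10" %in% names(measurements))
  if ("flag" %in% names(measurements)) {
    measurements <- dplyr::filter(measurements, .data$flag == "ok")
  }
  measurements <- dplyr::filter(measurements,
                                is.finite(.data$relative_fraction_log10))
  if (nrow(measurements) == 0L) {
    stop("no usable measurements to aggregate", call. = FALSE)
  }
  fraction <- mean(10^measurements$relative_fraction_log10)
  structure(
    list(
      measurements = tibble::as_tibble(measurements),
      fraction = fraction,
      fraction_log10 = log10(fraction),
      ppm = fraction * 1e6,
      percent = fraction * 100,
      display = list(
        fraction_log10 = round(log10(fraction), 1),
        ppm = signif(fraction * 1e6, 1),
        percent = signif(fraction * 100, 1)
      )
    ),
    class = "impurity_estimate"
  )
}

#' @export
print.impurity_estimate <- function(x, ...) {
  cat(sprintf(
    "<impurity_estimate> fraction 10^%.1f  (%g ppm, %g%%)  from %d measurement(s)\n",
    x$display$fraction_log10, x$display$ppm, x$display$percent,
    nrow(x$measurements)
  ))
  cat(sprintf("  full precision: fraction=%.6g, log10=%.4f\n",
              x$fraction, x$fraction_log10))
  invisible(x)
}

#' @export
tidy.impurity_estimate <- function(x, ...) {
  x$measurements
}

#' @export
glance.impurity_estimate <- function(x, ...) {
  tibble::tibble(
    fraction = x$fraction, fraction_log10 = x$fraction_log10,
    ppm = x$ppm, percent = x$percent,
    n_measurements = nrow(x$measurements)
  )
}

#' Quantify a trace contaminant from calibration and sample trials
#'
#' Runs the full analysis on a trial set (e.g. from
#' [simulate_experiment()]): per-trial bleach correction and
#' \eqn{\Delta F/F}; FID/imaging channel alignment on the contaminant's
#' calibration peak; per-animal normalization to the first reference peak
#' (ethyl butyrate protocol); across-animal trace averaging; response
#' measurement in the contaminant's aligned elution window; logistic
#' calibration fit; inverse read-off of the apparent concentration at each
#' sample dilution; co-dilution conversion to a relative fraction; and
#' aggregation to a single impurity estimate.
#'
#' @param trials A tibble of trials with columns `animal`, `role`
#'   (`"reference"`, `"calibration"`, `"sample"`), `dilution_log10`, and
#'   list columns `fluor`, `fid`, `ground_truth` (ground truth optional:
#'   only its response-window masks are used when `mask_from =
#'   "metadata"`).
#' @param contaminant `substance_spec` of the contaminant (also the
#'   alignment reference substance).
#' @param reference `substance_spec` of the calibration reference odorant
#'   (its first response peak, i.e. the contaminant's elution window within
#'   the reference trial, normalizes responses across animals).
#' @param window_halfwidth Response window half-width, seconds.
#' @param detection_mult Detection threshold in noise SDs.
#' @param search_window Alignment search half-window, seconds.
#' @param mask_from `"metadata"` (use the trial's recorded response
#'   windows for the bleach fit) or `"auto"` (iterative residual masking).
#' @param smooth_sd Gaussian smoothing SD (s) applied to traces before
#'   amplitude measurement (see [gaussian_smooth()]); applied identically
#'   to the reference, calibration and sample measurements, so the common
#'   amplitude shape factor cancels. `0` disables smoothing.
#' @return An object of class `impurity_report`: list with `alignment`,
#'   `reference_amplitudes`, `calibration` (dose-response tibble), `fit`
#'   (`logistic_fit`), `noise_sd`, `measurements` (per sample dilution),
#'   `estimate` (`impurity_estimate`, `NULL` when nothing was detected),
#'   `verdict`, `dilution_spread_log10`, `rt_check`.
#' @export
quantify_impurity <- function(trials, contaminant, reference,
                              window_halfwidth = 10, detection_mult = 2,
                              search_window = 30,
                              mask_from = c("metadata", "auto"),
                              smooth_sd = 2) {
  mask_from <- match.arg(mask_from)
  stopifnot(is.data.frame(trials),
            all(c("animal", "role", "dilution_log10", "fluor") %in%
                  names(trials)))
  if (diff(range(trials$dilution_log10[trials$role == "calibration"])) < 2) {
    stop("[calibration] trials must span at least 2 log10 units",
         call. = FALSE)
  }
  if (!any(trials$role == "sample")) {
    stop("[sample] no sample trials provided", call. = FALSE)
  }

  # --- stage: trace processing (bleach fit, correction, dF/F) ------------
  processed <- trials |>
    dplyr::mutate(
      dff = purrr::map2(.data$fluor, .data$ground_truth, function(tr, gt) {
        mask <- if (mask_from == "metadata" && !is.null(gt)) {
          gt$response_windows
        } else {
          NULL
        }
        bw <- if (!is.null(gt)) gt$baseline_window else NULL
        tryCatch(process_trace(tr, mask = mask, baseline_window = bw)$dff,
                 error = function(e) {
                   stop("[trace_processing] ", conditionMessage(e),
                        call. = FALSE)
                 })
      })
    )

  # --- stage: channel alignment on the top calibration dilution ----------
  calib <- dplyr::filter(processed, .data$role == "calibration")
  top <- dplyr::filter(calib,
                       .data$dilution_log10 == max(.data$dilution_log10))
  mean_dff_raw <- average_traces(top$dff)
  mean_dff_top <- gaussian_smooth(mean_dff_raw, smooth_sd)
  mean_fid_top <- average_traces(top$fid)
  align <- tryCatch(
    calibrate_alignment(
      detect_peaks(mean_fid_top),
      # detect on the measurement-smoothed trace, but threshold on the raw
      # trace's noise scale (the smoothed trace underestimates its own SD
      # through first differences)
      detect_peaks(mean_dff_top, polarity = "both",
                   min_prominence = 3 * robust_noise_sd(mean_dff_raw)),
      contaminant, search_window = search_window
    ),
    error = function(e) stop("[alignment] ", conditionMessage(e),
                             call. = FALSE)
  )
  rt_check <- align$fid_apex - contaminant$retention_time

  # --- stage: per-animal normalization to the reference first peak -------
  ref_trials <- dplyr::filter(processed, .data$role == "reference")
  ref_amps <- ref_trials |>
    dplyr::mutate(
      reference_amplitude = purrr::map_dbl(
        .data$dff,
        ~ measure_response(gaussian_smooth(.x, smooth_sd), contaminant,
                           align, window_halfwidth)$amplitude)
    ) |>
    dplyr::select("animal", "reference_amplitude")
  if (any(ref_amps$reference_amplitude <= 0)) {
    stop("[normalization] non-positive reference amplitude", call. = FALSE)
  }
  processed <- processed |>
    dplyr::left_join(ref_amps, by = "animal") |>
    dplyr::mutate(dff = purrr::map2(.data$dff, .data$reference_amplitude,
                                    normalize_to_reference))

  # --- stage: dose-response calibration ----------------------------------
  per_point <- function(rows) {
    amps <- purrr::map_dbl(rows$dff, ~ measure_response(
      gaussian_smooth(.x, smooth_sd), contaminant, align,
      window_halfwidth)$amplitude)
    mean_tr <- average_traces(rows$dff)
    tibble::tibble(
      response = measure_response(gaussian_smooth(mean_tr, smooth_sd),
                                  contaminant, align,
                                  window_halfwidth)$amplitude,
      n_animals = nrow(rows),
      sem = if (nrow(rows) > 1) stats::sd(amps) / sqrt(nrow(rows)) else NA,
      mean_trace = list(mean_tr)
    )
  }
  calibration <- processed |>
    dplyr::filter(.data$role == "calibration") |>
    dplyr::group_by(c = .data$dilution_log10) |>
    dplyr::group_modify(~ per_point(.x)) |>
    dplyr::ungroup()
  fit <- tryCatch(
    fit_logistic(dplyr::select(calibration, -"mean_trace")),
    error = function(e) stop("[dose_response] ", conditionMessage(e),
                             call. = FALSE)
  )

  # --- stage: sample read-off --------------------------------------------
  samples <- processed |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::group_by(sample_dilution = .data$dilution_log10) |>
    dplyr::group_modify(~ per_point(.x)) |>
    dplyr::ungroup()
  # detection threshold scale: robust noise SD of the bleach-corrected
  # dF/F baseline (the unsmoothed across-animal mean trace)
  noise_sd <- stats::median(
    purrr::map_dbl(samples$mean_trace, robust_noise_sd))
  measurements <- samples |>
    dplyr::select(-"mean_trace") |>
    dplyr::bind_cols(
      apparent_concentration(fit, samples$response, noise_sd,
                             detection_mult)[, c("apparent_c", "flag")]
    ) |>
    dplyr::mutate(
      relative_fraction_log10 = relative_fraction(.data$apparent_c,
                                                  .data$sample_dilution)
    )
  ok <- measurements$flag == "ok"
  estimate <- if (any(ok)) aggregate_impurity(measurements) else NULL
  spread <- if (sum(ok) > 1) {
    diff(range(measurements$relative_fraction_log10[ok]))
  } else {
    NA_real_
  }

  structure(
    list(
      alignment = align,
      reference_amplitudes = ref_amps,
      calibration = dplyr::select(calibration, -"mean_trace"),
      fit = fit,
      noise_sd = noise_sd,
      measurements = dplyr::select(measurements, -dplyr::any_of("response1")),
      estimate = estimate,
      verdict = if (is.null(estimate)) "not detected" else "quantified",
      dilution_spread_log10 = spread,
      rt_check = rt_check,
      contaminant = contaminant$name,
      reference = reference$name,
      params = list(window_halfwidth = window_halfwidth,
                    detection_mult = detection_mult,
                    search_window = search_window,
                    mask_from = mask_from,
                    smooth_sd = smooth_sd)
    ),
    class = "impurity_report"
  )
}

#' @export
print.impurity_report <- function(x, ...) {
  cat(sprintf("<impurity_report> contaminant=%s  reference=%s  verdict=%s\n",
              x$contaminant, x$reference, x$verdict))
  cat(sprintf("  alignment offset %.2f s; calibration EC50 10^%.2f (Rmax %.2f, h %.2f)\n",
              x$alignment$offset, x$fit$EC50, x$fit$Rmax, x$fit$h))
  print(x$measurements)
  if (!is.null(x$estimate)) print(x$estimate)
  invisible(x)
}

#' @export
tidy.impurity_report <- function(x, ...) {
  x$measurements
}

#' @export
glance.impurity_report <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    fraction_log10 = if (is.null(x$estimate)) NA_real_
                     else x$estimate$fraction_log10,
    ppm = if (is.null(x$estimate)) NA_real_ else x$estimate$ppm,
    EC50 = x$fit$EC50, Rmax = x$fit$Rmax, h = x$fit$h,
    alignment_offset = x$alignment$offset,
    dilution_spread_log10 = x$dilution_spread_log10,
    rt_check = x$rt_check
  )
}
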