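#' @keywords internal
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Merge overlapping windows into a disjoint mask
#' @keywords internal
merge_windows <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L) return(windows)
  windows <- dplyr::arrange(windows, .data$start)
  out <- windows[1, ]
  for (i in seq_len(nrow(windows))[-1]) {
    j <- nrow(out)
    if (windows$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], windows$end[i])
      if (nzchar(windows$label[i])) {
        out$label[j] <- paste(out$label[j], windows$label[i], sep = "+")
      }
    } else {
      out <- dplyr::bind_rows(out, windows[i, ])
    }
  }
  out
}

#' Simulate a GC-FID chromatogram for a sample
#'
#' Each substance elutes as a symmetric Gaussian centred on its retention
#' time; the apex height is `fid_response_factor * amount` where the
#' delivered amount of the main substance is the sample dilution and a
#' contaminant's amount co-dilutes as `relative_fraction * dilution`.
#' Additive Gaussian noise emulates detector noise.
#'
#' @param sample A [sample_spec()].
#' @param acq An [acquisition_spec()] with `mode = "gc_coupled"`.
#' @return A list with `trace` (a `ca_trace`, channel `"fid"`) and
#'   `ground_truth` (tibble: `name`, `apex_time`, `apex_height`, `amount`).
#' @export
simulate_fid_trace <- function(sample, acq = acquisition_spec()) {
  stopifnot(inherits(sample, "sample_spec"),
            inherits(acq, "acquisition_spec"))
  if (acq$mode != "gc_coupled") {
    stop("FID traces require gc_coupled acquisition", call. = FALSE)
  }
  amounts <- sample_amounts(sample)
  if (any(amounts$amount < 0)) {
    stop("negative delivered amount", call. = FALSE)
  }
  t <- acq_times(acq)
  signal <- rep(0, length(t))
  gt <- amounts |>
    dplyr::mutate(
      apex_time = purrr::map_dbl(.data$substance, "retention_time"),
      apex_height = purrr::map_dbl(.data$substance, "fid_response_factor") *
        .data$amount
    )
  for (i in seq_len(nrow(gt))) {
    s <- gt$substance[[i]]
    signal <- signal + gt$apex_height[i] *
      exp(-(t - s$retention_time)^2 / (2 * s$elution_width^2))
  }
  signal <- maybe_with_seed(acq$seed,
    signal + stats::rnorm(length(t), 0, acq$fid_noise_sd))
  list(
    trace = new_trace(t, signal, rate = acq$rate, channel = "fid",
                      meta = list(mode = acq$mode)),
    ground_truth = dplyr::select(gt, "name", "apex_time", "apex_height",
                                 "amount")
  )
}

#' Simulate a single response kernel on an acquisition grid
#'
#' The kernel rises instantaneously to `amplitude` at the first sample at or
#' after `onset` and decays exponentially. Above the receptor's saturation
#' amplitude the decay time constant stretches linearly with the amplitude
#' excess, reproducing the right-tailing of near-saturating responses;
#' inhibitory kernels are the negated shape.
#'
#' @param model A `receptor_model` (supplies `tau` and `sat`).
#' @param amplitude Signed peak \eqn{\Delta F/F} amplitude.
#' @param acq An [acquisition_spec()].
#' @param onset Onset time in seconds, within the trace span.
#' @return A `ca_trace` (channel `"dff"`) holding the noiseless kernel.
#' @export
simulate_response_kernel <- function(model, amplitude,
                                     acq = acquisition_spec(), onset) {
  t <- acq_times(acq)
  if (onset < t[1] || onset > t[length(t)]) {
    stop("onset outside trace duration", call. = FALSE)
  }
  new_trace(t, response_kernel_values(t, model, amplitude, onset),
            rate = acq$rate, channel = "dff")
}

#' @keywords internal
kernel_tau <- function(model, amplitude) {
  model$tau * max(1, abs(amplitude) / model$sat)
}

#' @keywords internal
response_kernel_values <- function(t, model, amplitude, onset) {
  v <- rep(0, length(t))
  if (amplitude == 0) return(v)
  i0 <- which(t >= onset)[1]
  if (is.na(i0)) return(v)
  tau <- kernel_tau(model, amplitude)
  idx <- i0:length(t)
  v[idx] <- amplitude * exp(-(t[idx] - t[i0]) / tau)
  v
}

#' Simulate a GC-coupled imaging trial (fluorescence + FID)
#'
#' GC separation delivers each substance of the sample to the antenna at its
#' own retention time (plus the column-to-antenna transit), so the
#' fluorescence trace is the bleaching baseline modulated by one response
#' kernel per substance:
#' `F(t) = (A e^{-t/B} + C) * (1 + gain * sum kernels) + C * noise`.
#' Kernel amplitudes come from each substance's receptor tuning evaluated at
#' the log10 of its delivered amount. Substances absent from the tuning map
#' are treated as inert (with a message).
#'
#' @param sample A [sample_spec()].
#' @param tuning Named list mapping substance name to `receptor_model`,
#'   see [or42b_tuning()].
#' @param acq An [acquisition_spec()] with `mode = "gc_coupled"`.
#' @return A list with `fluor` (raw-fluorescence `ca_trace`), `fid`
#'   (FID `ca_trace`) and `ground_truth` (list: per-substance table, bleach
#'   parameters, gain, response-window mask, baseline window).
#' @export
simulate_gc_imaging_trace <- function(sample, tuning = or42b_tuning(),
                                      acq = acquisition_spec()) {
  stopifnot(inherits(sample, "sample_spec"))
  if (acq$mode != "gc_coupled") {
    stop("GC-coupled traces require gc_coupled acquisition", call. = FALSE)
  }
  t <- acq_times(acq)
  amounts <- sample_amounts(sample)
  gt <- amounts |>
    dplyr::mutate(
      model = purrr::map(.data$name, function(nm) {
        if (!nm %in% names(tuning)) {
          message("substance '", nm, "' missing from tuning map; ",
                  "treated as inert")
          return(receptor_inert())
        }
        tuning[[nm]]
      }),
      c_log10 = log10(.data$amount),
      amplitude = acq$animal_gain *
        purrr::map2_dbl(.data$model, .data$c_log10, receptor_amplitude),
      arrival_time = purrr::map_dbl(.data$substance, "retention_time") +
        acq$gc_transit,
      tau = purrr::map2_dbl(.data$model, .data$amplitude, kernel_tau)
    )
  kernels <- rep(0, length(t))
  for (i in seq_len(nrow(gt))) {
    kernels <- kernels + response_kernel_values(
      t, gt$model[[i]], gt$amplitude[i], gt$arrival_time[i])
  }
  b <- acq$bleach
  bleach_curve <- b[["A"]] * exp(-t / b[["B"]]) + b[["C"]]
  fid <- simulate_fid_trace(sample, acq)
  values <- maybe_with_seed(
    if (is.null(acq$seed)) NULL else acq$seed + 1L,
    bleach_curve * (1 + kernels) +
      b[["C"]] * stats::rnorm(length(t), 0, acq$noise_sd)
  )
  mask <- response_mask(gt$arrival_time, gt$tau,
                        widths = purrr::map_dbl(gt$substance,
                                                "elution_width"),
                        labels = gt$name,
                        active = abs(gt$amplitude) > 0)
  gt_out <- list(
    substances = dplyr::select(gt, "name", "amount", "c_log10", "amplitude",
                               "arrival_time", "tau"),
    bleach = b, gain = acq$animal_gain, noise_sd = acq$noise_sd,
    response_windows = mask,
    baseline_window = response_window(0, min(60, acq$duration / 4),
                                      "baseline")
  )
  list(
    fluor = new_trace(t, values, rate = acq$rate, channel = "fluorescence",
                      meta = list(mode = acq$mode,
                                  sample = sample$main_substance$name,
                                  dilution = sample$dilution)),
    fid = fid$trace,
    ground_truth = gt_out
  )
}

#' @keywords internal
response_mask <- function(arrivals, taus, widths, labels, active) {
  keep <- which(active)
  if (length(keep) == 0L) return(response_window(0, 1)[0, ])
  merge_windows(response_window(
    start = arrivals[keep] - 3 * widths[keep] - 2,
    end = arrivals[keep] + 3 * widths[keep] + 4 * taus[keep],
    label = labels[keep]
  ))
}

#' Simulate a direct-stimulation trial (double pulse, GC bypassed)
#'
#' All substances of the sample arrive together, so signed amplitudes add:
#' the net response is the sum of each substance's tuned amplitude
#' (excitatory positive, inhibitory negative), applied at both pulse onsets
#' of the double-pulse protocol (injections at 6 and 8.5 s, arriving after
#' the delivery delay at 6.75 and 9.25 s by default).
#'
#' @inheritParams simulate_gc_imaging_trace
#' @param injection_times Injection times at the autosampler, seconds.
#' @return A list with `fluor` (raw fluorescence `ca_trace`) and
#'   `ground_truth` (per-substance amplitudes, net amplitude, onsets,
#'   bleach, mask).
#' @export
simulate_direct_stim_trace <- function(sample, tuning = or42b_tuning(),
                                       acq = acquisition_spec("direct_stim"),
                                       injection_times = c(6, 8.5)) {
  stopifnot(inherits(sample, "sample_spec"))
  if (acq$mode != "direct_stim") {
    stop("direct-stimulation traces require direct_stim acquisition",
         call. = FALSE)
  }
  t <- acq_times(acq)
  onsets <- stimulus_onsets(injection_times, acq$stim_delay)
  amounts <- sample_amounts(sample)
  gt <- amounts |>
    dplyr::mutate(
      model = purrr::map(.data$name, function(nm) {
        if (!nm %in% names(tuning)) {
          message("substance '", nm, "' missing from tuning map; ",
                  "treated as inert")
          return(receptor_inert())
        }
        tuning[[nm]]
      }),
      c_log10 = log10(.data$amount),
      amplitude = acq$animal_gain *
        purrr::map2_dbl(.data$model, .data$c_log10, receptor_amplitude)
    )
  kernels <- rep(0, length(t))
  for (i in seq_len(nrow(gt))) {
    for (on in onsets) {
      kernels <- kernels + response_kernel_values(
        t, gt$model[[i]], gt$amplitude[i], on)
    }
  }
  b <- acq$bleach
  bleach_curve <- b[["A"]] * exp(-t / b[["B"]]) + b[["C"]]
  values <- maybe_with_seed(
    acq$seed,
    bleach_curve * (1 + kernels) +
      b[["C"]] * stats::rnorm(length(t), 0, acq$noise_sd)
  )
  taus <- purrr::map2_dbl(gt$model, gt$amplitude, kernel_tau)
  net <- sum(gt$amplitude)
  mask <- if (any(gt$amplitude != 0)) {
    merge_windows(response_window(
      start = rep(onsets, each = 1) - 0.25,
      end = onsets + 1 + 4 * max(taus[gt$amplitude != 0]),
      label = "pulse"
    ))
  } else {
    response_window(0, 1)[0, ]
  }
  list(
    fluor = new_trace(t, values, rate = acq$rate, channel = "fluorescence",
                      meta = list(mode = acq$mode,
                                  sample = sample$main_substance$name,
                                  dilution = sample$dilution)),
    ground_truth = list(
      substances = dplyr::select(gt, "name", "amount", "c_log10",
                                 "amplitude"),
      net_amplitude = net, onsets = onsets, bleach = b,
      gain = acq$animal_gain, noise_sd = acq$noise_sd,
      response_windows = mask,
      baseline_window = response_window(0, min(5, onsets[1]), "baseline")
    )
  )
}

#' Expand a trace into a small grayscale image stack
#'
#' Pixels inside the ROI follow the trace plus independent per-pixel noise;
#' pixels outside follow the `background` level (a scalar or a per-frame
#' vector, e.g. a bleach-only baseline). The mean over the ROI recovers the
#' input trace (exactly when `noise_sd = 0`).
#'
#' @param trace A `ca_trace`.
#' @param roi Logical matrix marking ROI pixels; must fit `frame_shape`.
#' @param frame_shape Integer `c(rows, cols)`; default the ROI's dimensions.
#' @param noise_sd Per-pixel additive noise SD.
#' @param background Scalar or per-frame background outside the ROI.
#' @param seed Integer seed or `NULL`.
#' @return A numeric array of dimension `c(rows, cols, n_frames)`.
#' @export
simulate_movie <- function(trace, roi, frame_shape = dim(roi),
                           noise_sd = 0, background = 0, seed = NULL) {
  stopifnot(inherits(trace, "ca_trace"), is.matrix(roi))
  roi <- roi > 0
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  if (nrow(roi) > frame_shape[1] || ncol(roi) > frame_shape[2]) {
    stop("ROI does not fit frame_shape", call. = FALSE)
  }
  if (any(dim(roi) != frame_shape)) {
    full <- matrix(FALSE, frame_shape[1], frame_shape[2])
    full[seq_len(nrow(roi)), seq_len(ncol(roi))] <- roi
    roi <- full
  }
  n <- nrow(trace)
  bg <- rep(background, length.out = n)
  stack <- array(rep(bg, each = prod(frame_shape)),
                 dim = c(frame_shape, n))
  idx <- which(roi)
  maybe_with_seed(seed, {
    for (k in seq_len(n)) {
      frame <- stack[, , k]
      frame[idx] <- trace$value[k] +
        if (noise_sd > 0) stats::rnorm(length(idx), 0, noise_sd) else 0
      stack[, , k] <- frame
    }
  })
  stack
}

#' Simulate a full GC-imaging impurity experiment
#'
#' Generates, per animal, one reference trial (ethyl butyrate with its
#' characteristic contaminants), one GC-coupled calibration trial of pure
#' ethyl acetate per calibration dilution, and one trial of the
#' contaminated sample per sample dilution. Per-animal variability enters
#' as a multiplicative response gain and jittered bleach parameters; every
#' trial carries its ground truth.
#'
#' @param n_animals Number of animals.
#' @param calibration_dilutions Dilution fractions for the pure-contaminant
#'   dose series (default `10^(-10..-2)`).
#' @param sample_dilutions Dilution fractions of the contaminated sample
#'   (default `c(10^-2, 10^-1)`).
#' @param fraction True contaminant relative fraction (default `10^-5.2`).
#' @param library Substance library.
#' @param tuning Receptor tuning map.
#' @param noise_sd Imaging noise SD (\eqn{\Delta F/F} units).
#' @param gain_sdlog Log-SD of the per-animal lognormal gain.
#' @param seed Integer seed; drives per-trial seeds so each trial is
#'   individually reproducible.
#' @return A tibble with one row per trial: `animal`, `role`
#'   (`reference` / `calibration` / `sample`), `substance`, `dilution`,
#'   `dilution_log10`, and list columns `fluor`, `fid`, `ground_truth`.
#' @export
simulate_experiment <- function(n_animals = 3,
                                calibration_dilutions = 10^seq(-10, -2),
                                sample_dilutions = c(1e-2, 1e-1),
                                fraction = 10^-5.2,
                                library = substance_library(),
                                tuning = or42b_tuning(library),
                                noise_sd = 0.006,
                                gain_sdlog = 0.2,
                                seed = 1L) {
  plan <- tidyr::expand_grid(
    animal = seq_len(n_animals),
    tibble::tibble(
      role = c("reference",
               rep("calibration", length(calibration_dilutions)),
               rep("sample", length(sample_dilutions))),
      dilution = c(1e-2, calibration_dilutions, sample_dilutions)
    )
  )
  draws <- withr::with_seed(seed, list(
    gains = stats::rlnorm(n_animals, 0, gain_sdlog),
    bleach_jitter = matrix(stats::rlnorm(n_animals * 2, 0, 0.1),
                           ncol = 2),
    trial_seeds = sample.int(2^30, nrow(plan))
  ))
  trials <- purrr::pmap(
    list(plan$animal, plan$role, plan$dilution, draws$trial_seeds),
    function(animal, role, dilution, trial_seed) {
      smp <- switch(role,
        reference = reference_sample(dilution, library),
        calibration = sample_spec(library$ethyl_acetate, dilution),
        sample = contaminated_sample(dilution, fraction, library)
      )
      acq <- acquisition_spec(
        "gc_coupled",
        bleach = c(A = 250 * draws$bleach_jitter[animal, 1],
                   B = 180 * draws$bleach_jitter[animal, 2],
                   C = 750),
        noise_sd = noise_sd,
        animal_gain = draws$gains[animal],
        seed = trial_seed
      )
      sim <- simulate_gc_imaging_trace(smp, tuning, acq)
      sim$ground_truth$animal <- animal
      sim$ground_truth$true_fraction <- if (role == "sample") fraction else NA
      list(substance = smp$main_substance$name, sim = sim)
    }
  )
  plan |>
    dplyr::mutate(
      substance = purrr::map_chr(trials, "substance"),
      dilution_log10 = log10(.data$dilution),
      fluor = purrr::map(trials, ~ .x$sim$fluor),
      fid = purrr::map(trials, ~ .x$sim$fid),
      ground_truth = purrr::map(trials, ~ .x$sim$ground_truth)
    )
}
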