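#' Detect peaks on a chromatogram or response trace
#'
#' Finds local extrema whose topographic prominence exceeds a threshold.
#' Each peak is reported with its apex time, signed amplitude (apex minus
#' local baseline), full width at half extremum, and local baseline (the
#' median of flanking non-peak samples). Negative-going dips are detected
#' on the negated trace, so inhibitory responses surface as peaks with
#' negative amplitude.
#'
#' @param trace A `ca_trace`.
#' @param min_prominence Minimum prominence in trace units; default
#'   3 times the robust noise SD of the trace.
#' @param polarity `"positive"`, `"negative"`, or `"both"`.
#' @param min_width Minimum full width at half extremum, seconds; default
#'   2.5 sample intervals. Genuine elution and response peaks span several
#'   samples, so this rejects single-sample noise spikes that can clear a
#'   prominence threshold.
#' @param baseline_band Width (s) of the flanking bands used for the local
#'   baseline median.
#' @return A tibble sorted by `apex_time` with columns `apex_time`,
#'   `amplitude`, `width`, `baseline`, `prominence`, `polarity`, `channel`.
#'   Empty tibble when nothing exceeds the threshold.
#' @export
detect_peaks <- function(trace, min_prominence = NULL,
                         polarity = c("positive", "negative", "both"),
                         min_width = NULL, baseline_band = 5) {
  stopifnot(inherits(trace, "ca_trace"))
  polarity <- match.arg(polarity)
  if (is.null(min_prominence)) {
    min_prominence <- 3 * robust_noise_sd(trace)
  }
  if (min_prominence <= 0) {
    stop("min_prominence must be > 0", call. = FALSE)
  }
  if (is.null(min_width)) min_width <- 2.5 / trace_rate(trace)
  out <- list()
  if (polarity %in% c("positive", "both")) {
    out <- c(out, list(find_prominent_peaks(trace$time, trace$value,
                                            min_prominence, baseline_band,
                                            sign = 1)))
  }
  if (polarity %in% c("negative", "both")) {
    out <- c(out, list(find_prominent_peaks(trace$time, -trace$value,
                                            min_prominence, baseline_band,
                                            sign = -1)))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0L) res <- res[res$width >= min_width, ]
  if (nrow(res) == 0L) {
    res <- tibble::tibble(apex_time = numeric(), amplitude = numeric(),
                          width = numeric(), baseline = numeric(),
                          prominence = numeric(), polarity = character())
  }
  res$channel <- rep(trace_channel(trace), nrow(res))
  dplyr::arrange(res, .data$apex_time)
}

# Core prominence-based detector, positive peaks on signal y.
#' @keywords internal
find_prominent_peaks <- function(t, y, min_prominence, baseline_band, sign) {
  n <- length(y)
  apexes <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(apexes) == 0L) return(NULL)
  rows <- purrr::map(apexes, function(i) {
    # walk left/right to the first sample higher than the apex; the lowest
    # valley on each side bounds the peak, prominence is apex - higher valley
    left <- i; lmin <- y[i]; lpos <- i
    while (left > 1L && y[left - 1L] <= y[i]) {
      left <- left - 1L
      if (y[left] < lmin) { lmin <- y[left]; lpos <- left }
    }
    right <- i; rmin <- y[i]; rpos <- i
    while (right < n && y[right + 1L] <= y[i]) {
      right <- right + 1L
      if (y[right] < rmin) { rmin <- y[right]; rpos <- right }
    }
    prom <- y[i] - max(lmin, rmin)
    if (prom < min_prominence) return(NULL)
    # local baseline: median over flanking bands just outside the peak bases
    band_n <- length(t[t - t[1] <= baseline_band]) # samples per band
    lband <- y[max(1L, lpos - band_n):lpos]
    rband <- y[rpos:min(n, rpos + band_n)]
    baseline <- stats::median(c(lband, rband))
    amp <- y[i] - baseline
    tibble::tibble(
      apex_time = t[i],
      amplitude = sign * amp,
      width = half_height_width(t, y, i, baseline + amp / 2, lpos, rpos),
      baseline = sign * baseline,
      prominence = prom,
      polarity = if (sign > 0) "positive" else "negative"
    )
  })
  dplyr::bind_rows(rows)
}

# Full width at half extremum by linear interpolation of the crossings.
#' @keywords internal
half_height_width <- function(t, y, i, level, lpos, rpos) {
  li <- i
  while (li > lpos && y[li - 1L] > level) li <- li - 1L
  tl <- if (li == 1L || y[li - 1L] > level) t[li] else {
    t[li - 1L] + (level - y[li - 1L]) / (y[li] - y[li - 1L]) *
      (t[li] - t[li - 1L])
  }
  ri <- i
  while (ri < rpos && y[ri + 1L] > level) ri <- ri + 1L
  tr <- if (ri == length(y) || y[ri + 1L] > level) t[ri] else {
    t[ri] + (y[ri] - level) / (y[ri] - y[ri + 1L]) * (t[ri + 1L] - t[ri])
  }
  max(tr - tl, t[2] - t[1])
}

#' Calibrate the FID-to-imaging time offset
#'
#' The imaging channel lags the FID channel by the eluate's travel time
#' from the column split to the antenna. The offset is read off a reference
#' substance present on both channels (ethyl acetate in the standard
#' protocol): `offset = dff apex - fid apex`. On each channel the
#' attributed peak is the one nearest the reference retention time among
#' the dominant candidates in the search window (at least half the largest
#' candidate amplitude, so residual minor peaks cannot hijack the
#' attribution); exact distance ties go to the larger amplitude.
#'
#' @param fid_peaks,dff_peaks Peak tibbles from [detect_peaks()].
#' @param reference A `substance_spec` giving the expected retention time.
#' @param search_window Maximum |apex - retention_time| (s) for a peak to be
#'   attributable to the reference; also bounds the returned offset.
#' @return An `alignment_model`: list with `offset` (s), `fid_apex`,
#'   `dff_apex`, `reference`.
#' @export
calibrate_alignment <- function(fid_peaks, dff_peaks, reference,
                                search_window = 30) {
  stopifnot(inherits(reference, "substance_spec"))
  fid_apex <- nearest_peak(fid_peaks, reference$retention_time,
                           search_window)
  if (is.na(fid_apex)) {
    stop("reference substance '", reference$name,
         "' not found on the FID channel", call. = FALSE)
  }
  dff_apex <- nearest_peak(dff_peaks, reference$retention_time,
                           search_window)
  if (is.na(dff_apex)) {
    stop("reference substance '", reference$name,
         "' not found on the imaging channel", call. = FALSE)
  }
  offset <- dff_apex - fid_apex
  structure(list(offset = offset, fid_apex = fid_apex, dff_apex = dff_apex,
                 reference = reference$name),
            class = "alignment_model")
}

#' @keywords internal
nearest_peak <- function(peaks, target, search_window) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(NA_real_)
  cand <- peaks[abs(peaks$apex_time - target) <= search_window, ]
  if (nrow(cand) == 0L) return(NA_real_)
  cand <- cand[abs(cand$amplitude) >= 0.5 * max(abs(cand$amplitude)), ]
  d <- abs(cand$apex_time - target)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.max(abs(cand$amplitude[best]))]
  cand$apex_time[best]
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model> offset=%.3f s (reference %s: fid %.2f s, imaging %.2f s)\n",
              x$offset, x$reference, x$fid_apex, x$dff_apex))
  invisible(x)
}

#' Measure the signed response amplitude in a substance's elution window
#'
#' Looks at the window `retention_time + offset +/- window_halfwidth` on
#' the imaging trace and returns the signed extremum of `value - local
#' baseline`: the maximum if the window's largest excursion is positive,
#' the minimum if negative -- so both calcium increases and decreases are
#' captured. The local baseline is the median of flanking bands just
#' outside the window.
#'
#' @param trace A `ca_trace` (dF/F).
#' @param substance A `substance_spec`.
#' @param align An `alignment_model` (or `NULL` for zero offset).
#' @param window_halfwidth Half-width of the measurement window, seconds.
#' @param baseline_band Width (s) of the flanking baseline bands.
#' @return A one-row tibble: `substance`, `amplitude` (signed), `t_extremum`,
#'   `baseline`, `window_start`, `window_end`.
#' @export
measure_response <- function(trace, substance, align = NULL,
                             window_halfwidth = 10, baseline_band = 5) {
  stopifnot(inherits(trace, "ca_trace"), inherits(substance, "substance_spec"))
  offset <- if (is.null(align)) 0 else align$offset
  center <- substance$retention_time + offset
  w0 <- center - window_halfwidth
  w1 <- center + window_halfwidth
  if (w0 < trace$time[1] || w1 > trace$time[nrow(trace)]) {
    stop("measurement window [", w0, ", ", w1, "] outside trace span",
         call. = FALSE)
  }
  inside <- trace$time >= w0 & trace$time <= w1
  flank <- (trace$time >= w0 - baseline_band & trace$time < w0) |
    (trace$time > w1 & trace$time <= w1 + baseline_band)
  baseline <- if (any(flank)) stats::median(trace$value[flank]) else 0
  dev <- trace$value[inside] - baseline
  i_max <- which.max(dev); i_min <- which.min(dev)
  i_ext <- if (abs(dev[i_max]) >= abs(dev[i_min])) i_max else i_min
  tibble::tibble(
    substance = substance$name,
    amplitude = dev[i_ext],
    t_extremum = trace$time[inside][i_ext],
    baseline = baseline,
    window_start = w0,
    window_end = w1
  )
}
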