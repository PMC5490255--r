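#' Construct a time-series trace
#'
#' A trace is the package's basic container for a uniformly sampled signal:
#' a tibble with `time` (seconds) and `value` columns, carrying the sampling
#' rate, the channel role and free-form metadata as attributes. Traces hold
#' raw fluorescence, FID chromatogram signal, or normalized \eqn{\Delta F/F}.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing on a uniform grid.
#' @param value Numeric vector of signal values, same length as `time`.
#' @param rate Sampling rate in Hz. Defaults to `1 / median(diff(time))`.
#' @param channel One of `"fluorescence"`, `"fid"`, `"dff"`.
#' @param meta Named list of free-form tags (animal, stimulus, dilution, ...).
#'
#' @return A tibble of class `ca_trace` with columns `time` and `value`.
#' @export
#' @examples
#' tr <- new_trace(seq(0, 10, by = 0.25), rnorm(41), channel = "fluorescence")
#' trace_rate(tr)
new_trace <- function(time, value, rate = NULL,
                      channel = c("fluorescence", "fid", "dff"),
                      meta = list()) {
  channel <- match.arg(channel)
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) < 2L) {
    stop("a trace needs at least 2 samples", call. = FALSE)
  }
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  med <- stats::median(dt)
  if (any(abs(dt - med) > 1e-9 * max(abs(time), 1))) {
    stop("`time` must be a uniform grid", call. = FALSE)
  }
  if (is.null(rate)) rate <- 1 / med
  out <- tibble::tibble(time = time, value = value)
  structure(out,
    class = c("ca_trace", class(out)),
    rate = rate, channel = channel, meta = meta
  )
}

#' @rdname new_trace
#' @param x A `ca_trace` object.
#' @export
trace_rate <- function(x) attr(x, "rate")

#' @rdname new_trace
#' @export
trace_channel <- function(x) attr(x, "channel")

#' @rdname new_trace
#' @export
trace_meta <- function(x) attr(x, "meta")

#' Replace the values of a trace, keeping grid and metadata
#'
#' @param x A `ca_trace`.
#' @param value New values (same length), or a function applied to the
#'   current values.
#' @param channel Optional new channel label.
#' @return A `ca_trace` on the same time grid.
#' @keywords internal
#' @export
set_trace_values <- function(x, value, channel = NULL) {
  stopifnot(inherits(x, "ca_trace"))
  if (is.function(value)) value <- value(x$value)
  new_trace(x$time, value,
    rate = trace_rate(x),
    channel = channel %||% trace_channel(x),
    meta = trace_meta(x)
  )
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf(
    "<ca_trace> channel=%s  rate=%g Hz  n=%d  span=[%g, %g] s\n",
    trace_channel(x), trace_rate(x), nrow(x), x$time[1], x$time[nrow(x)]
  ))
  NextMethod()
}

#' Define a labelled time window
#'
#' Response windows mark stretches of a trace containing stimulus-evoked
#' activity; they are excluded from the photobleaching fit and used to
#' measure responses at aligned elution times.
#'
#' @param start,end Window bounds in seconds, `start < end`.
#' @param label Text label.
#' @return A one-row tibble with columns `start`, `end`, `label`.
#' @export
response_window <- function(start, end, label = "") {
  if (any(start >= end)) stop("window start must precede end", call. = FALSE)
  tibble::tibble(start = as.numeric(start), end = as.numeric(end),
                 label = as.character(label))
}

#' Validate a set of response windows
#'
#' Windows within one mask may not overlap.
#' @param windows A tibble of windows (`start`, `end`, `label`) or `NULL`.
#' @return The windows tibble, sorted by start.
#' @keywords internal
validate_windows <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    return(response_window(0, 1)[0, ])
  }
  if (any(windows$start >= windows$end)) {
    stop("window start must precede end", call. = FALSE)
  }
  windows <- dplyr::arrange(windows, .data$start)
  if (nrow(windows) > 1L &&
      any(windows$start[-1] < windows$end[-nrow(windows)])) {
    stop("response windows within one mask may not overlap", call. = FALSE)
  }
  windows
}

#' Logical index of samples falling inside any window
#' @keywords internal
in_windows <- function(time, windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    return(rep(FALSE, length(time)))
  }
  purrr::reduce(
    purrr::map2(windows$start, windows$end, ~ time >= .x & time <= .y),
    `|`
  )
}

#' Robust noise standard deviation of a trace
#'
#' Estimates the additive noise level from the median absolute first
#' difference, which is insensitive to slow baseline drift and to sparse
#' response transients: for i.i.d. Gaussian noise,
#' `sd = 1.4826 * median(|diff|) / sqrt(2)`.
#'
#' @param trace A `ca_trace` (or numeric vector).
#' @return Estimated noise SD in the trace's units.
#' @export
robust_noise_sd <- function(trace) {
  v <- if (inherits(trace, "data.frame")) trace$value else as.numeric(trace)
  stats::median(abs(diff(v))) * 1.4826 / sqrt(2)
}

#' Read and write trial files
#'
#' A trial is stored as tab-separated text with columns `time_s`,
#' `fluorescence` and (for GC-coupled trials) `fid_signal`, next to a JSON
#' sidecar `<stem>.json` holding the sample, acquisition and ground-truth
#' metadata.
#'
#' @param trial A list with elements `fluor` (a `ca_trace`), optionally
#'   `fid` (a `ca_trace`), and `meta` (a list).
#' @param stem Path stem; `<stem>.tsv` and `<stem>.json` are written.
#' @return `write_trial` returns `stem` invisibly; `read_trial` returns a
#'   trial list.
#' @export
write_trial <- function(trial, stem) {
  tb <- tibble::tibble(time_s = trial$fluor$time,
                       fluorescence = trial$fluor$value)
  if (!is.null(trial$fid)) tb$fid_signal <- trial$fid$value
  readr::write_tsv(tb, paste0(stem, ".tsv"))
  jsonlite::write_json(trial$meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  tb <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  trial <- list(
    fluor = new_trace(tb$time_s, tb$fluorescence,
                      channel = "fluorescence", meta = meta),
    meta = meta
  )
  if ("fid_signal" %in% names(tb)) {
    trial$fid <- new_trace(tb$time_s, tb$fid_signal,
                           channel = "fid", meta = meta)
  }
  trial
}
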