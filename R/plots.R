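#' Plot a trace
#'
#' @param object A `ca_trace`.
#' @param windows Optional response-window tibble to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_trace <- function(object, windows = NULL, ...) {
  ylab <- switch(trace_channel(object),
                 fid = "FID signal",
                 dff = expression(Delta * F / F),
                 "fluorescence (counts)")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(windows) && nrow(windows) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab)
}

#' Plot the two channels of a GC-coupled trial with detected peaks
#'
#' FID chromatogram and imaging trace stacked on a shared time axis;
#' detected peaks are marked on each channel.
#'
#' @param fluor,fid `ca_trace` objects of the trial.
#' @param fluor_peaks,fid_peaks Optional peak tibbles from [detect_peaks()].
#' @return A ggplot object (facetted by channel).
#' @export
plot_gc_trial <- function(fluor, fid, fluor_peaks = NULL, fid_peaks = NULL) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = fluor$time, value = fluor$value,
                   channel = "imaging"),
    tibble::tibble(time = fid$time, value = fid$value, channel = "FID")
  )
  pk <- dplyr::bind_rows(
    if (!is.null(fluor_peaks) && nrow(fluor_peaks)) {
      dplyr::mutate(fluor_peaks, channel = "imaging")
    },
    if (!is.null(fid_peaks) && nrow(fid_peaks)) {
      dplyr::mutate(fid_peaks, channel = "FID")
    }
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(pk) && nrow(pk)) {
    p <- p + ggplot2::geom_point(
      data = pk,
      ggplot2::aes(x = .data$apex_time, y = .data$baseline + .data$amplitude),
      colour = "firebrick", shape = 4, size = 3
    )
  }
  p
}
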