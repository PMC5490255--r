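#' Relative fluorescence change
#'
#' Computes \eqn{\Delta F/F = (F_i - F_0)/F_0} where \eqn{F_0} is the mean
#' fluorescence over an explicit pre-stimulus baseline window.
#'
#' @param trace A `ca_trace` (raw or bleach-corrected fluorescence).
#' @param baseline_window A [response_window()] preceding the first stimulus.
#'   Default: the first 5 s of the trace.
#' @return A `ca_trace` with `channel = "dff"`.
#' @export
#' @examples
#' tr <- new_trace(0:19, c(rep(100, 10), rep(110, 10)))
#' delta_f_over_f(tr, response_window(0, 9))$value[15] # 0.1
delta_f_over_f <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  if (is.null(baseline_window)) {
    baseline_window <- response_window(trace$time[1], trace$time[1] + 5,
                                       "baseline")
  }
  idx <- in_windows(trace$time, baseline_window)
  if (!any(idx)) stop("baseline window contains no samples", call. = FALSE)
  f0 <- mean(trace$value[idx])
  if (!is.finite(f0) || f0 == 0) {
    stop("baseline mean F0 is zero; cannot form dF/F", call. = FALSE)
  }
  set_trace_values(trace, (trace$value - f0) / f0, channel = "dff")
}

#' Fit the photobleaching decay model
#'
#' Fits `A * exp(-t / B) + C` to the trace by Levenberg-Marquardt least
#' squares, using only samples outside the response-window mask (the parts
#' of the trace where stimulus-evoked activity was recorded are left out).
#' Initialisation: `A0 = first - last` unmasked value, `C0 = last` unmasked
#' value, `B0 = half the unmasked span`; on failure the fit is restarted
#' with `B0` scaled by 0.1 and 10. When the decay amplitude is negligible
#' (`|A|` below ~1e-6 of the signal scale) the time constant is
#' unidentifiable and `B` is reported as `NA`.
#'
#' @param trace A `ca_trace`.
#' @param mask Tibble of response windows to exclude, or `NULL`.
#' @param auto_mask If `TRUE` and `mask` is `NULL`, build a mask
#'   automatically: fit once, flag samples with residuals beyond 3 robust
#'   SDs, and refit.
#' @return An object of class `bleach_fit`: list with `A`, `B`, `C`, `rss`,
#'   `mask`, `converged`, `n_used`.
#' @export
fit_bleach <- function(trace, mask = NULL, auto_mask = is.null(mask)) {
  stopifnot(inherits(trace, "ca_trace"))
  force(auto_mask)
  mask <- validate_windows(mask)
  fit <- fit_bleach_masked(trace, mask)
  if (auto_mask && nrow(mask) == 0L) {
    resid <- trace$value - bleach_curve(fit, trace$time)
    sd_r <- stats::mad(resid)
    if (sd_r > 0) {
      flagged <- abs(resid) > 3 * sd_r
      if (any(flagged)) {
        mask <- flagged_windows(trace$time, flagged, pad = 2 / trace_rate(trace))
        fit <- fit_bleach_masked(trace, mask)
      }
    }
  }
  fit
}

#' @keywords internal
flagged_windows <- function(time, flagged, pad = 2) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(response_window(0, 1)[0, ])
  merge_windows(response_window(
    start = time[starts[keep]] - pad,
    end = time[ends[keep]] + pad,
    label = "auto"
  ))
}

#' @keywords internal
fit_bleach_masked <- function(trace, mask) {
  use <- !in_windows(trace$time, mask)
  t <- trace$time[use]
  y <- trace$value[use]
  if (length(t) < 10L || length(unique(t)) < 3L) {
    stop("need at least 10 unmasked samples at 3 distinct times",
         call. = FALSE)
  }
  scale_y <- max(abs(y), 1e-12)
  # Degenerate (constant) trace: C is the mean, A ~ 0, B unidentifiable.
  if (stats::sd(y) < 1e-12 * scale_y) {
    return(new_bleach_fit(A = 0, B = NA_real_, C = mean(y), rss = 0,
                          mask = mask, converged = TRUE,
                          n_used = length(t)))
  }
  # Profile over B: for fixed B the model is linear in (A, C), so a log-grid
  # over B plus exact linear solves always yields a near-optimal seed, even
  # on short, nearly-linear segments where a free 3-parameter start is
  # ill-conditioned. Levenberg-Marquardt then refines from the best seed
  # (plus scaled-B restarts). B is bounded to [span/100, 5*span] of the
  # full trace: when the unmasked samples alone cannot identify the
  # curvature, an unbounded B trades off against A along a ridge of
  # near-identical fits whose extrapolations into the masked response
  # windows differ wildly.
  span <- diff(range(trace$time))
  profile_b <- function(B) {
    e <- exp(-t / B)
    X <- cbind(e, 1)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(.) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    list(A = cf[[1]], B = B, C = cf[[2]],
         rss = sum((y - X %*% cf)^2))
  }
  grid <- seq(log(span / 100), log(span * 5), length.out = 40)
  profs <- purrr::compact(purrr::map(exp(grid), profile_b))
  seed <- profs[[which.min(purrr::map_dbl(profs, "rss"))]]
  best <- list(A = seed$A, B = seed$B, C = seed$C, rss = seed$rss)
  for (b_try in seed$B * c(1, 0.3, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-t / B) + C,
        start = list(A = seed$A, B = min(b_try, span * 5), C = seed$C),
        lower = c(A = -Inf, B = span / 1000, C = -Inf),
        upper = c(A = Inf, B = span * 5, C = Inf),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best$rss) {
        p <- stats::coef(fit)
        best <- list(A = unname(p["A"]), B = unname(p["B"]),
                     C = unname(p["C"]), rss = rss)
      }
    }
  }
  A <- best$A; B <- best$B; C <- best$C
  if (abs(A) < 1e-6 * scale_y) {
    # decay amplitude negligible -> B unidentifiable
    A <- 0; B <- NA_real_; C <- mean(y)
  }
  new_bleach_fit(A = A, B = B, C = C, rss = best$rss, mask = mask,
                 converged = TRUE, n_used = length(t))
}

#' @keywords internal
new_bleach_fit <- function(A, B, C, rss, mask, converged, n_used) {
  structure(list(A = A, B = B, C = C, rss = rss, mask = mask,
                 converged = converged, n_used = n_used),
            class = "bleach_fit")
}

#' Evaluate a fitted bleach curve
#' @param fit A `bleach_fit`.
#' @param time Times in seconds.
#' @return Fitted `A * exp(-t/B) + C` (constant `C` when `B` is `NA`).
#' @export
bleach_curve <- function(fit, time) {
  if (is.na(fit$B)) rep(fit$C, length(time))
  else fit$A * exp(-time / fit$B) + fit$C
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "<bleach_fit> A=%.4g  B=%s s  C=%.4g  rss=%.3g  (n=%d, %d masked windows)\n",
    x$A, if (is.na(x$B)) "unidentifiable" else sprintf("%.4g", x$B),
    x$C, x$rss, x$n_used, nrow(x$mask)
  ))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.bleach_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = c(x$A, x$B, x$C))
}

#' @export
#' @importFrom generics glance
glance.bleach_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_used = x$n_used,
                 converged = x$converged,
                 b_identifiable = !is.na(x$B))
}

#' Subtract the fitted bleaching decay from a trace
#'
#' The corrected value is `raw - (A * exp(-t/B) + C) + C`: the decay
#' component is removed while the fluorescence offset `C` is preserved, so
#' unmasked (response-free) samples average to `C` and additive response
#' excursions are untouched.
#'
#' @param trace A `ca_trace` on the same time grid the fit was made on.
#' @param fit A `bleach_fit`.
#' @return A corrected `ca_trace` (same channel).
#' @export
correct_bleach <- function(trace, fit) {
  stopifnot(inherits(trace, "ca_trace"), inherits(fit, "bleach_fit"))
  decay <- bleach_curve(fit, trace$time) - fit$C
  set_trace_values(trace, trace$value - decay)
}

#' Average fluorescence over an ROI, frame by frame
#'
#' @param stack Numeric array `c(rows, cols, frames)`.
#' @param roi Logical matrix of ROI pixels within the frame bounds.
#' @param rate Sampling rate in Hz (default 1).
#' @param t0 Time of the first frame (default 0).
#' @return A `ca_trace` (channel `"fluorescence"`).
#' @export
extract_roi_trace <- function(stack, roi, rate = 1, t0 = 0) {
  stopifnot(length(dim(stack)) == 3L, is.matrix(roi))
  roi <- roi > 0
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  if (nrow(roi) != dim(stack)[1] || ncol(roi) != dim(stack)[2]) {
    stop("ROI dimensions do not match frame bounds", call. = FALSE)
  }
  idx <- which(roi)
  n <- dim(stack)[3]
  vals <- vapply(seq_len(n), function(k) mean(stack[, , k][idx]), numeric(1))
  new_trace(t0 + (seq_len(n) - 1) / rate, vals, rate = rate,
            channel = "fluorescence")
}

#' Normalize a dF/F trace to a reference response amplitude
#'
#' Calibrates responses across animals by dividing by each animal's
#' amplitude to the shared reference stimulus (the first response peak of
#' ethyl butyrate), so a response equal to the reference maps to 1.0.
#'
#' @param trace A `ca_trace` with `channel = "dff"`.
#' @param reference_amplitude Positive reference amplitude in
#'   \eqn{\Delta F/F} units.
#' @return The normalized `ca_trace`.
#' @export
normalize_to_reference <- function(trace, reference_amplitude) {
  stopifnot(inherits(trace, "ca_trace"))
  if (!is.numeric(reference_amplitude) || length(reference_amplitude) != 1L ||
      !is.finite(reference_amplitude) || reference_amplitude <= 0) {
    stop("reference_amplitude must be a positive number", call. = FALSE)
  }
  set_trace_values(trace, trace$value / reference_amplitude)
}

#' Smooth a trace with a Gaussian kernel
#'
#' Light temporal smoothing matched to the slow calcium response kernel,
#' used before amplitude measurement so that the window-extremum statistic
#' has a null distribution on the scale of the trace's noise SD (an
#' unsmoothed extremum over a 20 s window is biased upward by roughly twice
#' the per-sample noise SD, which would defeat a noise-SD-based detection
#' threshold). Smoothing scales all response amplitudes by a common shape
#' factor, which cancels under reference normalization.
#'
#' @param trace A `ca_trace`.
#' @param sd Gaussian kernel SD in seconds; `0` returns the trace
#'   unchanged.
#' @return The smoothed `ca_trace`.
#' @export
gaussian_smooth <- function(trace, sd = 2) {
  stopifnot(inherits(trace, "ca_trace"))
  if (sd <= 0) return(trace)
  dt <- 1 / trace_rate(trace)
  half <- ceiling(3 * sd / dt)
  w <- stats::dnorm(seq(-half, half) * dt, sd = sd)
  w <- w / sum(w)
  n <- nrow(trace)
  # reflect edges so the baseline is not pulled toward zero
  padded <- c(trace$value[half:1], trace$value, trace$value[n:(n - half + 1)])
  sm <- stats::filter(padded, w, sides = 2)
  set_trace_values(trace, as.numeric(sm[(half + 1):(half + n)]))
}

#' Process one raw GC-coupled trial to a dF/F trace
#'
#' Convenience wrapper chaining the standard order: fit the bleach model on
#' response-masked samples, subtract the decay, then form \eqn{\Delta F/F}
#' against the baseline-window mean of the corrected trace.
#'
#' @param trace Raw fluorescence `ca_trace`.
#' @param mask Response windows to exclude from the bleach fit (`NULL` for
#'   automatic masking).
#' @param baseline_window Pre-stimulus window for \eqn{F_0}; default the
#'   first 60 s (GC-coupled) or 5 s (direct) depending on trace length.
#' @return A list with `dff` (`ca_trace`), `fit` (`bleach_fit`).
#' @export
process_trace <- function(trace, mask = NULL, baseline_window = NULL) {
  if (is.null(baseline_window)) {
    span <- trace$time[nrow(trace)] - trace$time[1]
    len <- if (span > 120) 60 else 5
    baseline_window <- response_window(trace$time[1], trace$time[1] + len,
                                       "baseline")
  }
  fit <- fit_bleach(trace, mask)
  corrected <- correct_bleach(trace, fit)
  list(dff = delta_f_over_f(corrected, baseline_window), fit = fit)
}
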