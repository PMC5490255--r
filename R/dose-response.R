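#' Fit the sigmoidal logistic dose-response model
#'
#' Least-squares fit of \eqn{R = R_{max} / (1 + e^{-h (c - EC_{50})})} to
#' normalized response amplitudes on a log10-dilution axis, with
#' \eqn{R_{max}} the maximum response asymptote, \eqn{EC_{50}} the
#' half-effective log10 dilution and \eqn{h} the steepness (reminiscent of
#' the Hill coefficient). Points are unweighted; a per-point `sem` column,
#' if present, is carried for reporting only.
#'
#' Initialisation: `Rmax0 = max(response)`, `EC500 = c` at the point whose
#' response is closest to `Rmax0/2`, `h0 = 1`; parameters are bounded to
#' `Rmax` in `(0, 10 * max(response)]` and `h` in `(0, 50]`, with bounded
#' restarts on failure.
#'
#' @param points A data frame with columns `c` (log10 dilution) and
#'   `response` (normalized amplitude); extra columns (`n_animals`, `sem`)
#'   are retained in the result.
#' @return An object of class `logistic_fit`: list with `Rmax`, `EC50`,
#'   `h`, `rss`, `converged`, `data`.
#' @export
#' @examples
#' pts <- tibble::tibble(c = -9:-2,
#'                       response = 1 / (1 + exp(-2 * (-9:-2 - -5))))
#' fit <- fit_logistic(pts)
#' round(c(fit$Rmax, fit$EC50, fit$h), 6)
fit_logistic <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("c", "response") %in% names(points)))
  points <- dplyr::filter(points, is.finite(.data$c),
                          is.finite(.data$response))
  if (nrow(points) < 4L) {
    stop("need at least 4 dose-response points", call. = FALSE)
  }
  if (diff(range(points$c)) < 2) {
    stop("dose-response points must span at least 2 log10 units",
         call. = FALSE)
  }
  if (all(points$response == 0)) {
    stop("all responses are zero; the logistic model is unidentifiable",
         call. = FALSE)
  }
  cc <- points$c
  rr <- points$response
  rmax0 <- max(rr)
  ec0 <- cc[which.min(abs(rr - rmax0 / 2))]
  best <- NULL
  for (start in list(list(Rmax = rmax0, EC50 = ec0, h = 1),
                     list(Rmax = rmax0, EC50 = stats::median(cc), h = 0.5),
                     list(Rmax = rmax0 * 1.5, EC50 = ec0, h = 3))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rr ~ Rmax / (1 + exp(-h * (cc - EC50))),
        start = start,
        lower = c(Rmax = 1e-12, EC50 = min(cc) - 20, h = 1e-6),
        upper = c(Rmax = 10 * rmax0, EC50 = max(cc) + 20, h = 50),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (!is.null(best)) {
    p <- stats::coef(best$fit)
    best <- list(Rmax = unname(p["Rmax"]), EC50 = unname(p["EC50"]),
                 h = unname(p["h"]), rss = best$rss)
  } else {
    # Near-step data drive h to the boundary, where the saturated logistic
    # has a singular Jacobian and Levenberg-Marquardt aborts. Fall back to
    # a dense grid over (EC50, h) with Rmax profiled out (the model is
    # linear in Rmax at fixed shape), which always yields the bounded-box
    # least-squares optimum.
    for (EC50 in seq(min(cc) - 1, max(cc) + 1, length.out = 81)) {
      for (h in exp(seq(log(0.1), log(50), length.out = 61))) {
        f <- 1 / (1 + exp(-h * (cc - EC50)))
        Rmax <- min(max(sum(f * rr) / sum(f^2), 1e-12), 10 * rmax0)
        rss <- sum((rr - Rmax * f)^2)
        if (is.null(best) || rss < best$rss) {
          best <- list(Rmax = Rmax, EC50 = EC50, h = h, rss = rss)
        }
      }
    }
  }
  structure(
    c(best[c("Rmax", "EC50", "h", "rss")],
      list(converged = TRUE, data = tibble::as_tibble(points))),
    class = "logistic_fit"
  )
}

#' Predicted response of a logistic dose-response fit
#'
#' @param fit A `logistic_fit` (or any list with `Rmax`, `EC50`, `h`).
#' @param c Log10 dilution(s).
#' @return Normalized response amplitude(s)
#'   \eqn{R_{max} / (1 + e^{-h (c - EC_{50})})}.
#' @export
predict_response <- function(fit, c) {
  fit$Rmax / (1 + exp(-fit$h * (c - fit$EC50)))
}

#' Invert a logistic dose-response fit
#'
#' Reads a concentration off the calibration curve:
#' \eqn{c = EC_{50} - \ln(R_{max}/R - 1) / h}. The algebraic inverse of
#' [predict_response()], defined for responses strictly between 0 and
#' `Rmax`.
#'
#' @param fit A `logistic_fit`.
#' @param response Normalized response amplitude in `(0, Rmax)`.
#' @return The log10 dilution producing that response.
#' @export
invert_logistic <- function(fit, response) {
  if (any(response <= 0)) {
    stop("response at or below 0: below detection, no concentration",
         call. = FALSE)
  }
  if (any(response >= fit$Rmax)) {
    stop("response at or above Rmax: saturated, no concentration",
         call. = FALSE)
  }
  fit$EC50 - log(fit$Rmax / response - 1) / fit$h
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> Rmax=%.4g  EC50=%.3f (log10 dilution)  h=%.3f  rss=%.3g  (n=%d)\n",
    x$Rmax, x$EC50, x$h, x$rss, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("Rmax", "EC50", "h"),
                 estimate = c(x$Rmax, x$EC50, x$h))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), converged = x$converged)
}

#' @export
#' @importFrom stats predict
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  c <- if (is.null(newdata)) object$data$c else newdata$c
  predict_response(object, c)
}

#' Plot a dose-response fit
#'
#' Points (with SEM bars when available) and the fitted logistic curve on
#' the log10-dilution axis, with the half-maximal level marked at the
#' fitted EC50.
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  grid <- tibble::tibble(
    c = seq(min(object$data$c) - 0.5, max(object$data$c) + 0.5,
            length.out = 200)
  )
  grid$response <- predict_response(object, grid$c)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$c,
                                                 y = .data$response)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$EC50, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$Rmax / 2, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::labs(
      x = "log10 dilution",
      y = "normalized response",
      title = sprintf("EC50 at 10^%.1f, Rmax %.2f, h %.2f",
                      object$EC50, object$Rmax, object$h)
    )
  if ("sem" %in% names(object$data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$response - .data$sem,
                   ymax = .data$response + .data$sem),
      width = 0.15
    )
  }
  p
}
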