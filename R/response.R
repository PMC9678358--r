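#' Fractional fluorescence change
#'
#' Computes dF/F0 from a fluorescence trace: `(F - F0)/F0` with `F0` the
#' mean fluorescence over the pre-stimulus baseline window.
#'
#' @param trace Data frame with columns `time` (s) and `F` (fluorescence,
#'   a.u.).
#' @param baseline Length-2 time window `c(t0, t1)` defining the baseline.
#' @return Data frame with columns `time` and `dff`.
#' @export
dff <- function(trace, baseline = range(trace$time)) {
  stopifnot(is.data.frame(trace), all(c("time", "F") %in% names(trace)),
            length(baseline) == 2L)
  sel <- trace$time >= baseline[1] & trace$time <= baseline[2]
  if (!any(sel)) stop("baseline window contains no samples")
  F0 <- mean(trace$F[sel])
  if (!is.finite(F0) || F0 <= 0) {
    stop("baseline fluorescence must be positive")
  }
  data.frame(time = trace$time, dff = (trace$F - F0) / F0)
}

# Boltzmann sigmoid with zero lower asymptote.
boltzmann <- function(f, A, f0, w) A / (1 + exp((f0 - f) / w))

#' Fit a Boltzmann force-response curve
#'
#' Least-squares fit of the sigmoid `R(f) = A / (1 + exp((f0 - f)/w))`
#' (plateau `A`, half-point `f0`, width `w`) to force-response data.
#' By default the fit targets the per-force mean response across cells,
#' matching how force-response plots are summarised; set
#' `per_force_mean = FALSE` to fit all points. Initial values: `A` from
#' the maximum response, `f0` from linear interpolation to half-maximum,
#' `w` from a quarter of the force span.
#'
#' @param data Data frame with columns `force` (mN) and `response`
#'   (dF/F0), optionally `cell`.
#' @param per_force_mean Fit per-force means (default) or raw points.
#' @return An object of class `boltzmann_fit` with methods [print()],
#'   [summary()], [coef()], [predict()], [plot()], [residuals()] and
#'   [fitted()]. Fields include the derived half-activation force `f50`
#'   (= `f0`) and full-activation force `f90` (= `f0 + w log 9`).
#' @seealso [f_at_fraction()]
#' @export
fit_boltzmann <- function(data, per_force_mean = TRUE) {
  stopifnot(is.data.frame(data), all(c("force", "response") %in% names(data)))
  if (any(data$force < 0)) stop("forces must be nonnegative")
  pts <- if (per_force_mean) {
    stats::aggregate(response ~ force, data, mean)
  } else {
    data[, c("force", "response")]
  }
  pts <- pts[order(pts$force), ]
  if (length(unique(pts$force)) < 4L) {
    stop("Boltzmann fitting needs at least 4 distinct force levels")
  }
  A0 <- max(pts$response)
  if (A0 <= 0 || stats::sd(pts$response) < 1e-12 * max(A0, 1)) {
    stop("degenerate force-response data: responses are flat")
  }
  above <- which(pts$response >= A0 / 2)[1]
  f0_0 <- if (above == 1L) {
    pts$force[1]
  } else {
    stats::approx(pts$response[(above - 1):above],
                  pts$force[(above - 1):above], xout = A0 / 2)$y
  }
  w0 <- diff(range(pts$force)) / 4
  start <- list(A = A0, f0 = f0_0, w = w0)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ A / (1 + exp((f0 - force) / w)),
                      data = pts, start = start,
                      lower = c(A = 1e-8, f0 = -Inf, w = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Boltzmann fit failed to converge (starting values A = ",
           signif(start$A, 3), ", f0 = ", signif(start$f0, 3), ", w = ",
           signif(start$w, 3), "): ", conditionMessage(e))
    })
  cf <- stats::coef(fit)
  structure(list(coefficients = cf,
                 f50 = unname(cf["f0"]),
                 f90 = unname(cf["f0"] + cf["w"] * log(9)),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 points = pts, data = data, fit = fit,
                 per_force_mean = per_force_mean),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Boltzmann force-response fit: R(f) = A / (1 + exp((f0 - f)/w))\n")
  cat(sprintf("  A = %.3g, f0 = %.3g mN, w = %.3g mN (rms residual %.3g)\n",
              cf["A"], cf["f0"], cf["w"], x$residual))
  cat(sprintf("  half-activation f50 = %.3g mN, full-activation f90 = %.3g mN\n",
              x$f50, x$f90))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  fitted on %d %s spanning %g-%g mN\n",
              nrow(object$points),
              if (object$per_force_mean) "per-force means" else "points",
              min(object$points$force), max(object$points$force)))
  invisible(object)
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
fitted.boltzmann_fit <- function(object, ...) {
  stats::fitted(object$fit)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @param object,x A `boltzmann_fit`.
#' @param newdata Optional data frame with a `force` column (or a numeric
#'   vector of forces).
#' @rdname fit_boltzmann
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) {
    object$points$force
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$force
  }
  cf <- object$coefficients
  boltzmann(f, cf["A"], cf["f0"], cf["w"])
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$force, x$data$response, col = "grey60", pch = 16,
                 xlab = "force (mN)", ylab = "response (dF/F0)", ...)
  graphics::points(x$points$force, x$points$response, pch = 16)
  fg <- seq(min(x$points$force), max(x$points$force), length.out = 200)
  graphics::lines(fg, predict(x, fg), lty = 2)
  graphics::abline(v = c(x$f50, x$f90), col = "grey80", lty = 3)
  invisible(x)
}

#' Force at a given fraction of the fitted plateau
#'
#' Inverts the fitted Boltzmann curve: the force at which the response
#' reaches `q * A` is `f0 + w log(q / (1 - q))`; `q = 0.5` gives the
#' half-activation force and `q = 0.9` the full-activation force.
#'
#' @param fit A [fit_boltzmann()] result (or a list with elements `f0`
#'   and `w`).
#' @param q Fraction of the plateau, in (0, 1).
#' @return Force in mN.
#' @export
f_at_fraction <- function(fit, q) {
  stopifnot(is.numeric(q))
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly between 0 and 1")
  cf <- if (inherits(fit, "boltzmann_fit")) {
    list(f0 = unname(fit$coefficients["f0"]), w = unname(fit$coefficients["w"]))
  } else {
    fit
  }
  cf$f0 + cf$w * log(q / (1 - q))
}
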