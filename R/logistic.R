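#' Logistic vessel-density growth model
#'
#' The vessel density rho(t) during vasculogenesis follows the solution of
#' the logistic growth equation
#' \deqn{\rho(t) = \frac{1}{1/\rho_{max} + (1/\rho_0 - 1/\rho_{max})\, e^{-\omega t}},}
#' where `rho0` is the initial density, `rho_max` the saturation plateau and
#' `omega` the growth rate per hour.
#'
#' @param rho0 initial density in (0, 1].
#' @param rho_max plateau density in (0, 1].
#' @param omega growth rate (1/h), positive.
#' @param rss,se optional fit diagnostics (residual sum of squares and
#'   per-parameter standard errors), attached by [fit_logistic()].
#' @return an object of class `logistic_params`.
#' @export
logistic_params <- function(rho0, rho_max, omega, rss = NA_real_, se = NULL) {
  if (!is.numeric(rho0) || rho0 <= 0 || rho0 > 1) {
    stop_invalid("rho0 must lie in (0, 1]")
  }
  if (!is.numeric(rho_max) || rho_max <= 0 || rho_max > 1) {
    stop_invalid("rho_max must lie in (0, 1]")
  }
  if (!is.numeric(omega) || omega <= 0) stop_invalid("omega must be positive")
  structure(list(rho0 = rho0, rho_max = rho_max, omega = omega,
                 rss = rss, se = se),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> rho0 = %.4g, rho_max = %.4g, omega = %.4g /h",
              x$rho0, x$rho_max, x$omega))
  if (is.finite(x$rss)) cat(sprintf(" (rss = %.3g)", x$rss))
  cat("\n")
  invisible(x)
}

#' Evaluate the logistic density curve
#'
#' @param t_h time(s) in hours (vectorised).
#' @param p a [logistic_params()].
#' @return density values; monotone non-decreasing in `t_h`, bounded by
#'   `(0, rho_max]` when `rho0 <= rho_max`.
#' @export
logistic_density <- function(t_h, p) {
  1 / (1 / p$rho_max + (1 / p$rho0 - 1 / p$rho_max) * exp(-p$omega * t_h))
}

#' Density time series container
#'
#' @param times_h strictly increasing timestamps in hours.
#' @param values densities in \[0, 1\], one per timestamp.
#' @param label free-text label (e.g. experimental group).
#' @return an object of class `density_series`.
#' @export
density_series <- function(times_h, values, label = "") {
  if (length(times_h) != length(values)) {
    stop_invalid("times_h and values must have equal length")
  }
  if (any(diff(times_h) <= 0)) stop_invalid("times_h must be strictly increasing")
  if (any(values < 0 | values > 1)) stop_invalid("values must lie in [0, 1]")
  structure(list(times_h = times_h, values = values, label = label),
            class = "density_series")
}

#' Generate a noisy logistic density series
#'
#' Evaluates the logistic curve at the requested times, adds i.i.d. Gaussian
#' noise and clips to \[0, 1\].  Identical arguments and seed give identical
#' output.
#'
#' @param p a [logistic_params()] with `rho0 <= rho_max` (densities grow).
#' @param times_h strictly increasing sampling times (hours).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param label label for the series.
#' @return a [density_series()].
#' @export
generate_logistic_series <- function(p, times_h, noise_sd = 0, seed = 1,
                                     label = "") {
  if (any(diff(times_h) <= 0)) stop_invalid("times_h must be strictly increasing")
  if (p$rho0 > p$rho_max) {
    stop_invalid("rho0 > rho_max: density curves must grow monotonically")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  v <- logistic_density(times_h, p)
  if (noise_sd > 0) {
    v <- withr::with_seed(seed, v + rnorm(length(v), sd = noise_sd))
  }
  density_series(times_h, pmin(pmax(v, 0), 1), label = label)
}

#' Fit the logistic growth model to a density series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over
#' (rho0, rho_max, omega), initialised at the first value (floored at 1e-3),
#' the series maximum, and 0.5/h, with deterministic restarts that jitter
#' the initial growth rate.  Standard errors come from the local curvature
#' of the converged fit.
#'
#' @param series a [density_series()] with at least 5 points.
#' @return a [logistic_params()] carrying `rss` and `se`.
#' @export
fit_logistic <- function(series) {
  stopifnot(inherits(series, "density_series"))
  t <- series$times_h
  y <- series$values
  if (length(y) < 5) stop_invalid("need at least 5 points to fit")
  if (sd(y) < 1e-9) stop_fit_failure("flat series: logistic fit is unidentifiable")

  start0 <- list(rho0 = max(y[1], 1e-3), rho_max = max(y), omega = 0.5)
  lower <- c(rho0 = 1e-6, rho_max = 1e-6, omega = 1e-6)
  upper <- c(rho0 = 1, rho_max = 1, omega = 50)
  jitters <- c(1, 0.4, 2.5, 0.15, 6)  # restart multipliers on omega

  best <- NULL
  diag_msgs <- character(0)
  for (j in jitters) {
    st <- start0
    st$omega <- start0$omega * j
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 / (1 / rho_max + (1 / rho0 - 1 / rho_max) * exp(-omega * t)),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop_fit_failure("logistic fit did not converge from any restart",
                     diagnostics = diag_msgs)
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) NULL)
  logistic_params(rho0 = unname(cf["rho0"]),
                  rho_max = unname(cf["rho_max"]),
                  omega = unname(cf["omega"]),
                  rss = best$rss, se = se)
}

#' Detect percolation onset and saturation times in a density series
#'
#' Operationalises the two characteristic times of the largest-cluster
#' density: the plateau is the mean of the final 10% of points; the onset is
#' the earliest (linearly interpolated) crossing of
#' `theta_on * plateau` after which the series never falls back below half
#' that level, and the saturation time is the earliest crossing of
#' `theta_sat * plateau`.
#'
#' @param series a [density_series()] with at least 5 points.
#' @param theta_on onset threshold as a fraction of the plateau (default 0.1).
#' @param theta_sat saturation threshold fraction (default 0.95).
#' @return an object of class `transition_times`: list with `onset_h`,
#'   `saturation_h` (`NA` with `saturation_defined = FALSE` if the series
#'   never reaches the saturation threshold) and `plateau_value`.
#' @export
detect_transitions <- function(series, theta_on = 0.1, theta_sat = 0.95) {
  stopifnot(inherits(series, "density_series"))
  t <- series$times_h
  v <- series$values
  n <- length(v)
  if (n < 5) stop_invalid("need at least 5 points")
  plateau <- mean(v[seq.int(n - ceiling(0.1 * n) + 1, n)])
  thr_on <- theta_on * plateau
  thr_sat <- theta_sat * plateau

  cross_time <- function(thr, from = 1L) {
    idx <- which(v > thr & seq_along(v) >= from)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    if (i == 1) return(t[1])
    # linear interpolation between the bracketing samples
    t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  }

  # earliest crossing of thr_on after which the series stays above thr_on/2
  suffix_min <- rev(cummin(rev(v)))
  onset <- NA_real_
  for (i in which(v > thr_on)) {
    if (suffix_min[i] >= thr_on / 2) {
      onset <- if (i == 1) t[1] else
        t[i - 1] + (thr_on - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
      break
    }
  }
  saturation <- cross_time(thr_sat)
  structure(list(onset_h = onset, saturation_h = saturation,
                 plateau_value = plateau,
                 saturation_defined = !is.na(saturation)),
            class = "transition_times")
}

#' @export
print.transition_times <- function(x, ...) {
  cat(sprintf("<transition_times> onset %.3g h, saturation %s h (plateau %.4g)\n",
              x$onset_h,
              if (x$saturation_defined) sprintf("%.3g", x$saturation_h) else "undefined",
              x$plateau_value))
  invisible(x)
}
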