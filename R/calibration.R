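#' Calibration-in-the-large
#'
#' Fits the logistic recalibration model
#' `P(y = 1) = plogis(a + logit(p))` with the slope fixed at 1 (an offset
#' model, maximum likelihood via IRLS) and returns the intercept `a`.
#' A positive value means the model under-predicts on average (the mean
#' predicted EP risk is below the observed EP rate); a negative value means
#' over-prediction. When `p` is constant the maximum-likelihood solution is
#' the closed form `logit(observed rate) - logit(p)`.
#'
#' @param p Predicted probabilities.
#' @param y Logical/0-1 observed events; needs at least one event and one
#'   non-event.
#' @param level Confidence level for the Wald interval.
#' @return A list: `citl`, `ci_low`, `ci_high`, `mean_predicted`,
#'   `observed_rate`, `n`.
#' @export
calibration_in_the_large <- function(p, y, level = 0.95) {
  y <- as.integer(as.logical(y))
  check_calibration_input(p, y)
  off <- logit(p)
  fit <- glm(y ~ 1, family = binomial(), offset = off,
             control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("Calibration-in-the-large fit did not converge.",
          class = "pulvalidate_fit_error")
  }
  a <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  z <- qnorm(1 - (1 - level) / 2)
  list(citl = a, ci_low = a - z * se, ci_high = a + z * se,
       mean_predicted = mean(p), observed_rate = mean(y), n = length(y))
}

#' Calibration slope (logistic recalibration)
#'
#' Fits `P(y = 1) = plogis(a + b * logit(p))` by maximum likelihood and
#' returns both coefficients with Wald intervals. A slope below 1 indicates
#' predictions that are too extreme (high risks overestimated, low risks
#' underestimated); above 1, too moderate.
#'
#' @inheritParams calibration_in_the_large
#' @return A list: `intercept`, `slope`, and `*_ci_low` / `*_ci_high` for
#'   both, plus `n`.
#' @export
calibration_slope <- function(p, y, level = 0.95) {
  y <- as.integer(as.logical(y))
  check_calibration_input(p, y)
  lp <- logit(p)
  if (length(unique(lp)) < 2) {
    abort("`p` must take at least two distinct values for a slope.",
          class = "pulvalidate_degenerate_design")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ lp, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (separated || !fit$converged || any(!is.finite(cf))) {
    abort("Separation detected: calibration slope diverges.",
          class = "pulvalidate_separation_error")
  }
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - level) / 2)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       intercept_ci_low = unname(cf[1] - z * se[1]),
       intercept_ci_high = unname(cf[1] + z * se[1]),
       slope_ci_low = unname(cf[2] - z * se[2]),
       slope_ci_high = unname(cf[2] + z * se[2]),
       n = length(y))
}

check_calibration_input <- function(p, y) {
  if (length(p) != length(y)) {
    abort("`p` and `y` must be aligned.", class = "pulvalidate_argument_error")
  }
  if (any(p < 0 | p > 1)) {
    abort("`p` must be probabilities in [0, 1].",
          class = "pulvalidate_argument_error")
  }
  if (sum(y) == 0 || sum(y) == length(y)) {
    abort("Need at least one event and one non-event.",
          class = "pulvalidate_degenerate_input")
  }
  invisible(TRUE)
}

#' Calibration summary for a cohort of predictions
#'
#' Data-frame-first wrapper combining [calibration_in_the_large()] and
#' [calibration_slope()].
#'
#' @param data Data frame of predictions.
#' @param p Column of predicted probabilities (tidy-eval).
#' @param truth Column of observed events (tidy-eval).
#' @param level Confidence level.
#' @return A `pul_calibration` object; [tidy()] gives a term-level tibble,
#'   [glance()] a one-row summary.
#' @examples
#' set.seed(1)
#' d <- data.frame(p = runif(500, 0.01, 0.6))
#' d$y <- rbinom(500, 1, d$p)
#' glance(calibration_metrics(d, p, y))
#' @export
calibration_metrics <- function(data, p, truth, level = 0.95) {
  pv <- dplyr::pull(data, {{ p }})
  yv <- as.logical(dplyr::pull(data, {{ truth }}))
  citl <- calibration_in_the_large(pv, yv, level)
  slp <- calibration_slope(pv, yv, level)
  structure(list(citl = citl, slope = slp, level = level),
            class = "pul_calibration")
}

#' @export
print.pul_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration-in-the-large %.3f (%.3f to %.3f); slope %.3f (%.3f to %.3f)\n",
    x$citl$citl, x$citl$ci_low, x$citl$ci_high,
    x$slope$slope, x$slope$slope_ci_low, x$slope$slope_ci_high))
  cat(sprintf("mean predicted %.3f vs observed rate %.3f (n = %d)\n",
              x$citl$mean_predicted, x$citl$observed_rate, x$citl$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("calibration_in_the_large", "recalibration_intercept",
             "calibration_slope"),
    estimate = c(x$citl$citl, x$slope$intercept, x$slope$slope),
    conf.low = c(x$citl$ci_low, x$slope$intercept_ci_low,
                 x$slope$slope_ci_low),
    conf.high = c(x$citl$ci_high, x$slope$intercept_ci_high,
                  x$slope$slope_ci_high)
  )
}

#' @exportS3Method generics::glance
glance.pul_calibration <- function(x, ...) {
  tibble::tibble(citl = x$citl$citl, slope = x$slope$slope,
                 mean_predicted = x$citl$mean_predicted,
                 observed_rate = x$citl$observed_rate, n = x$citl$n)
}

#' Loess-smoothed calibration curve
#'
#' Local linear regression (tricube kernel) of the binary outcome on the
#' predicted probability, evaluated on an even grid spanning the observed
#' predictions, with pointwise Wald intervals from the local fit's standard
#' errors. Smoothed values and interval bounds are clipped to `[0, 1]`.
#'
#' @inheritParams calibration_metrics
#' @param span Loess span in (0, 1]; fraction of the data in each local
#'   neighbourhood. Default 0.75.
#' @param degree Local polynomial degree (1 = local linear).
#' @param grid_size Number of evenly spaced evaluation points.
#' @return A `pul_calibration_curve` tibble with columns `predicted`
#'   (grid), `observed` (smoothed proportion), `ci_low`, `ci_high`.
#' @export
calibration_curve <- function(data, p, truth, span = 0.75, degree = 1,
                              grid_size = 100, level = 0.95) {
  pv <- dplyr::pull(data, {{ p }})
  yv <- as.integer(as.logical(dplyr::pull(data, {{ truth }})))
  if (length(pv) < 20) {
    abort("Need at least 20 observations for a loess calibration curve.",
          class = "pulvalidate_small_sample_error")
  }
  if (span <= 0 || span > 1) {
    abort("`span` must lie in (0, 1].", class = "pulvalidate_argument_error")
  }
  fit <- loess(yv ~ pv, span = span, degree = degree, family = "gaussian",
               surface = "direct")
  grid <- seq(min(pv), max(pv), length.out = grid_size)
  pr <- predict(fit, newdata = data.frame(pv = grid), se = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  fit_hat <- unname(pr$fit)
  se_hat <- unname(pr$se.fit)
  out <- tibble::tibble(
    predicted = grid,
    observed = pmin(pmax(fit_hat, 0), 1),
    ci_low = pmin(pmax(fit_hat - z * se_hat, 0), 1),
    ci_high = pmin(pmax(fit_hat + z * se_hat, 0), 1)
  )
  structure(out, class = c("pul_calibration_curve", class(out)),
            span = span, degree = degree, level = level, n = length(pv))
}

#' Is a calibration curve close to the diagonal over a risk band?
#'
#' Operationalises "well calibrated up to risk r": `TRUE` iff the smoothed
#' observed proportion deviates from the identity line by at most `tol` at
#' every grid point whose predicted value lies in `[lo, hi]`.
#'
#' @param curve A `pul_calibration_curve`.
#' @param lo,hi Risk band (inclusive).
#' @param tol Maximum absolute deviation tolerated.
#' @return Logical flag.
#' @export
calibration_band_ok <- function(curve, lo = 0, hi = 0.2, tol = 0.05) {
  stopifnot(inherits(curve, "pul_calibration_curve"))
  idx <- curve$predicted >= lo & curve$predicted <= hi
  if (!any(idx)) {
    abort("No grid points fall inside the requested band.",
          class = "pulvalidate_argument_error")
  }
  all(abs(curve$observed[idx] - curve$predicted[idx]) <= tol)
}

#' Export a calibration curve as CSV
#'
#' @param curve A `pul_calibration_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pul_calibration_curve"))
  readr::write_csv(tibble::as_tibble(curve), path, progress = FALSE)
  invisible(path)
}
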