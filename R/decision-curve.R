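#' Odds weight of a risk threshold
#'
#' A threshold probability `pt` implies the harm-benefit exchange rate a
#' clinician accepts: `w = pt / (1 - pt)` is the weight a false positive
#' carries relative to a true positive, and `1 / w` is the number of false
#' positives accepted per true positive. At the conventional 5% threshold
#' the odds are 1:19, i.e. 19 false positives per correctly identified EP.
#'
#' @param pt Threshold probability strictly inside (0, 1), vectorised.
#' @return `pt / (1 - pt)`.
#' @examples
#' 1 / threshold_weight(0.05) # 19 false positives per true positive
#' @export
threshold_weight <- function(pt) {
  if (any(!is.finite(pt) | pt <= 0 | pt >= 1)) {
    abort("`pt` must lie strictly inside (0, 1).",
          class = "pulvalidate_argument_error")
  }
  pt / (1 - pt)
}

#' Net benefit of a classification at a threshold
#'
#' `nb = tp/n - (fp/n) * pt/(1 - pt)`: true positives per patient minus
#' false positives per patient weighted by the threshold odds. Reported per
#' patient (unit scale).
#'
#' @param tp,fp True/false positive counts.
#' @param n Cohort size (> 0, consistent with the counts).
#' @param pt Threshold probability in (0, 1).
#' @return Net benefit per patient.
#' @examples
#' net_benefit(tp = 226, fp = 412, n = 1061, pt = 0.05)
#' @export
net_benefit <- function(tp, fp, n, pt) {
  stopifnot(n > 0, all(tp + fp <= n), all(tp >= 0), all(fp >= 0))
  tp / n - (fp / n) * threshold_weight(pt)
}

#' Net benefit of the treat-all strategy
#'
#' Classifying everyone as high risk yields `tp/n = prevalence` and
#' `fp/n = 1 - prevalence`, so
#' `nb = prevalence - (1 - prevalence) * pt/(1 - pt)`; it breaks even
#' exactly at `pt = prevalence`.
#'
#' @param prevalence Event prevalence in `[0, 1]`.
#' @param pt Threshold probability in (0, 1), vectorised.
#' @return Net benefit per patient.
#' @export
nb_treat_all <- function(prevalence, pt) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  prevalence - (1 - prevalence) * threshold_weight(pt)
}

#' Decision curve for a model's predicted risks
#'
#' Net benefit of treating according to the model (high risk iff
#' `p_ep >= pt`) at each threshold on the grid, against the treat-all and
#' treat-none (net benefit 0) defaults. `has_utility` is `TRUE` where the
#' model's net benefit exceeds both defaults; a model whose curve falls
#' below a default at some threshold has no clinical utility there.
#'
#' @param data Data frame of predictions.
#' @param p Column of predicted EP probabilities (tidy-eval).
#' @param truth Column of observed EP indicators (tidy-eval).
#' @param grid Strictly increasing thresholds inside (0, 1); default 0.01
#'   to 0.50 by 0.01 (the clinically relevant PUL range).
#' @return A `pul_decision_curve` tibble: `threshold`, `nb_model`,
#'   `nb_all`, `nb_none`, `has_utility`.
#' @export
decision_curve <- function(data, p, truth, grid = seq(0.01, 0.50, by = 0.01)) {
  pv <- dplyr::pull(data, {{ p }})
  yv <- as.logical(dplyr::pull(data, {{ truth }}))
  if (length(pv) == 0) {
    abort("Empty cohort.", class = "pulvalidate_degenerate_input")
  }
  if (any(grid <= 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing inside (0, 1).",
          class = "pulvalidate_argument_error")
  }
  n <- length(pv)
  prev <- mean(yv)
  out <- purrr::map_dfr(grid, function(pt) {
    cc <- confusion_at_threshold(pv, yv, pt)
    tibble::tibble(threshold = pt,
                   nb_model = net_benefit(cc$tp, cc$fp, n, pt),
                   nb_all = nb_treat_all(prev, pt),
                   nb_none = 0)
  })
  out$has_utility <- out$nb_model > pmax(out$nb_all, 0)
  structure(out, class = c("pul_decision_curve", class(out)),
            prevalence = prev, n = n)
}

#' Export a decision curve as CSV
#'
#' @param curve A `pul_decision_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pul_decision_curve"))
  readr::write_csv(tibble::as_tibble(curve), path, progress = FALSE)
  invisible(path)
}
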