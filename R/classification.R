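#' Confusion counts at a risk threshold
#'
#' Applies the high-risk rule `p_ep >= threshold` (see [classify_risk()])
#' and cross-tabulates against the dichotomised outcome.
#'
#' @param p_ep Predicted EP probabilities.
#' @param truth Logical/0-1 EP indicators, aligned with `p_ep`.
#' @param threshold Risk threshold in (0, 1).
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_at_threshold(c(0.9, 0.04, 0.5, 0.02), c(1, 1, 0, 0), 0.05)
#' @export
confusion_at_threshold <- function(p_ep, truth, threshold) {
  y <- as.logical(truth)
  if (length(p_ep) != length(y)) {
    abort("`p_ep` and `truth` must be aligned.",
          class = "pulvalidate_argument_error")
  }
  high <- classify_risk(p_ep, threshold)
  tibble::tibble(
    threshold = threshold,
    tp = sum(high & y), fp = sum(high & !y),
    tn = sum(!high & !y), fn = sum(!high & y)
  )
}

#' Accuracy measures from confusion counts
#'
#' Computes the four measures conventional in PUL triage validation, each
#' with a Wilson score interval:
#' sensitivity `tp/(tp+fn)` (EP classified high risk), false positive rate
#' `fp/(fp+tn)` (non-EP classified high risk), negative predictive value
#' `tn/(tn+fn)` (non-EP among low-risk classifications), and the proportion
#' classified low risk `(tn+fn)/n`. A measure whose denominator is zero is
#' reported as `NA` with `defined = FALSE`, never as 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @param level Confidence level for the Wilson intervals.
#' @return A tibble with columns `measure`, `estimate`, `conf.low`,
#'   `conf.high`, `defined`.
#' @export
accuracy_measures <- function(tp, fp, tn, fn, level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  one <- function(x, d) {
    if (d == 0) {
      tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, defined = FALSE)
    } else {
      dplyr::mutate(wilson_ci(x, d, level), defined = TRUE)
    }
  }
  dplyr::bind_cols(
    tibble::tibble(measure = c("sensitivity", "fpr", "npv", "pct_low_risk")),
    dplyr::bind_rows(one(tp, tp + fn), one(fp, fp + tn),
                     one(tn, tn + fn), one(tn + fn, n))
  )
}

#' Classification accuracy table over risk thresholds
#'
#' Builds the threshold-by-measure accuracy table (sensitivity, FPR, NPV,
#' percent low risk, each with 95% Wilson intervals) for one model's
#' predictions, by default at the 2.5%, 5% and 10% thresholds.
#'
#' @param data Data frame of predictions.
#' @param p Column of predicted EP probabilities (tidy-eval).
#' @param truth Column of observed EP indicators (tidy-eval).
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param level Confidence level.
#' @return A tibble with one row per threshold and measure, plus the
#'   underlying confusion counts.
#' @export
accuracy_table <- function(data, p, truth, thresholds = c(0.025, 0.05, 0.10),
                           level = 0.95) {
  pv <- dplyr::pull(data, {{ p }})
  yv <- as.logical(dplyr::pull(data, {{ truth }}))
  purrr::map_dfr(thresholds, function(thr) {
    cc <- confusion_at_threshold(pv, yv, thr)
    meas <- accuracy_measures(cc$tp, cc$fp, cc$tn, cc$fn, level)
    dplyr::bind_cols(cc[rep(1, nrow(meas)), ], meas)
  })
}

#' Export an accuracy table as CSV
#'
#' @param table Output of [accuracy_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_accuracy_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' McNemar's test for paired high-risk classifications
#'
#' Compares two models' high-risk calls on the same records through the
#' discordant pairs: `b` = records model A calls high and B calls low,
#' `c` = the reverse. Restricting to true positives compares sensitivities;
#' restricting to true negatives compares false positive rates. The exact
#' two-sided binomial p-value is used when `b + c < 25`, the
#' continuity-corrected chi-square otherwise (the rule used is reported in
#' the result). Zero discordance gives `p = 1` by convention.
#'
#' @param high_a,high_b Logical high-risk flags from the two models,
#'   aligned on the same records.
#' @param truth Logical EP indicators; required when `restrict` is not
#'   `"all"`.
#' @param restrict `"all"`, `"positives"` or `"negatives"`.
#' @return A list: `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_paired <- function(high_a, high_b, truth = NULL,
                           restrict = c("all", "positives", "negatives")) {
  restrict <- match.arg(restrict)
  if (length(high_a) != length(high_b)) {
    abort("`high_a` and `high_b` must be aligned.",
          class = "pulvalidate_argument_error")
  }
  keep <- rep(TRUE, length(high_a))
  if (restrict != "all") {
    if (is.null(truth)) {
      abort("`truth` is required when restricting to a class.",
            class = "pulvalidate_argument_error")
    }
    keep <- if (restrict == "positives") as.logical(truth) else !as.logical(truth)
  }
  a <- as.logical(high_a)[keep]
  b_ <- as.logical(high_b)[keep]
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  if (b + cc == 0) {
    return(list(b = b, c = cc, p_value = 1,
                method = "no discordant pairs (p = 1 by convention)"))
  }
  if (b + cc < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact binomial (b + c < 25)"
  } else {
    tab <- matrix(c(0, cc, b, 0), nrow = 2) + diag(c(sum(a & b_), sum(!a & !b_)))
    p <- mcnemar.test(tab, correct = TRUE)$p.value
    method <- "chi-square with continuity correction (b + c >= 25)"
  }
  list(b = b, c = cc, p_value = p, method = method)
}
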