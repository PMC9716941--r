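#' Mann-Whitney AUC from class-separated scores
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen positive scores higher than a randomly chosen negative, with ties
#' counting one half. Computed via midranks in O(n log n); identical to the
#' brute-force pairwise count.
#'
#' @param pos_scores Scores of the positive class (nonempty).
#' @param neg_scores Scores of the negative class (nonempty).
#' @return The AUC as a single number in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(0.9, 0.4), c(0.5, 0.1)) # 0.75
#' @export
auc_mann_whitney <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    abort("Both classes must be nonempty to compute an AUC.",
          class = "pulvalidate_degenerate_input")
  }
  m <- length(pos_scores)
  n <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# Placement components of the DeLong construction. V10[i] is the fraction
# of negatives that positive i beats (ties half); V01[j] likewise for
# negative j against the positives. mean(V10) = mean(V01) = AUC.
delong_placements <- function(pos_scores, neg_scores) {
  m <- length(pos_scores)
  n <- length(neg_scores)
  r_all <- rank(c(pos_scores, neg_scores), ties.method = "average")
  r_pos <- rank(pos_scores, ties.method = "average")
  r_neg <- rank(neg_scores, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong AUC and its sampling variance
#'
#' Uses the structural-components construction: the variance of the AUC is
#' `var(V10)/n_pos + var(V01)/n_neg`, where `V10` and `V01` are the
#' per-observation placement values. Under perfect separation all
#' components are equal, the variance estimate is exactly 0, and a
#' `degenerate` flag is set (with a warning) since a Wald interval then
#' collapses.
#'
#' @inheritParams auc_mann_whitney
#' @return A list with `auc`, `variance`, `n_pos`, `n_neg`, `degenerate`.
#' @export
delong_variance <- function(pos_scores, neg_scores) {
  if (length(pos_scores) < 2 || length(neg_scores) < 2) {
    abort("Need at least 2 observations per class for a DeLong variance.",
          class = "pulvalidate_degenerate_input")
  }
  pl <- delong_placements(pos_scores, neg_scores)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  degenerate <- v <= 0
  if (degenerate) {
    warn("Degenerate DeLong variance (all placement components equal).")
  }
  list(auc = pl$auc, variance = v,
       n_pos = length(pos_scores), n_neg = length(neg_scores),
       degenerate = degenerate)
}

#' Wald confidence interval for an AUC
#'
#' `auc +/- z * sqrt(variance)`, truncated to `[0, 1]`.
#'
#' @param auc AUC point estimate.
#' @param variance DeLong variance estimate (nonnegative).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(auc, variance, level = 0.95) {
  stopifnot(variance >= 0, level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  c(max(0, auc - half), min(1, auc + half))
}

#' ROC discrimination of predicted EP risk
#'
#' Data-frame-first wrapper producing the AUC with DeLong variance and a
#' Wald 95% interval for one score column against the dichotomised truth.
#'
#' @param data A data frame of predictions.
#' @param score Column of predicted probabilities (tidy-eval).
#' @param truth Column of logical/0-1 event indicators (tidy-eval).
#' @param level Confidence level for the interval.
#' @return A `pul_auc` object; use [tidy()] for a one-row tibble.
#' @examples
#' d <- data.frame(p = c(0.9, 0.4, 0.5, 0.1, 0.2), y = c(1, 1, 0, 0, 1))
#' tidy(roc_auc(d, p, y))
#' @export
roc_auc <- function(data, score, truth, level = 0.95) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.logical(dplyr::pull(data, {{ truth }}))
  dl <- delong_variance(s[y], s[!y])
  ci <- auc_ci(dl$auc, dl$variance, level)
  structure(list(auc = dl$auc, variance = dl$variance,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 n_pos = dl$n_pos, n_neg = dl$n_neg,
                 degenerate = dl$degenerate),
            class = "pul_auc")
}

#' @export
print.pul_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f to %.3f), %d events / %d non-events\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_auc <- function(x, ...) {
  tibble::tibble(auc = x$auc, variance = x$variance,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve points
#'
#' Exports the empirical (FPR, TPR) pairs over all distinct score cut-offs
#' (rule: positive when score >= cut-off), for plotting or CSV export.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(data, score, truth) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.logical(dplyr::pull(data, {{ truth }}))
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE))
  purrr::map_dfr(cuts, function(ct) {
    hi <- s >= ct
    tibble::tibble(threshold = ct,
                   fpr = sum(hi & !y) / sum(!y),
                   tpr = sum(hi & y) / sum(y))
  })
}

#' DeLong's paired test for the difference of two AUCs
#'
#' Both models score the same records, so the two AUC estimates are
#' correlated; the paired DeLong construction estimates the covariance from
#' the placement components and refers
#' `z = (auc_a - auc_b) / sd(auc_a - auc_b)` to the standard normal
#' (two-sided).
#'
#' @param data A data frame of predictions from both models.
#' @param score_a,score_b Score columns for the two models (tidy-eval).
#' @param truth Event indicator column (tidy-eval).
#' @return A `pul_delong_test` with fields `auc_a`, `auc_b`, `difference`,
#'   `z`, `p_value`; use [tidy()] for a tibble.
#' @export
delong_test <- function(data, score_a, score_b, truth) {
  sa <- dplyr::pull(data, {{ score_a }})
  sb <- dplyr::pull(data, {{ score_b }})
  y <- as.logical(dplyr::pull(data, {{ truth }}))
  if (length(sa) != length(sb) || length(sa) != length(y)) {
    abort("Scores and truth must be aligned on the same records.",
          class = "pulvalidate_argument_error")
  }
  pa <- delong_placements(sa[y], sa[!y])
  pb <- delong_placements(sb[y], sb[!y])
  m <- sum(y); n <- sum(!y)
  if (m < 2 || n < 2) {
    abort("Need at least 2 events and 2 non-events.",
          class = "pulvalidate_degenerate_input")
  }
  diff_v10 <- pa$v10 - pb$v10
  diff_v01 <- pa$v01 - pb$v01
  var_diff <- var(diff_v10) / m + var(diff_v01) / n
  difference <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (isTRUE(all.equal(sa, sb)) || abs(difference) < 1e-15) {
      z <- 0; p <- 1
    } else {
      abort("Degenerate variance of the AUC difference.",
            class = "pulvalidate_degenerate_input")
    }
  } else {
    z <- difference / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = difference,
                 variance = var_diff, z = z, p_value = p),
            class = "pul_delong_test")
}

#' @export
print.pul_delong_test <- function(x, ...) {
  cat(sprintf(
    "Paired DeLong test: AUC %.3f vs %.3f (diff %.3f), z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$difference, x$z, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_delong_test <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b,
                 difference = x$difference, statistic = x$z,
                 p.value = x$p_value)
}
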