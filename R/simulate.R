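#' Parameters of the synthetic PUL cohort generator
#'
#' Defaults emulate the marginal structure of a large single-centre PUL
#' validation cohort: outcome mix 461 failed PUL / 362 IUP / 238 EP (46 of
#' them persisting PUL) out of 1061; first hCG log-normal with median
#' 703 IU/L and log-sd matched so the theoretical quartiles hit 210 and
#' 2312; hCG-ratio log-normal per outcome class with medians (failed 0.50,
#' IUP 2.0, EP 1.05; log-sd 0.5 each) chosen so the mixture median is about
#' 0.94, truncated to the plausible range 0.06-5.65; sampling interval
#' drawn 13% / 71% / 16% from the 24-39 / 40-56 / 57-72 h bins, uniform
#' within bin; covariate flag rates from the same cohort (bleeding 68%,
#' prior EP 7%, IUD 3%, inpatient 8%).
#'
#' `ratio_marginal_*` govern the single marginal ratio distribution used by
#' the model-consistent generator [simulate_from_model()] (median 0.94,
#' log-sd quartile-matched to the 0.45-1.59 IQR). `frac_gtd`, `frac_lost`
#' and `frac_out_of_window` optionally contaminate the cohort with records
#' that the inclusion filter should remove (all default 0).
#'
#' @param ... Named overrides of any default listed above.
#' @return A `pul_sim_params` list.
#' @export
sim_params <- function(...) {
  z75 <- qnorm(0.75)
  p <- list(
    prevalences = c(failed_pul = 461, iup = 362, ep = 238) / 1061,
    hcg1_log_median = log(703),
    hcg1_log_sd = (log(2312) - log(210)) / (2 * z75),
    ratio_log_median = c(failed_pul = log(0.50), iup = log(2.0),
                         ep = log(1.05)),
    ratio_log_sd = c(failed_pul = 0.5, iup = 0.5, ep = 0.5),
    ratio_range = c(0.06, 5.65),
    ratio_marginal_log_median = log(0.94),
    ratio_marginal_log_sd = (log(1.59) - log(0.45)) / (2 * z75),
    interval_mix = c("24-39" = 0.13, "40-56" = 0.71, "57-72" = 0.16),
    interval_bounds = list("24-39" = c(24, 39), "40-56" = c(40, 56),
                           "57-72" = c(57, 72)),
    age_median = 31, age_sd = (35 - 26) / (2 * z75), age_range = c(15, 49),
    covariate_rates = c(bleeding = 723 / 1061, prior_ep = 76 / 1061,
                        iud = 30 / 1061, inpatient = 89 / 1061),
    pul_type_mix = c(true_pul = 793, probable_iup = 239,
                     probable_ep = 29) / 1061,
    ppul_fraction_of_ep = 46 / 238,
    frac_gtd = 0, frac_lost = 0, frac_out_of_window = 0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    abort(paste0("Unknown generator parameter(s): ",
                 paste(unknown, collapse = ", ")),
          class = "pulvalidate_argument_error")
  }
  p <- modifyList(p, over)
  stopifnot(abs(sum(p$prevalences) - 1) < 1e-8,
            abs(sum(p$interval_mix) - 1) < 1e-8,
            all(p$ratio_log_sd > 0), p$hcg1_log_sd > 0)
  structure(p, class = "pul_sim_params")
}

# Run expr with a locally seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

draw_covariates <- function(n, params) {
  age <- pmin(pmax(round(stats::rnorm(n, params$age_median, params$age_sd)),
                   params$age_range[1]), params$age_range[2])
  hcg1 <- rlnorm(n, params$hcg1_log_median, params$hcg1_log_sd)
  bins <- sample(names(params$interval_mix), n, replace = TRUE,
                 prob = params$interval_mix)
  interval_hours <- vapply(bins, function(b) {
    bd <- params$interval_bounds[[b]]
    runif(1, bd[1], bd[2])
  }, numeric(1), USE.NAMES = FALSE)
  if (params$frac_out_of_window > 0) {
    idx <- runif(n) < params$frac_out_of_window
    lo <- runif(n) < 0.5
    interval_hours[idx & lo] <- runif(sum(idx & lo), 8, 23)
    interval_hours[idx & !lo] <- runif(sum(idx & !lo), 73, 120)
  }
  tibble::tibble(
    age = age, hcg1 = hcg1, interval_hours = interval_hours,
    bleeding = runif(n) < params$covariate_rates[["bleeding"]],
    prior_ep = runif(n) < params$covariate_rates[["prior_ep"]],
    iud = runif(n) < params$covariate_rates[["iud"]],
    inpatient = runif(n) < params$covariate_rates[["inpatient"]],
    pul_type = sample(names(params$pul_type_mix), n, replace = TRUE,
                      prob = params$pul_type_mix)
  )
}

contaminate <- function(cohort, params) {
  n <- nrow(cohort)
  if (params$frac_gtd > 0) {
    cohort$outcome[runif(n) < params$frac_gtd] <- "gtd"
  }
  if (params$frac_lost > 0) {
    idx <- cohort$outcome != "gtd" & runif(n) < params$frac_lost
    cohort$outcome[idx] <- "lost"
  }
  cohort
}

#' Simulate a descriptive synthetic PUL cohort
#'
#' Draws outcome classes from the configured prevalence mixture, the first
#' hCG from its log-normal, and the hCG ratio from the class-conditional
#' log-normal (truncated to the plausible range), so the marginal medians
#' and the outcome mix match the targets in [sim_params()]. A share of the
#' EP records is labelled `ppul` (persisting PUL), which the analysis
#' groups with EP. Fully reproducible from `seed`.
#'
#' @param n Cohort size.
#' @param params A `pul_sim_params` list from [sim_params()].
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return A [pul_cohort] tibble; the generating class of each record is
#'   attached as the `"ground_truth"` attribute tibble (`id`,
#'   `true_class`).
#' @examples
#' cohort <- simulate_pul_cohort(200, seed = 1)
#' dplyr::count(cohort, outcome)
#' @export
simulate_pul_cohort <- function(n = 1061, params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "pul_sim_params"), n >= 1)
  with_local_seed(seed, {
    classes <- sample(names(params$prevalences), n, replace = TRUE,
                      prob = params$prevalences)
    cohort <- draw_covariates(n, params)
    ratio <- rlnorm(n, params$ratio_log_median[classes],
                    params$ratio_log_sd[classes])
    ratio <- pmin(pmax(ratio, params$ratio_range[1]), params$ratio_range[2])
    cohort <- dplyr::mutate(
      cohort,
      id = sprintf("syn-%06d", seq_len(n)),
      hcg2 = .data$hcg1 * ratio,
      outcome = classes,
      .before = 1
    )
    is_ep <- cohort$outcome == "ep"
    ppul <- is_ep & runif(n) < params$ppul_fraction_of_ep
    cohort$outcome[ppul] <- "ppul"
    cohort <- contaminate(cohort, params)
    cohort <- cohort[, c("id", "age", "hcg1", "hcg2", "interval_hours",
                         "bleeding", "prior_ep", "iud", "inpatient",
                         "pul_type", "outcome")]
    attr(cohort, "ground_truth") <- tibble::tibble(id = cohort$id,
                                                   true_class = classes)
    cohort
  })
}

#' Simulate a cohort whose outcomes follow a given risk model
#'
#' Draws the covariates (first hCG, a single marginal hCG-ratio
#' distribution, sampling interval, flags) and then draws each record's
#' outcome from the probabilities the supplied model assigns to it. Scoring
#' that same model on the result is therefore perfectly calibrated by
#' construction (calibration slope 1, calibration-in-the-large 0 in
#' expectation), which gives downstream validation code a known-truth
#' fixture.
#'
#' @param model A `pul_model`.
#' @param n Cohort size.
#' @param params A `pul_sim_params`; only the covariate settings are used.
#' @param seed Integer seed.
#' @return A [pul_cohort] tibble with `"ground_truth"` attribute tibble
#'   (`id`, `p_failed`, `p_iup`, `p_ep`, `true_class`).
#' @export
simulate_from_model <- function(model, n, params = sim_params(), seed = NULL) {
  stopifnot(inherits(model, "pul_model"), n >= 1)
  with_local_seed(seed, {
    cohort <- draw_covariates(n, params)
    ratio <- rlnorm(n, params$ratio_marginal_log_median,
                    params$ratio_marginal_log_sd)
    ratio <- pmin(pmax(ratio, params$ratio_range[1]), params$ratio_range[2])
    cohort <- dplyr::mutate(
      cohort,
      id = sprintf("sim-%06d", seq_len(n)),
      hcg2 = .data$hcg1 * ratio,
      .before = 1
    )
    scored <- predict_pul(cohort, model)
    u <- runif(n)
    outcome <- ifelse(u < scored$p_failed, "failed_pul",
                      ifelse(u < scored$p_failed + scored$p_iup, "iup", "ep"))
    cohort$outcome <- outcome
    cohort <- cohort[, c("id", "age", "hcg1", "hcg2", "interval_hours",
                         "bleeding", "prior_ep", "iud", "inpatient",
                         "pul_type", "outcome")]
    attr(cohort, "ground_truth") <- tibble::tibble(
      id = cohort$id, p_failed = scored$p_failed, p_iup = scored$p_iup,
      p_ep = scored$p_ep, true_class = outcome)
    cohort
  })
}

#' Retrieve the generator's ground truth for a synthetic cohort
#'
#' @param cohort A cohort from [simulate_pul_cohort()] or
#'   [simulate_from_model()].
#' @return The ground-truth tibble stored by the generator.
#' @export
ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) {
    abort("No ground truth attached; not a generated cohort?",
          class = "pulvalidate_argument_error")
  }
  gt
}

#' Adjudicate a persisting PUL from an hCG follow-up series
#'
#' A persisting PUL (plateauing hCG) is called when at least three
#' consecutive measurements within a 1-week window all change by less than
#' 15% relative to the preceding value. Fewer than three measurements can
#' never qualify.
#'
#' @param values Ordered hCG measurements (IU/L).
#' @param times_days Measurement times in days, nondecreasing, aligned with
#'   `values`.
#' @return `TRUE` if a plateau run is found.
#' @examples
#' adjudicate_ppul(c(1000, 900, 990, 940), c(0, 2, 4, 5)) # TRUE
#' adjudicate_ppul(c(1000, 800, 640), c(0, 2, 4))         # FALSE
#' @export
adjudicate_ppul <- function(values, times_days = seq_along(values) - 1) {
  stopifnot(length(values) == length(times_days),
            !is.unsorted(times_days))
  k <- length(values)
  if (k < 3) return(FALSE)
  ok <- abs(diff(values)) / values[-k] < 0.15
  for (i in seq_len(k - 2)) {
    if (ok[i] && ok[i + 1] && times_days[i + 2] - times_days[i] <= 7) {
      return(TRUE)
    }
  }
  FALSE
}
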