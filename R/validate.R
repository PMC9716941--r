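#' Run the full external-validation battery on a PUL cohort
#'
#' End-to-end pipeline: applies the inclusion criteria, scores each model,
#' dichotomises the outcome into EP vs non-EP, and computes discrimination
#' (AUC with DeLong variance), calibration (calibration-in-the-large,
#' slope, loess curve), threshold classification accuracy, and the decision
#' curve. With two models it also runs the paired DeLong test and McNemar
#' comparisons of sensitivity and false positive rate at each threshold.
#' Deterministic given its inputs.
#'
#' @param cohort A [pul_cohort] tibble (unfiltered; the interval window and
#'   GTD/lost exclusions are applied here).
#' @param models A named list of `pul_model` objects (one or two), or a
#'   single `pul_model`.
#' @param thresholds Classification thresholds; default 2.5%, 5%, 10%.
#' @param min_hours,max_hours Inclusive sampling-interval window; set
#'   `min_hours = 0, max_hours = Inf` to keep all intervals.
#' @param span,grid_size Loess calibration-curve settings.
#' @param dc_grid Decision-curve threshold grid.
#' @param out_dir Optional directory; when given, the report JSON and the
#'   per-model curve/table CSVs are written there.
#' @return A `pul_validation` object; see [tidy()] and [glance()] methods.
#' @examples
#' m <- model_spec("toy",
#'   iup = c(intercept = -1, log_ratio = 2),
#'   ep = c(intercept = -1, log_ratio_sq = -1))
#' cohort <- simulate_from_model(m, 500, seed = 42)
#' rep <- pul_validate(cohort, list(toy = m))
#' glance(rep)
#' @export
pul_validate <- function(cohort, models,
                         thresholds = c(0.025, 0.05, 0.10),
                         min_hours = 24, max_hours = 72,
                         span = 0.75, grid_size = 100,
                         dc_grid = seq(0.01, 0.50, by = 0.01),
                         out_dir = NULL) {
  if (inherits(models, "pul_model")) {
    models <- stats::setNames(list(models), models$name)
  }
  if (length(models) < 1 || length(models) > 2 ||
      !all(vapply(models, inherits, logical(1), "pul_model"))) {
    abort("`models` must be one or two `pul_model` objects.",
          class = "pulvalidate_config_error")
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, character(1), "name")
  }
  filtered <- apply_inclusion(cohort, min_hours = min_hours,
                              max_hours = max_hours)
  if (nrow(filtered) == 0) {
    abort("No records left after inclusion criteria.",
          class = "pulvalidate_data_error")
  }
  filtered$ep <- dichotomize_outcome(filtered$outcome)
  cohort_summary <- list(
    n = nrow(filtered),
    outcome_counts = table(filtered$outcome),
    n_ep = sum(filtered$ep),
    prevalence = mean(filtered$ep),
    exclusions = exclusion_log(filtered)$counts
  )

  per_model <- purrr::imap(models, function(model, label) {
    scored <- predict_pul(filtered, model)
    list(
      label = label,
      scored = scored,
      auc = roc_auc(scored, "p_ep", "ep"),
      calibration = calibration_metrics(scored, "p_ep", "ep"),
      curve = calibration_curve(scored, "p_ep", "ep",
                                span = span, grid_size = grid_size),
      accuracy = accuracy_table(scored, "p_ep", "ep",
                                thresholds = thresholds),
      dc = decision_curve(scored, "p_ep", "ep", grid = dc_grid)
    )
  })

  pairwise <- NULL
  if (length(per_model) == 2) {
    a <- per_model[[1]]; b <- per_model[[2]]
    both <- dplyr::tibble(p_a = a$scored$p_ep, p_b = b$scored$p_ep,
                          ep = filtered$ep)
    mcnemar <- purrr::map_dfr(thresholds, function(thr) {
      ha <- classify_risk(both$p_a, thr)
      hb <- classify_risk(both$p_b, thr)
      purrr::map_dfr(c(sens = "positives", fpr = "negatives",
                       overall = "all"), function(r) {
        res <- mcnemar_paired(ha, hb, both$ep, restrict = r)
        tibble::tibble(threshold = thr, restrict = r, b = res$b, c = res$c,
                       p.value = res$p_value, method = res$method)
      })
    })
    pairwise <- list(delong = delong_test(both, "p_a", "p_b", "ep"),
                     mcnemar = mcnemar)
  }

  report <- structure(
    list(cohort = cohort_summary, models = per_model, pairwise = pairwise,
         settings = list(thresholds = thresholds, min_hours = min_hours,
                         max_hours = max_hours, span = span,
                         dc_grid_range = range(dc_grid)),
         version = as.character(utils::packageVersion("pulvalidate"))),
    class = "pul_validation")
  if (!is.null(out_dir)) {
    write_validation_report(report, out_dir)
  }
  report
}

#' @export
print.pul_validation <- function(x, ...) {
  cat("PUL external-validation report\n")
  cat(sprintf("  cohort: n = %d, EP prevalence = %.1f%% (%d events)\n",
              x$cohort$n, 100 * x$cohort$prevalence, x$cohort$n_ep))
  for (m in x$models) {
    cat(sprintf("  %s: AUC %.3f (%.3f-%.3f), CITL %.3f, slope %.3f\n",
                m$label, m$auc$auc, m$auc$ci_low, m$auc$ci_high,
                m$calibration$citl$citl, m$calibration$slope$slope))
  }
  if (!is.null(x$pairwise)) {
    print(x$pairwise$delong)
  }
  invisible(x)
}

#' @rdname pul_validate
#' @param x A `pul_validation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pul_validation <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::mutate(m$accuracy, model = m$label, .before = 1)
  })
}

#' @rdname pul_validate
#' @exportS3Method generics::glance
glance.pul_validation <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    nb5 <- m$dc[which.min(abs(m$dc$threshold - 0.05)), ]
    tibble::tibble(
      model = m$label, n = x$cohort$n, prevalence = x$cohort$prevalence,
      auc = m$auc$auc, auc_low = m$auc$ci_low, auc_high = m$auc$ci_high,
      citl = m$calibration$citl$citl, slope = m$calibration$slope$slope,
      nb_at_5pct = nb5$nb_model
    )
  })
}

#' Write a validation report and its curve/table artifacts to disk
#'
#' Writes `report.json` (summary numbers plus run metadata) and, per model,
#' the calibration curve, accuracy table and decision curve as CSV.
#'
#' @param report A `pul_validation`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_validation_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pul_validation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in report$models) {
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(m$label))
    write_calibration_curve(m$curve,
                            file.path(out_dir, paste0(slug, "_calibration.csv")))
    write_accuracy_table(m$accuracy,
                         file.path(out_dir, paste0(slug, "_accuracy.csv")))
    write_decision_curve(m$dc,
                         file.path(out_dir, paste0(slug, "_decision_curve.csv")))
  }
  summary <- list(
    cohort = list(n = report$cohort$n, n_ep = report$cohort$n_ep,
                  prevalence = report$cohort$prevalence,
                  outcome_counts = as.list(report$cohort$outcome_counts)),
    models = purrr::map(report$models, function(m) {
      list(auc = m$auc$auc, auc_ci = c(m$auc$ci_low, m$auc$ci_high),
           citl = m$calibration$citl$citl,
           slope = m$calibration$slope$slope,
           accuracy = m$accuracy[, c("threshold", "measure", "estimate",
                                     "conf.low", "conf.high")])
    }),
    pairwise = if (!is.null(report$pairwise)) {
      list(delong = unclass(tidy(report$pairwise$delong)),
           mcnemar = report$pairwise$mcnemar)
    },
    settings = report$settings,
    metadata = list(version = report$version,
                    timestamp = format(Sys.time(), tz = "UTC"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Sensitivity analysis: validate with and without the interval window
#'
#' Runs [pul_validate()] twice — once restricted to the 24-72 h sampling
#' window and once keeping every interval — and tabulates the side-by-side
#' difference of each accuracy measure, the AUC, and the calibration
#' summary. A cohort already confined to the window yields zero deltas.
#'
#' @inheritParams pul_validate
#' @return A `pul_sensitivity` list: `windowed` and `all_intervals`
#'   (`pul_validation` objects) and `delta` (tibble of measure
#'   differences, all-intervals minus windowed).
#' @export
pul_sensitivity <- function(cohort, models,
                            thresholds = c(0.025, 0.05, 0.10),
                            min_hours = 24, max_hours = 72, ...) {
  windowed <- pul_validate(cohort, models, thresholds = thresholds,
                           min_hours = min_hours, max_hours = max_hours, ...)
  all_int <- pul_validate(cohort, models, thresholds = thresholds,
                          min_hours = 0, max_hours = Inf, ...)
  key <- c("model", "threshold", "measure")
  acc_w <- tidy(windowed)[, c(key, "estimate")]
  acc_a <- tidy(all_int)[, c(key, "estimate")]
  acc <- dplyr::full_join(acc_w, acc_a, by = key,
                          suffix = c("_windowed", "_all"))
  extra <- purrr::map_dfr(names(windowed$models), function(lb) {
    w <- windowed$models[[lb]]; a <- all_int$models[[lb]]
    tibble::tibble(
      model = lb, threshold = NA_real_,
      measure = c("auc", "citl", "slope"),
      estimate_windowed = c(w$auc$auc, w$calibration$citl$citl,
                            w$calibration$slope$slope),
      estimate_all = c(a$auc$auc, a$calibration$citl$citl,
                       a$calibration$slope$slope)
    )
  })
  delta <- dplyr::mutate(dplyr::bind_rows(acc, extra),
                         delta = .data$estimate_all - .data$estimate_windowed)
  structure(list(windowed = windowed, all_intervals = all_int, delta = delta),
            class = "pul_sensitivity")
}

#' @export
print.pul_sensitivity <- function(x, ...) {
  cat("Sensitivity analysis (all intervals vs 24-72 h window)\n")
  cat(sprintf("  windowed n = %d, all-intervals n = %d\n",
              x$windowed$cohort$n, x$all_intervals$cohort$n))
  print(x$delta, n = 20)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_sensitivity <- function(x, ...) x$delta
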