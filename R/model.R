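#' Basis functions available to PUL risk models
#'
#' Triage models of the M4/M6 family are polynomial multinomial logistic
#' regressions in the (natural) logs of the first hCG and of the hCG ratio.
#' The registry below names every basis term a model configuration may use;
#' an unknown name in a configuration is rejected at load time so that a
#' coefficient typo cannot silently evaluate to zero.
#'
#' @return Character vector of valid basis-function names.
#' @export
basis_functions <- function() {
  names(.basis_registry)
}

.basis_registry <- list(
  intercept = function(log_hcg1, log_ratio) rep(1, length(log_hcg1)),
  log_hcg1 = function(log_hcg1, log_ratio) log_hcg1,
  log_hcg1_sq = function(log_hcg1, log_ratio) log_hcg1^2,
  log_ratio = function(log_hcg1, log_ratio) log_ratio,
  log_ratio_sq = function(log_hcg1, log_ratio) log_ratio^2,
  log_hcg1_x_log_ratio = function(log_hcg1, log_ratio) log_hcg1 * log_ratio
)

check_terms <- function(terms, outcome) {
  if (length(terms) == 0) {
    abort(paste0("Logit for `", outcome, "` has no terms."),
          class = "pulvalidate_config_error")
  }
  unknown <- setdiff(names(terms), basis_functions())
  if (length(unknown) > 0) {
    abort(paste0("Unknown basis function(s) in `", outcome, "` logit: ",
                 paste(unknown, collapse = ", ")),
          class = "pulvalidate_config_error")
  }
  if (anyDuplicated(names(terms))) {
    abort(paste0("Duplicate basis function in `", outcome, "` logit."),
          class = "pulvalidate_config_error")
  }
  vals <- unlist(terms, use.names = FALSE)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    abort(paste0("Non-finite coefficient in `", outcome, "` logit."),
          class = "pulvalidate_config_error")
  }
  lapply(terms, as.numeric)
}

#' Construct a PUL risk-model specification
#'
#' A model is a three-class multinomial logistic regression with
#' `failed_pul` as the reference outcome; the `iup` and `ep` linear
#' predictors are sums of coefficient x basis-function terms (see
#' [basis_functions()]).
#'
#' @param name Model name, e.g. `"M6NP"`.
#' @param iup,ep Named numeric lists/vectors mapping basis-function names
#'   to coefficients for the IUP and EP logits.
#' @return A `pul_model` object.
#' @examples
#' model_spec("toy",
#'   iup = c(intercept = -1, log_ratio = 2),
#'   ep = c(intercept = -0.5, log_ratio_sq = -1))
#' @export
model_spec <- function(name, iup, ep) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("Model `name` must be a nonempty string.",
          class = "pulvalidate_config_error")
  }
  spec <- structure(
    list(name = name,
         reference = "failed_pul",
         logits = list(iup = check_terms(as.list(iup), "iup"),
                       ep = check_terms(as.list(ep), "ep"))),
    class = "pul_model")
  spec
}

#' @export
print.pul_model <- function(x, ...) {
  cat("PUL risk model '", x$name, "' (reference outcome: ", x$reference,
      ")\n", sep = "")
  for (oc in names(x$logits)) {
    terms <- x$logits[[oc]]
    cat("  ", oc, " logit: ",
        paste(sprintf("%s=%.6g", names(terms), unlist(terms)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pul_model <- function(x, ...) {
  purrr::map_dfr(names(x$logits), function(oc) {
    tibble::tibble(outcome = oc,
                   term = names(x$logits[[oc]]),
                   estimate = unlist(x$logits[[oc]], use.names = FALSE))
  })
}

#' Read a risk-model specification from JSON
#'
#' Expected schema:
#' `{"name": str, "reference": "failed_pul",
#'   "logits": {"iup": {basis: coeff, ...}, "ep": {...}}}`.
#' Unknown top-level keys, unknown basis names, a missing logit or a
#' reference other than `failed_pul` are load-time errors.
#'
#' @param path JSON file path.
#' @return A `pul_model`.
#' @export
read_model_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  extra <- setdiff(names(cfg), c("name", "reference", "logits"))
  if (length(extra) > 0) {
    abort(paste0("Unknown key(s) in model config: ",
                 paste(extra, collapse = ", ")),
          class = "pulvalidate_config_error")
  }
  if (is.null(cfg$name) || is.null(cfg$logits)) {
    abort("Model config needs `name` and `logits`.",
          class = "pulvalidate_config_error")
  }
  if (!is.null(cfg$reference) && !identical(cfg$reference, "failed_pul")) {
    abort("`reference` must be \"failed_pul\".",
          class = "pulvalidate_config_error")
  }
  extra_logits <- setdiff(names(cfg$logits), c("iup", "ep"))
  if (length(extra_logits) > 0 || !all(c("iup", "ep") %in% names(cfg$logits))) {
    abort("`logits` must contain exactly `iup` and `ep`.",
          class = "pulvalidate_config_error")
  }
  model_spec(cfg$name, iup = cfg$logits$iup, ep = cfg$logits$ep)
}

#' Write a risk-model specification to JSON
#'
#' Round-trips losslessly with [read_model_spec()].
#'
#' @param model A `pul_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "pul_model"))
  jsonlite::write_json(
    list(name = model$name, reference = model$reference,
         logits = model$logits),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Evaluate one outcome logit's linear predictor for a cohort.
linear_predictor <- function(cohort, terms) {
  lh <- log(cohort$hcg1)
  lr <- log(cohort$hcg2 / cohort$hcg1)
  eta <- rep(0, nrow(cohort))
  for (nm in names(terms)) {
    eta <- eta + terms[[nm]] * .basis_registry[[nm]](lh, lr)
  }
  eta
}

#' Predict PUL outcome probabilities for a cohort
#'
#' Evaluates the model's IUP and EP linear predictors for each record and
#' converts them to outcome probabilities with a numerically stable softmax
#' (the reference `failed_pul` logit is identically 0; the row maximum is
#' subtracted before exponentiation). The three probabilities are each in
#' (0, 1) and sum to 1 to within 1e-12.
#'
#' @param cohort A [pul_cohort] tibble (needs `hcg1`, `hcg2`).
#' @param model A `pul_model` from [model_spec()] or [read_model_spec()].
#' @return The cohort with added columns `p_failed`, `p_iup`, `p_ep` and
#'   `predicted_outcome` (argmax label).
#' @export
predict_pul <- function(cohort, model) {
  stopifnot(inherits(model, "pul_model"))
  cohort <- tibble::as_tibble(cohort)
  if (any(!is.finite(cohort$hcg1) | cohort$hcg1 <= 0) ||
      any(!is.finite(cohort$hcg2) | cohort$hcg2 <= 0)) {
    abort("hCG values must be positive for prediction.",
          class = "pulvalidate_invalid_record")
  }
  eta <- cbind(failed_pul = 0,
               iup = linear_predictor(cohort, model$logits$iup),
               ep = linear_predictor(cohort, model$logits$ep))
  bad <- !is.finite(eta[, "iup"]) | !is.finite(eta[, "ep"])
  if (any(bad)) {
    ids <- if ("id" %in% names(cohort)) cohort$id[bad] else which(bad)
    abort(paste0("Non-finite linear predictor for record(s): ",
                 paste(utils::head(ids, 5), collapse = ", ")),
          class = "pulvalidate_numeric_error")
  }
  p <- softmax_rows(eta)
  cohort$p_failed <- unname(p[, "failed_pul"])
  cohort$p_iup <- unname(p[, "iup"])
  cohort$p_ep <- unname(p[, "ep"])
  cohort$predicted_outcome <- predicted_outcome(p[, "failed_pul"],
                                                p[, "iup"], p[, "ep"])
  cohort
}

#' Classify predicted EP risk at a probability threshold
#'
#' A record is high risk when its predicted EP probability reaches the
#' threshold, i.e. `p_ep >= threshold` (the boundary counts as high risk).
#'
#' @param p_ep Predicted EP probabilities.
#' @param threshold Risk threshold in (0, 1); the conventional clinical
#'   cut-off is 0.05.
#' @return Logical vector: `TRUE` for high risk.
#' @examples
#' classify_risk(c(0.049, 0.05, 0.5), threshold = 0.05)
#' @export
classify_risk <- function(p_ep, threshold = 0.05) {
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).",
          class = "pulvalidate_argument_error")
  }
  p_ep >= threshold
}

#' Most probable outcome label from a probability triple
#'
#' Ties are broken by the fixed order `failed_pul` < `iup` < `ep`, so a
#' uniform triple maps to `failed_pul`; this keeps results deterministic.
#'
#' @param p_failed,p_iup,p_ep Probability vectors (rowwise triples).
#' @return Character vector of outcome labels.
#' @export
predicted_outcome <- function(p_failed, p_iup, p_ep) {
  p <- cbind(p_failed, p_iup, p_ep)
  c("failed_pul", "iup", "ep")[max.col(p, ties.method = "first")]
}
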