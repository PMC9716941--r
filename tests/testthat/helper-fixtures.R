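# Shared fixtures: small models and cohort builders, all constructed in code.

toy_model <- function(name = "toy") {
  model_spec(name,
             iup = c(intercept = -4.0, log_hcg1 = 0.4, log_ratio = 4.0,
                     log_ratio_sq = -0.8),
             ep = c(intercept = 1.0, log_hcg1 = -0.35, log_ratio = 0.3,
                    log_ratio_sq = -1.2))
}

# Same basis structure with every coefficient scaled: sharper (factor > 1)
# or flatter (factor < 1) logits than the original.
scaled_model <- function(model, factor, name = paste0(model$name, "_scaled")) {
  model_spec(name,
             iup = lapply(model$logits$iup, `*`, factor),
             ep = lapply(model$logits$ep, `*`, factor))
}

intercept_only_model <- function(eta_iup, eta_ep, name = "intercepts") {
  model_spec(name, iup = c(intercept = eta_iup), ep = c(intercept = eta_ep))
}

# Minimal valid cohort; vectors recycle to the longest length.
make_cohort <- function(hcg1 = 500, hcg2 = 500, interval_hours = 48,
                        outcome = "failed_pul", pul_type = "true_pul",
                        n = max(length(hcg1), length(hcg2),
                                length(interval_hours), length(outcome))) {
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    age = 30,
    hcg1 = rep_len(hcg1, n),
    hcg2 = rep_len(hcg2, n),
    interval_hours = rep_len(interval_hours, n),
    bleeding = FALSE, prior_ep = FALSE, iud = FALSE, inpatient = FALSE,
    pul_type = rep_len(pul_type, n),
    outcome = rep_len(outcome, n)
  )
}

# O(n^2) brute-force AUC: the independent oracle for the rank-based path.
auc_brute_force <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# drop generator/filter attributes before comparing cohort contents
strip_attrs <- function(x) {
  attr(x, "exclusion_log") <- NULL
  attr(x, "ground_truth") <- NULL
  tibble::as_tibble(x)
}
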