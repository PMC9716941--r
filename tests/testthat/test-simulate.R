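test_that("generator parameters hit the documented quartile targets", {
  p <- sim_params()
  expect_equal(sum(p$prevalences), 1)
  expect_equal(sum(p$interval_mix), 1)
  expect_equal(p$prevalences[["ep"]], 238 / 1061)
  # log-sd is matched to the printed interquartile spread: the distribution
  # puts ~25% below 210 IU/L and ~75% below 2312 IU/L, with median 703 exact
  expect_equal(qlnorm(0.5, p$hcg1_log_median, p$hcg1_log_sd), 703)
  expect_equal(plnorm(210, p$hcg1_log_median, p$hcg1_log_sd), 0.25,
               tolerance = 0.01)
  expect_equal(plnorm(2312, p$hcg1_log_median, p$hcg1_log_sd), 0.75,
               tolerance = 0.01)
  expect_error(sim_params(nonsense = 1), class = "pulvalidate_argument_error")
})

test_that("cohort generation is a pure function of the seed", {
  a <- simulate_pul_cohort(300, seed = 9)
  b <- simulate_pul_cohort(300, seed = 9)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_pul_cohort(a, pa)
  write_pul_cohort(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_false(identical(simulate_pul_cohort(300, seed = 10)$hcg1, a$hcg1))
})

test_that("descriptive-mode marginals converge to their targets", {
  co <- simulate_pul_cohort(100000, seed = 12)
  expect_lt(abs(median(co$hcg1) - 703) / 703, 0.05)
  ratio <- co$hcg2 / co$hcg1
  expect_lt(abs(median(ratio) - 0.94), 0.05)
  expect_true(all(ratio >= 0.06 * (1 - 1e-9) & ratio <= 5.65 * (1 + 1e-9)))
  ep_frac <- mean(co$outcome %in% c("ep", "ppul"))
  expect_lt(abs(ep_frac - 238 / 1061), 0.01)
  mix <- table(interval_bin(co$interval_hours)) / nrow(co)
  expect_equal(unname(mix[c("24-39", "40-56", "57-72")]),
               c(0.13, 0.71, 0.16), tolerance = 0.05, ignore_attr = TRUE)
  # persisting PUL share of all EP
  expect_equal(sum(co$outcome == "ppul") / sum(co$outcome %in% c("ep", "ppul")),
               46 / 238, tolerance = 0.05)
})

test_that("model-consistent cohorts carry valid ground truth", {
  m <- toy_model()
  co <- simulate_from_model(m, 5000, seed = 13)
  gt <- ground_truth(co)
  expect_equal(gt$p_failed + gt$p_iup + gt$p_ep, rep(1, 5000),
               tolerance = 1e-12)
  # empirical EP rate within 3 SEs of the mean generating probability
  p_ep_bar <- mean(gt$p_ep)
  se <- sqrt(mean(gt$p_ep * (1 - gt$p_ep)) / 5000)
  expect_lt(abs(mean(co$outcome == "ep") - p_ep_bar), 3 * se + 1e-12)
  expect_error(ground_truth(make_cohort(n = 2)),
               class = "pulvalidate_argument_error")
})

test_that("scoring the generating model recovers perfect calibration", {
  m <- toy_model()
  co <- simulate_from_model(m, 20000, seed = 14)
  sc <- predict_pul(co, m)
  sc$ep <- dichotomize_outcome(sc$outcome)
  cal <- calibration_metrics(sc, "p_ep", "ep")
  expect_lt(abs(cal$slope$slope - 1), 0.05)
  expect_lt(abs(cal$citl$citl), 0.05)
  # AUC of the model's scores matches the ground-truth-probability AUC
  gt <- ground_truth(co)
  auc_model <- auc_mann_whitney(sc$p_ep[sc$ep], sc$p_ep[!sc$ep])
  auc_truth <- auc_mann_whitney(gt$p_ep[sc$ep], gt$p_ep[!sc$ep])
  expect_lt(abs(auc_model - auc_truth), 0.01)
})

test_that("validating a sharpened model degrades the slope detectably", {
  m <- toy_model()
  co <- simulate_from_model(m, 20000, seed = 15)
  co$ep <- dichotomize_outcome(co$outcome)
  sharp <- predict_pul(co, scaled_model(m, 1.6))
  slope_sharp <- calibration_slope(sharp$p_ep, sharp$ep)$slope
  expect_lt(slope_sharp, 0.9) # too-extreme predictions -> slope < 1
  flat <- predict_pul(co, scaled_model(m, 0.6))
  slope_flat <- calibration_slope(flat$p_ep, flat$ep)$slope
  expect_gt(slope_flat, 1.1) # too-moderate predictions -> slope > 1
})

test_that("contamination flags inject records the filter removes", {
  co <- simulate_pul_cohort(2000, sim_params(frac_gtd = 0.02,
                                             frac_lost = 0.02,
                                             frac_out_of_window = 0.1),
                            seed = 16)
  kept <- apply_inclusion(co)
  counts <- setNames(exclusion_log(kept)$counts$n,
                     exclusion_log(kept)$counts$disposition)
  expect_gt(counts[["excluded_interval"]], 0)
  expect_gt(counts[["excluded_gtd"]], 0)
  expect_gt(counts[["excluded_lost"]], 0)
  expect_true(all(kept$interval_hours >= 24 & kept$interval_hours <= 72))
})

test_that("persisting-PUL adjudication needs a 3-point plateau inside a week", {
  expect_true(adjudicate_ppul(c(1000, 1000, 1000), c(0, 3, 6)))
  expect_false(adjudicate_ppul(c(1000, 800, 640), c(0, 2, 4))) # 20% drops
  expect_true(adjudicate_ppul(c(1000, 900, 990, 940), c(0, 2, 4, 5)))
  expect_false(adjudicate_ppul(c(1000, 1000), c(0, 2))) # too few samples
  expect_false(adjudicate_ppul(c(1000, 1000, 1000), c(0, 5, 10))) # > 7 days
  # plateau triple embedded in a longer noisy series is still found
  expect_true(adjudicate_ppul(c(500, 900, 950, 980, 300), c(0, 1, 3, 5, 9)))
})
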