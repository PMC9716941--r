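test_that("confusion counts partition the cohort at a threshold", {
  cc <- confusion_at_threshold(c(0.9, 0.04, 0.5, 0.02), c(1, 1, 0, 0), 0.05)
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  all_high <- confusion_at_threshold(rep(1, 6), c(1, 1, 0, 0, 1, 0), 0.5)
  expect_equal(all_high$fn + all_high$tn, 0)
  all_low <- confusion_at_threshold(rep(0, 6), c(1, 1, 0, 0, 1, 0), 0.5)
  expect_equal(all_low$tp + all_low$fp, 0)
  expect_error(confusion_at_threshold(c(0.1, 0.2), 1, 0.5),
               class = "pulvalidate_argument_error")
})

test_that("accuracy measures reproduce their count definitions", {
  # 238 EP of which 12 classified low risk -> sensitivity ~ 95%
  m <- accuracy_measures(tp = 226, fp = 400, tn = 400, fn = 12)
  sens <- m$estimate[m$measure == "sensitivity"]
  expect_equal(sens, 226 / 238)
  expect_equal(round(100 * sens), 95)

  toy <- accuracy_measures(1, 1, 1, 1)
  expect_equal(toy$estimate, rep(0.5, 4))

  perfect_npv <- accuracy_measures(tp = 5, fp = 2, tn = 10, fn = 0)
  expect_equal(perfect_npv$estimate[perfect_npv$measure == "npv"], 1)

  # zero denominator -> undefined marker, never 0
  und <- accuracy_measures(tp = 0, fp = 3, tn = 2, fn = 0)
  expect_true(is.na(und$estimate[und$measure == "sensitivity"]))
  expect_false(und$defined[und$measure == "sensitivity"])
})

test_that("Wilson intervals contain the estimate and stay inside [0, 1]", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_true(ci$conf.low >= 0 && ci$conf.high <= 1)
    expect_true(ci$conf.low <= ci$estimate && ci$estimate <= ci$conf.high)
  }
})

test_that("sensitivity falls and percent-low-risk rises with the threshold", {
  set.seed(52)
  p <- runif(400)
  y <- rbinom(400, 1, p)
  grid <- seq(0.005, 0.995, length.out = 100)
  tab <- accuracy_table(tibble::tibble(p = p, y = y), p, y, thresholds = grid)
  sens <- tab$estimate[tab$measure == "sensitivity"]
  low <- tab$estimate[tab$measure == "pct_low_risk"]
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(low) >= -1e-12))
})

test_that("percent low risk obeys the prevalence identity exactly", {
  set.seed(53)
  p <- runif(300)
  y <- rbinom(300, 1, 0.25)
  for (thr in c(0.025, 0.05, 0.1, 0.5)) {
    cc <- confusion_at_threshold(p, y, thr)
    m <- accuracy_measures(cc$tp, cc$fp, cc$tn, cc$fn)
    est <- setNames(m$estimate, m$measure)
    prev <- mean(y)
    expect_equal(est[["pct_low_risk"]],
                 1 - (prev * est[["sensitivity"]] +
                        (1 - prev) * est[["fpr"]]))
  }
})

test_that("a dominating score is at least as sensitive at every threshold", {
  set.seed(54)
  p_b <- runif(500, 0, 0.8)
  p_a <- pmin(1, p_b + 0.1) # dominates everywhere
  y <- rbinom(500, 1, p_b)
  for (thr in seq(0.05, 0.9, by = 0.05)) {
    ca <- confusion_at_threshold(p_a, y, thr)
    cb <- confusion_at_threshold(p_b, y, thr)
    expect_gte(ca$tp, cb$tp) # sensitivity_A >= sensitivity_B
    expect_gte(ca$fp, cb$fp) # fpr_A >= fpr_B
  }
})

test_that("McNemar uses the exact binomial tail for few discordant pairs", {
  same <- mcnemar_paired(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$b + same$c, 0)
  expect_equal(same$p_value, 1)

  # b = 8, c = 2: exact two-sided p = 2 * P(Bin(10, 1/2) <= 2)
  ha <- rep(c(TRUE, FALSE, TRUE), c(8, 2, 5))
  hb <- rep(c(FALSE, TRUE, TRUE), c(8, 2, 5))
  res <- mcnemar_paired(ha, hb)
  expect_equal(res$b, 8)
  expect_equal(res$c, 2)
  expect_equal(res$p_value, 0.109375)
  expect_match(res$method, "exact")

  sym <- mcnemar_paired(rep(c(TRUE, FALSE), c(5, 5)),
                        rep(c(FALSE, TRUE), c(5, 5)))
  expect_equal(sym$p_value, 1) # capped at 1
})

test_that("McNemar switches to corrected chi-square at 25 discordant pairs", {
  ha <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 10, 30, 30))
  hb <- rep(c(FALSE, TRUE, TRUE, FALSE), c(20, 10, 30, 30))
  res <- mcnemar_paired(ha, hb)
  expect_equal(res$b + res$c, 30)
  expect_match(res$method, "chi-square")
  ref <- mcnemar.test(table(ha, hb), correct = TRUE)$p.value
  expect_equal(res$p_value, ref)
})

test_that("restricting McNemar to a class compares the right proportions", {
  y <- c(1, 1, 1, 0, 0, 0)
  ha <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  hb <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  pos <- mcnemar_paired(ha, hb, y, restrict = "positives")
  expect_equal(c(pos$b, pos$c), c(1, 1))
  neg <- mcnemar_paired(ha, hb, y, restrict = "negatives")
  expect_equal(c(neg$b, neg$c), c(1, 1))
  expect_error(mcnemar_paired(ha, hb, restrict = "positives"),
               class = "pulvalidate_argument_error")
})
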