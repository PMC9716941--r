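test_that("Mann-Whitney AUC equals the pairwise count on fixed examples", {
  expect_equal(auc_mann_whitney(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc_mann_whitney(rep(0.3, 5), rep(0.3, 7)), 0.5)
  expect_equal(auc_mann_whitney(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_error(auc_mann_whitney(numeric(0), 1),
               class = "pulvalidate_degenerate_input")
})

test_that("rank-based AUC matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:50) {
    n_pos <- sample(1:50, 1)
    n_neg <- sample(1:50, 1)
    # coarse rounding forces plenty of ties
    pos <- round(runif(n_pos), 1)
    neg <- round(runif(n_neg), 1)
    expect_equal(auc_mann_whitney(pos, neg), auc_brute_force(pos, neg))
  }
})

test_that("AUC symmetry and invariance under monotone transforms", {
  set.seed(32)
  pos <- runif(40); neg <- runif(30)
  expect_equal(auc_mann_whitney(pos, neg) + auc_mann_whitney(1 - pos, 1 - neg),
               1)
  a0 <- auc_mann_whitney(pos, neg)
  expect_equal(auc_mann_whitney(qlogis(pos), qlogis(neg)), a0)
  expect_equal(auc_mann_whitney(exp(3 * pos), exp(3 * neg)), a0)
})

test_that("DeLong variance matches the hand-built placement-component table", {
  # pos = (3, 2, 1), neg = (2.5, 0.5, 0):
  # V10 = (1, 2/3, 2/3), V01 = (1/3, 1, 1); AUC = 7/9
  # var(V10) = 1/27, var(V01) = 4/27 -> variance = (1/27 + 4/27)/3 = 5/81
  dl <- delong_variance(c(3, 2, 1), c(2.5, 0.5, 0))
  expect_equal(dl$auc, 7 / 9)
  expect_equal(dl$variance, 5 / 81)
  expect_false(dl$degenerate)
})

test_that("DeLong variance agrees with an independent implementation", {
  set.seed(33)
  s <- runif(120)
  y <- rbinom(120, 1, plogis(3 * s - 1.5))
  dl <- delong_variance(s[y == 1], s[y == 0])
  r <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  expect_equal(dl$auc, as.numeric(pROC::auc(r)))
  expect_equal(dl$variance, as.numeric(pROC::var(r, method = "delong")))
})

test_that("perfect separation gives zero variance with a degenerate flag", {
  expect_warning(dl <- delong_variance(c(3, 4, 5), c(0, 1, 2)),
                 "Degenerate")
  expect_equal(dl$variance, 0)
  expect_true(dl$degenerate)
})

test_that("variance scales roughly as 1/n when the cohort is duplicated", {
  set.seed(34)
  pos <- runif(30); neg <- runif(40)
  v1 <- delong_variance(pos, neg)$variance
  v2 <- delong_variance(rep(pos, 2), rep(neg, 2))$variance
  expect_equal(v2 / v1, 0.5, tolerance = 0.08)
})

test_that("Wald AUC interval is symmetric and truncated to [0, 1]", {
  expect_equal(auc_ci(0.8, 0), c(0.8, 0.8))
  expect_equal(auc_ci(0.5, 0.0025), c(0.402, 0.598), tolerance = 1e-3)
  expect_equal(auc_ci(0.99, 0.01)[2], 1.0)
})

test_that("paired DeLong test handles identical and anti-correlated models", {
  set.seed(35)
  d <- tibble::tibble(a = runif(40), y = rbinom(40, 1, 0.4))
  d$b <- d$a
  same <- delong_test(d, a, b, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # separable instance: model a perfect, model b = 1 - a its anti-classifier
  d2 <- tibble::tibble(a = c(0.9, 0.8, 0.2, 0.1), y = c(1, 1, 0, 0),
                       b = 1 - c(0.9, 0.8, 0.2, 0.1))
  expect_equal(auc_mann_whitney(d2$a[d2$y == 1], d2$a[d2$y == 0]), 1)
  expect_equal(auc_mann_whitney(d2$b[d2$y == 1], d2$b[d2$y == 0]), 0)
  # the AUC difference is degenerate (variance 0 without equality)
  expect_error(delong_test(d2, a, b, y),
               class = "pulvalidate_degenerate_input")
})

test_that("paired DeLong z agrees in sign and size with a permutation oracle", {
  set.seed(36)
  d <- tibble::tibble(
    a = c(0.9, 0.7, 0.65, 0.3, 0.6, 0.2, 0.4, 0.1),
    b = c(0.8, 0.4, 0.9, 0.5, 0.3, 0.45, 0.7, 0.6),
    y = c(1, 1, 1, 1, 0, 0, 0, 0))
  res <- delong_test(d, a, b, y)
  auc_of <- function(s) auc_mann_whitney(s[d$y == 1], s[d$y == 0])
  obs <- auc_of(d$a) - auc_of(d$b)
  expect_equal(res$difference, obs)
  # exhaustive sign-flip (swap a/b within records) null distribution
  diffs <- vapply(0:(2^8 - 1), function(mask) {
    swap <- as.logical(bitwAnd(mask, 2^(0:7)))
    sa <- ifelse(swap, d$b, d$a)
    sb <- ifelse(swap, d$a, d$b)
    auc_of(sa) - auc_of(sb)
  }, numeric(1))
  p_perm <- mean(abs(diffs) >= abs(obs) - 1e-12)
  expect_equal(sign(res$z), sign(obs))
  expect_lt(abs(res$p_value - p_perm), 0.35)
})

test_that("roc_auc wraps the DeLong machinery for data frames", {
  set.seed(37)
  d <- tibble::tibble(p = runif(200))
  d$y <- rbinom(200, 1, plogis(4 * d$p - 2))
  res <- roc_auc(d, p, y)
  expect_equal(res$auc, auc_mann_whitney(d$p[d$y == 1], d$p[d$y == 0]))
  td <- tidy(res)
  expect_true(td$conf.low <= td$auc && td$auc <= td$conf.high)
  pts <- roc_points(d, p, y)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
})
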