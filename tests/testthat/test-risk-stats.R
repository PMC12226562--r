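test_that("Pearson chi-square reproduces the reference value and a cell-loop oracle", {
  res <- pearson_chi2(new_two_by_two(51, 72, 14, 343))
  expect_equal(round(res$statistic, 3), 110.125)
  expect_equal(res$df, 1)

  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)

  # independent oracle: explicit expected-count loop over cells
  chi_oracle <- function(m) {
    n <- sum(m); tot <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      tot <- tot + (m[i, j] - e)^2 / e
    }
    tot
  }
  m <- matrix(c(20, 5, 10, 15), 2)
  expect_equal(pearson_chi2(m)$statistic, chi_oracle(m), tolerance = 1e-12)

  set.seed(3)
  for (i in 1:50) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(stats::rpois(r * c, 15) + 1, r, c)
    got <- pearson_chi2(m)
    expect_equal(got$statistic, chi_oracle(m), tolerance = 1e-10)
    expect_equal(got$df, (r - 1) * (c - 1))
    # cross-check against the uncorrected base-R test
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
    # invariance under transposition and permutations
    expect_equal(pearson_chi2(t(m))$statistic, got$statistic, tolerance = 1e-10)
    expect_equal(pearson_chi2(m[sample(r), sample(c)])$statistic,
                 got$statistic, tolerance = 1e-10)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "adetrigger_degenerate_table_error")
})

test_that("Mann-Whitney U matches the pairwise-count oracle with midrank ties", {
  # U is oriented to x: pairs with x > y plus half the ties
  u_oracle <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) {
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    }
    u
  }
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$U, 9)

  x <- c(2, 2, 5, 7)
  expect_equal(mann_whitney_u(x, x)$U, length(x)^2 / 2)

  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:10, 20, replace = TRUE)  # heavy ties
    y <- sample(3:12, 20, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$U, u_oracle(x, y))
    # z and p agree with the tie-corrected, uncorrected-continuity base test
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                               exact = FALSE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  flat <- mann_whitney_u(rep(4, 5), rep(4, 7))
  expect_true(flat$undefined)
  expect_true(is.na(flat$z))
})

test_that("intercept-only logistic fit equals the closed-form log-odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(matrix(nrow = 100, ncol = 0), y)
  expect_equal(unname(fit$coefficients), log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("logistic regression recovers known coefficients from its own model", {
  set.seed(2024)
  n <- 5000
  x <- stats::rnorm(n)
  eta <- -2.0 + 0.8 * x
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  fit <- fit_logistic(data.frame(x = x), y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["x"]] - 0.8), 0.1)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - (-2.0)), 0.1)

  # bias shrinks with n (fixed seeds)
  set.seed(99)
  n2 <- 500
  x2 <- stats::rnorm(n2)
  y2 <- stats::rbinom(n2, 1, stats::plogis(-1 + 0.6 * x2))
  f_small <- fit_logistic(data.frame(x = x2), y2)
  set.seed(99)
  n3 <- 5000
  x3 <- stats::rnorm(n3)
  y3 <- stats::rbinom(n3, 1, stats::plogis(-1 + 0.6 * x3))
  f_big <- fit_logistic(data.frame(x = x3), y3)
  expect_lt(abs(f_big$coefficients[["x"]] - 0.6),
            abs(f_small$coefficients[["x"]] - 0.6) + 0.05)
})

test_that("logistic fit agrees with glm and reports Wald odds-ratio intervals", {
  set.seed(31)
  n <- 300
  x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.4)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.7 * x1 - 0.4 * x2))
  fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  ref <- stats::glm(y ~ x1 + x2, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$odds_ratio, exp(fit$coefficients))
  expect_true(all(fit$ci_low < fit$odds_ratio & fit$odds_ratio < fit$ci_high))
  expect_equal(unname(fit$ci_low), unname(exp(fit$coefficients - 1.96 * fit$se)))
})

test_that("separation, rank deficiency and one-class outcomes are errors", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2, -1.2, 1.2, -1.8, 1.9, -0.9, 0.8)
  y <- as.integer(x > 0)
  expect_error(fit_logistic(data.frame(x = x), y), "separation",
               class = "adetrigger_separation_error")
  set.seed(8)
  z <- stats::rnorm(30)
  yy <- stats::rbinom(30, 1, 0.5)
  expect_error(fit_logistic(data.frame(a = z, b = 2 * z), yy),
               class = "adetrigger_rank_error")
  expect_error(fit_logistic(data.frame(x = z), rep(1, 30)),
               class = "adetrigger_validation_error")
})

test_that("AUC equals the pairwise concordance probability with half-weight ties", {
  auc_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(0, 1), 5))$auc, 0.5)

  scores <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  labels <- c(0, 0, 1, 0, 1, 1, 0, 1, 0, 1)
  got <- roc_auc(scores, labels)
  expect_equal(got$auc, auc_oracle(scores, labels))

  set.seed(17)
  for (i in 1:20) {
    s <- sample(1:8, 30, replace = TRUE)
    l <- stats::rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    r <- roc_auc(s, l)
    expect_equal(r$auc, auc_oracle(s, l))
    # complement symmetry
    expect_equal(roc_auc(-s, l)$auc + r$auc, 1)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), class = "adetrigger_validation_error")
})

test_that("AUC and its Hanley-McNeil interval agree with pROC on a reference sample", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- stats::rnorm(200) + rep(c(0, 1.2), each = 100)
  l <- rep(c(0, 1), each = 100)
  got <- roc_auc(s, l)
  ref <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("the model AUC on a simulated cohort lies in a wide sanity band", {
  sim <- simulate_cohort(sim_config(n_patients = 2000), seed = 202)
  scr <- screen_cohort(sim$cohort)
  adj <- build_ade_records(sim$cohort, scr, sim$adjudication)
  df <- risk_factor_data(sim$cohort, scr, adj)
  fit <- fit_logistic(df[, c("age_stratum", "trigger_positive")], df$ade)
  roc <- roc_auc(fit$fitted, df$ade)
  expect_gt(roc$auc, 0.75)
  expect_lt(roc$auc, 0.98)
})

test_that("risk-factor data codes strata as documented", {
  cb <- calib()
  df <- risk_factor_data(cb$cohort, cb$screen, cb$adjudicated)
  expect_equal(nrow(df), 480)
  expect_equal(sum(df$ade), 65)
  expect_equal(unname(table(df$age_stratum)), c(303L, 147L, 30L),
               ignore_attr = TRUE)
  expect_equal(sum(df$trigger_positive), 123)
  # LOS of exactly 13 days belongs to the lower stratum
  los <- length_of_stay(cb$cohort)
  expect_true(all(df$los_stratum[los == 13] == 1))
  expect_true(all(df$los_stratum[los > 13] == 2))
  # trigger-positivity stratum chi-square equals the headline statistic
  tab <- table(df$trigger_positive, df$ade)
  expect_equal(round(pearson_chi2(tab)$statistic, 3), 110.125)
})
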