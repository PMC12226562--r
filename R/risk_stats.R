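#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O-E)^2/E)` on an r x c table of
#' counts, with `df = (r-1)(c-1)`. No continuity correction is applied
#' (for a 2x2 table the statistic equals
#' `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`).
#'
#' @param table matrix of non-negative counts (or a `two_by_two`).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  if (inherits(table, "two_by_two")) table <- as.matrix(table)
  m <- as.matrix(table)
  stopifnot(is.numeric(m), all(m >= 0), nrow(m) >= 2, ncol(m) >= 2)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    abort_adetrigger("degenerate contingency table: zero row or column margin",
                     "adetrigger_degenerate_table_error")
  }
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties, oriented to the first
#' sample: `U = R_x - n_x(n_x+1)/2`, the number of (x, y) pairs with
#' `x > y` plus half the tied pairs. The normal approximation uses the
#' tie-corrected variance
#' `m n / 12 * ((N+1) - sum(t^3 - t) / (N (N-1)))`; no continuity
#' correction is applied.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U`, `z`, `p_value` and `undefined` (TRUE when all
#'   values are identical so the variance is zero).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    return(list(U = U, z = NA_real_, p_value = NA_real_, undefined = TRUE))
  }
  z <- (U - m * n / 2) / sqrt(v)
  list(U = U, z = z, p_value = 2 * stats::pnorm(-abs(z)), undefined = FALSE)
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `logit P(y=1) = X beta` with an intercept
#' prepended. Convergence is declared when the maximum absolute score
#' (gradient) falls below `1e-8` or the relative log-likelihood change
#' below `1e-10`, capped at 100 iterations. Odds ratios are `exp(beta)`
#' with Wald 95% intervals `exp(beta +/- 1.96 se)` and Wald p-values.
#' Rank-deficient designs and complete separation (diverging coefficients
#' with fitted probabilities at the boundary) are errors.
#'
#' @param design data frame or matrix of predictors (no intercept column).
#' @param outcome binary 0/1 vector with both classes present.
#' @param max_iter iteration cap.
#' @return An object of class `logistic_fit` with `coefficients`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `z`, `p_value`, `converged`,
#'   `iterations`, `log_lik`.
#' @export
fit_logistic <- function(design, outcome, max_iter = 100) {
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  y <- as.numeric(outcome)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    abort_adetrigger("outcome must contain both classes",
                     "adetrigger_validation_error")
  }
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  if (nrow(X) <= p) {
    abort_adetrigger("more parameters than observations",
                     "adetrigger_validation_error")
  }
  if (qr(X)$rank < p) {
    abort_adetrigger("rank-deficient design matrix",
                     "adetrigger_rank_error")
  }

  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (max(abs(score)) < 1e-8 ||
        (is.finite(ll_old) && abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    ll_old <- ll
    if (iter >= max_iter) break
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  boundary <- mu[y == 1] > 1 - 1e-8 | mu[y == 1] < 1e-8
  if (max(abs(beta)) > 15 &&
      (all(mu[y == 1] > 1 - 1e-6) || all(mu[y == 0] < 1e-6) ||
       mean(abs(mu - y) < 1e-6) > 0.99)) {
    offender <- colnames(X)[which.max(abs(beta))]
    abort_adetrigger(
      sprintf("complete or quasi-complete separation detected (predictor: %s)",
              offender),
      "adetrigger_separation_error")
  }
  if (!converged) {
    abort_adetrigger(sprintf("IRLS did not converge in %d iterations", max_iter),
                     "adetrigger_convergence_error")
  }

  w <- pmax(mu * (1 - mu), 1e-12)
  cov_beta <- solve(crossprod(X * w, X))
  se <- sqrt(diag(cov_beta))
  z <- beta / se
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    odds_ratio = setNames(exp(beta), colnames(X)),
    ci_low = setNames(exp(beta - 1.96 * se), colnames(X)),
    ci_high = setNames(exp(beta + 1.96 * se), colnames(X)),
    z = setNames(z, colnames(X)),
    p_value = setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    converged = converged, iterations = iter,
    log_lik = sum(y * eta - log1p(exp(eta))),
    fitted = mu),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Binary logistic regression (IRLS, %d iterations, %s)\n",
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  df <- data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratio,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value)
  print(round(df, 4))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' ROC curve and AUC
#'
#' The area under the ROC curve computed as the Mann-Whitney concordance
#' probability: the proportion of (positive, negative) score pairs in which
#' the positive scores higher, ties counted one half. The 95% confidence
#' interval uses the Hanley-McNeil standard error. The threshold sweep
#' enumerates every distinct score as a cut-point (predict positive when
#' `score >= threshold`).
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 outcome with both classes present.
#' @return An object of class `roc_result` with `auc`, `ci_low`, `ci_high`,
#'   `se`, and a `points` data frame (threshold, sensitivity, one minus
#'   specificity).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) {
    abort_adetrigger("both outcome classes are required for a ROC curve",
                     "adetrigger_validation_error")
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
              (n - 1) * (q2 - auc^2)) / (m * n))

  thr <- sort(unique(scores), decreasing = TRUE)
  points <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), 1)),
    fpr = c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), 1)))
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - 1.96 * se),
                 ci_high = min(1, auc + 1.96 * se),
                 points = points),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f, Hanley-McNeil)\n",
              x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' Risk-factor analysis table for ADE occurrence
#'
#' Builds the per-patient analysis dataset used in risk-factor modelling:
#' the binary ADE outcome, the ordinal age stratum (65-75, 76-85, >=86
#' coded 1, 2, 3), length-of-stay stratum (2-13 vs 14-24 days, 13 assigned
#' to the lower stratum), medication-count stratum (5-15, 16-26, >=27),
#' the binary trigger-positivity indicator and the positive-trigger count.
#'
#' @param cohort a `gtt_cohort`.
#' @param screen a `screen_result`.
#' @param adjudicated an `adjudicated_cohort`.
#' @return data frame, one row per patient.
#' @export
risk_factor_data <- function(cohort, screen, adjudicated) {
  pts <- cohort$patients
  ade <- adjudicated$per_patient$n_ades[
    match(pts$patient_id, adjudicated$per_patient$patient_id)] > 0
  n_hits <- vapply(pts$patient_id,
                   function(id) sum(screen$hits$patient_id == id), 1L)
  data.frame(
    patient_id = pts$patient_id,
    ade = as.integer(ade),
    age_stratum = ifelse(pts$age >= 86, 3L, ifelse(pts$age >= 76, 2L, 1L)),
    los_stratum = ifelse(length_of_stay(cohort) <= 13, 1L, 2L),
    meds_stratum = ifelse(pts$n_medications >= 27, 3L,
                          ifelse(pts$n_medications >= 16, 2L, 1L)),
    trigger_positive = as.integer(screen$patient_positive[pts$patient_id]),
    n_positive_triggers = n_hits,
    stringsAsFactors = FALSE)
}
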