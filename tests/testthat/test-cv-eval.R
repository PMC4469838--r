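test_that("folds are event-stratified and seeded", {
  ev <- rep(c(1, 0), c(30, 20))
  f1 <- make_folds(ev, K = 5, seed = 3)
  f2 <- make_folds(ev, K = 5, seed = 3)
  expect_identical(f1, f2)
  tab <- table(f1, ev)
  expect_true(all(tab[, "1"] == 6))
  expect_true(all(tab[, "0"] == 4))
})

test_that("all-zero fits reduce the CV score to risk-set arithmetic", {
  d <- tiny_data(30, 3, seed = 61, beta = c(0.8, 0, 0), censor = 0.2)
  folds <- make_folds(d$events, K = 3, seed = 2)
  # a penalty above every training lambda0 forces beta = 0 in every fold
  lam_max <- max(vapply(1:3, function(kf)
    compute_lambda0(subset_patients(d, folds != kf)), numeric(1)))
  got <- cv_score(1.01 * lam_max, d, folds = folds)
  want <- 0
  for (kf in 1:3) {
    keep <- folds != kf
    want <- want +
      loglik_enum(rep(0, 3), d$expression, d$times, d$events) -
      loglik_enum(rep(0, 3), d$expression[keep, , drop = FALSE],
                  d$times[keep], d$events[keep])
  }
  expect_equal(got, want)
})

test_that("the CV score matches an independent re-evaluation oracle", {
  d <- tiny_data(30, 3, seed = 62, beta = c(1, -0.6, 0))
  folds <- make_folds(d$events, K = 3, seed = 9)
  lam <- 0.4 * compute_lambda0(d)
  got <- cv_score(lam, d, folds = folds)
  want <- 0
  for (kf in 1:3) {
    keep <- folds != kf
    Xtr <- d$expression[keep, , drop = FALSE]
    btr <- lasso_oracle(lam, Xtr, d$times[keep], d$events[keep])
    want <- want + loglik_enum(btr, d$expression, d$times, d$events) -
      loglik_enum(btr, Xtr, d$times[keep], d$events[keep])
  }
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("the CV score is invariant to patient order", {
  d <- tiny_data(24, 3, seed = 63, beta = c(1, 0, 0))
  folds <- make_folds(d$events, K = 3, seed = 4)
  lam <- 0.5 * compute_lambda0(d)
  v1 <- cv_score(lam, d, folds = folds)
  set.seed(10)
  perm <- sample(24)
  d2 <- survival_dataset(d$expression[perm, ], d$times[perm],
                         d$events[perm])
  v2 <- cv_score(lam, d2, folds = folds[perm])
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("degenerate folds are rejected", {
  d <- tiny_data(12, 2, seed = 64, beta = c(1, 0))
  folds <- rep(1:3, each = 4)
  d$events[folds == 2] <- 0
  d2 <- survival_dataset(d$expression, d$times, d$events)
  expect_error(cv_score(1, d2, folds = folds), "degenerate fold")
})

test_that("CV penalty selection walks the path and honours the tie rule", {
  d <- tiny_data(40, 5, seed = 65, beta = c(1.2, -1, 0, 0, 0))
  path <- compute_path(d, min_ratio = 0.1)
  sel <- select_lambda_by_cv(d, path, K = 4, fold_seed = 8)
  expect_true(sel$lambda %in% sel$cv$lambda)
  expect_equal(sel$cv$cv[match(sel$lambda, sel$cv$lambda)], max(sel$cv$cv))
  # ties towards larger lambda: the first index attaining the max
  expect_equal(match(sel$lambda, sel$cv$lambda),
               which.max(sel$cv$cv))
})

test_that("the prognostic index is the linear risk score, median-split", {
  d <- tiny_data(21, 3, seed = 66, beta = c(1, 0, 0))
  beta <- c(0.5, -0.25, 0)
  pi <- prognostic_index(beta, d)
  expect_equal(unname(pi$eta), unname(drop(d$expression %*% beta)))
  expect_equal(unname(pi$median), median(pi$eta))
  expect_true(all(pi$eta[pi$group == "better"] <= pi$median))
  expect_true(all(pi$eta[pi$group == "worse"] > pi$median))
  # patients exactly at the median go to the better group
  expect_gte(sum(pi$group == "better"), sum(pi$group == "worse"))
})

test_that("log-rank p-value matches a hand-computed O-E statistic", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  groups <- rep(c("A", "B"), 5)
  # hand computation: at each event time, O - E and hypergeometric variance
  O1 <- E1 <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & groups == "A")
    dth <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == "A")
    O1 <- O1 + d1
    E1 <- E1 + dth * n1 / n
    if (n > 1) V <- V + dth * (n1 / n) * (1 - n1 / n) * (n - dth) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  p <- logrank_test(times, events, groups)
  expect_equal(attr(p, "statistic"), chisq, tolerance = 1e-10)
  expect_equal(as.numeric(p), pchisq(chisq, 1, lower.tail = FALSE))
  expect_error(logrank_test(times, events, rep("A", 10)), "two nonempty")
})

test_that("prognostic-index Cox p-value agrees with coxph", {
  d <- tiny_data(60, 2, seed = 67, beta = c(1, 0))
  eta <- drop(d$expression %*% c(0.8, 0))
  p <- pi_cox_pvalue(eta, d)
  cf <- survival::coxph(survival::Surv(d$times, d$events) ~ eta,
                        ties = "breslow")
  expect_equal(attr(p, "alpha"), unname(coef(cf)), tolerance = 1e-4)
  expect_equal(as.numeric(p),
               summary(cf)$coefficients[1, "Pr(>|z|)"], tolerance = 1e-3)
  expect_gt(attr(p, "alpha"), 0)   # matches the planted direction
  expect_lt(as.numeric(p), 0.01)   # strong signal is detected
  expect_error(pi_cox_pvalue(rep(1, 60), d), "constant")
})

test_that("validation deviance is zero at the null and compositional", {
  d <- tiny_data(25, 3, seed = 68, beta = c(1, -1, 0))
  expect_identical(validation_deviance(rep(0, 3), d), 0)
  b <- c(0.7, -0.4, 0.1)
  want <- -2 * (loglik_enum(b, d$expression, d$times, d$events) -
                loglik_enum(rep(0, 3), d$expression, d$times, d$events))
  expect_equal(validation_deviance(b, d), want)
  # a coefficient vector fitted on this data improves its likelihood
  expect_lt(validation_deviance(fit_lasso_at(1, d), d), 0)
})

test_that("ranked subsets beat random subsets when signal is planted", {
  d <- tiny_data(60, 12, seed = 69,
                 beta = c(rep(1.4, 3), rep(0, 9)))
  beta <- fit_lasso_at(0.25 * compute_lambda0(d), d)
  m <- length(active_set(beta))
  expect_gte(m, 5)
  # subset_size = m: every random subset is the whole active set
  full <- rank_vs_random_aic(beta, d, subset_size = m, n_random = 20,
                             seed = 1)
  expect_equal(full$fraction, 0)
  expect_true(all(abs(full$aic_random - full$aic_ranked) < 1e-4))
  sel <- rank_vs_random_aic(beta, d, subset_size = 3, n_random = 60,
                            seed = 2)
  expect_lt(sel$fraction, 0.5)
  expect_error(rank_vs_random_aic(beta, d, subset_size = m + 1),
               "exceeds")
})

test_that("the evaluation report bundles the three criteria", {
  set.seed(70)
  d <- tiny_data(80, 4, seed = 70, beta = c(1.5, -1, 0, 0))
  train <- subset_patients(d, 1:50)
  valid <- subset_patients(d, 51:80)
  beta <- fit_lasso_at(0.2 * compute_lambda0(train), train)
  rep <- evaluate_model(beta, valid)
  expect_true(rep$logrank_p >= 0 && rep$logrank_p <= 1)
  expect_true(rep$pi_cox_p >= 0 && rep$pi_cox_p <= 1)
  expect_equal(rep$deviance,
               validation_deviance(beta, valid))
  expect_equal(sum(unlist(rep$group_sizes)), 30)
  expect_true(all(c("group", "time", "n_risk", "survival") %in%
                  names(rep$km)))
})
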