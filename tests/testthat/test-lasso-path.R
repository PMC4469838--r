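make_path_data <- function(seed = 21, n = 40, p = 4) {
  tiny_data(n, p, seed = seed, beta = c(1, -0.8, rep(0, p - 2)))
}

test_that("penalties at or above lambda0 give the all-zero fit", {
  d <- make_path_data()
  lam0 <- compute_lambda0(d)
  expect_equal(unname(fit_lasso_at(1.0001 * lam0, d)), rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(unname(fit_lasso_at(2 * lam0, d)), rep(0, 4),
               ignore_attr = TRUE)
  b <- fit_lasso_at(0.9999 * lam0, d)
  expect_gte(sum(b != 0), 1)
})

test_that("the first gene to enter attains the lambda0 maximum", {
  d <- make_path_data()
  lam0 <- compute_lambda0(d)
  jmax <- which.max(abs(cox_gradient(rep(0, 4), d)))
  b <- fit_lasso_at(0.98 * lam0, d)
  expect_equal(active_set(b), jmax)
})

test_that("single-penalty fits match the derivative-free oracle", {
  d <- make_path_data()
  lam0 <- compute_lambda0(d)
  for (frac in c(0.7, 0.4, 0.15)) {
    lam <- frac * lam0
    mine <- fit_lasso_at(lam, d)
    orc <- lasso_oracle(lam, d$expression, d$times, d$events,
                        start = as.numeric(mine) + 0.05)
    expect_lt(max(abs(as.numeric(mine) - orc)), 1e-4)
  }
})

test_that("fits are warm-start independent", {
  d <- make_path_data(seed = 31)
  lam <- 0.3 * compute_lambda0(d)
  cold <- fit_lasso_at(lam, d)
  set.seed(1)
  warm <- fit_lasso_at(lam, d, beta_init = rnorm(4))
  expect_equal(as.numeric(cold), as.numeric(warm), tolerance = 1e-6)
})

test_that("every path step satisfies the KKT certificate", {
  for (s in 1:3) {
    d <- tiny_data(35, 6, seed = 40 + s, beta = c(1.2, -1, 0.6, 0, 0, 0))
    path <- compute_path(d, min_ratio = 0.05)
    kkt_tol <- path$diagnostics$kkt_tol
    for (i in seq_len(nrow(path$steps))) {
      beta <- path$beta[, i]
      lam <- path$steps$lambda[i]
      g <- cox_gradient(beta, d)
      nz <- abs(beta) > path$zero_tol
      if (any(!nz)) expect_lte(max(abs(g[!nz])) - lam, kkt_tol)
      if (any(nz))
        expect_lte(max(abs(g[nz] - lam * sign(beta[nz]))), kkt_tol)
    }
  }
})

test_that("consecutive steps change the active set by exactly one gene", {
  d <- tiny_data(50, 8, seed = 77, beta = c(1.5, -1.2, 0.8, rep(0, 5)))
  path <- compute_path(d, min_ratio = 0.05)
  st <- path$steps
  expect_identical(st$m[1], 0L)
  expect_true(all(diff(st$lambda) <= 0))
  for (i in 2:nrow(st)) {
    prev <- active_set(path$beta[, i - 1], path$zero_tol)
    cur <- active_set(path$beta[, i], path$zero_tol)
    expect_equal(abs(st$m[i] - st$m[i - 1]), 1)
    changed <- union(setdiff(cur, prev), setdiff(prev, cur))
    expect_equal(changed, st$change_gene[i])
    expect_equal(st$change_dir[i], if (st$m[i] > st$m[i - 1]) 1 else -1)
  }
})

test_that("L1 norm shrinks monotonically as the penalty grows", {
  d <- make_path_data(seed = 55)
  path <- compute_path(d, min_ratio = 0.05)
  l1 <- colSums(abs(path$beta))
  expect_true(all(diff(l1) >= -1e-8))   # lambda decreases along columns
})

test_that("the active-set sequence matches a dense-grid oracle", {
  d <- make_path_data(seed = 60, n = 40, p = 4)
  path <- compute_path(d, min_ratio = 0.1)
  st <- path$steps
  # oracle: refit at the midpoint of each inter-change interval and read
  # off which coefficients are materially nonzero
  start <- rep(0, 4)
  for (i in 2:nrow(st)) {
    lam_mid <- if (i < nrow(st)) (st$lambda[i] + st$lambda[i + 1]) / 2
               else st$lambda[i] * 0.98
    orc <- lasso_oracle(lam_mid, d$expression, d$times, d$events,
                        start = start)
    start <- orc
    expect_equal(which(abs(orc) > 1e-4),
                 unname(active_set(path$beta[, i], path$zero_tol)))
  }
})

test_that("an all-zero design is rejected as degenerate", {
  d <- survival_dataset(matrix(0, 10, 3), rexp(10) + 0.1, rep(1, 10))
  expect_error(compute_path(d, min_ratio = 0.05), "degenerate design")
})

test_that("exactly one of lambda_min / min_ratio may be given", {
  d <- make_path_data()
  expect_error(compute_path(d, lambda_min = 1, min_ratio = 0.1),
               "exactly one")
  expect_error(compute_path(d, lambda_min = 2 * compute_lambda0(d)),
               "below lambda0")
})

test_that("coefficients agree with glmnet's penalized Cox fit", {
  skip_if_not_installed("glmnet")
  d <- tiny_data(45, 6, seed = 91, beta = c(1, -0.7, 0.5, 0, 0, 0),
                 censor = 0.2)
  lam0 <- compute_lambda0(d)
  for (frac in c(0.5, 0.2)) {
    lam <- frac * lam0
    mine <- fit_lasso_at(lam, d)
    # glmnet's coxnet minimizes -(1/n) l + lambda * penalty
    gf <- glmnet::glmnet(d$expression,
                         survival::Surv(d$times, d$events),
                         family = "cox", standardize = FALSE,
                         lambda = lam / d$n, thresh = 1e-12)
    expect_equal(as.numeric(mine), as.numeric(gf$beta), tolerance = 1e-4)
  }
})
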