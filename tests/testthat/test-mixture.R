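rlaplace <- function(n, scale) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

test_that("log-density has the right closed forms and symmetry", {
  # pure Laplace(0, 1): density 1/2 at the mode
  p1 <- mixture_params(pi0 = 1, pi = 0, tau = 1, mu = 1, sigma = 1)
  expect_equal(mixture_logpdf(0, p1), -log(2))
  # symmetric when the normal component has zero weight
  v <- c(0.1, 0.5, 2, 7)
  expect_equal(mixture_logpdf(v, p1), mixture_logpdf(-v, p1))
  # normal-only mixture reduces to dnorm
  p2 <- mixture_params(pi0 = 0, pi = 1, tau = 1, mu = 1.5, sigma = 0.3)
  expect_equal(mixture_logpdf(v, p2), dnorm(v, 1.5, 0.3, log = TRUE))
})

test_that("the mixture density integrates to one", {
  p <- mixture_params(pi0 = 0.6, pi = 0.4, tau = 4, mu = 1.2, sigma = 0.4)
  grid <- seq(-30, 30, by = 0.001)
  integral <- sum(exp(mixture_logpdf(grid, p))) * 0.001
  expect_equal(integral, 1, tolerance = 1e-3)
  # with the n/p prefactor the spike carries the remaining mass
  p2 <- mixture_params(pi0 = 0.6, pi = 0.4, tau = 4, mu = 1.2, sigma = 0.4,
                       n_over_p = 0.3)
  dens_away <- sum(exp(mixture_logpdf(grid[abs(grid) > 1e-3], p2))) * 0.001
  expect_equal(dens_away, 0.3, tolerance = 5e-3)
})

test_that("free fit recovers known mixture parameters", {
  set.seed(1234)
  x <- c(rlaplace(1000, 0.2), rnorm(1000, 1.5, 0.3))
  fit <- fit_mixture(x, C = 1)
  expect_true(fit$converged)
  expect_equal(fit$params$pi0, 0.5, tolerance = 0.05)
  expect_equal(1 / fit$params$tau, 0.2, tolerance = 0.05)
  expect_equal(fit$params$mu[1], 1.5, tolerance = 0.1)
  expect_equal(fit$params$sigma[1], 0.3, tolerance = 0.1)
})

test_that("identical coefficients are rejected as degenerate", {
  expect_error(fit_mixture(rep(0.4, 30), C = 1), "degenerate")
  expect_error(fit_mixture(rnorm(4), C = 1), "insufficient active set")
})

test_that("fixing all mass on the Laplace yields the closed-form scale MLE", {
  set.seed(8)
  x <- rlaplace(200, 0.5)
  fit <- fit_mixture(x, C = 1, fixed_props = c(1, 0))
  expect_equal(1 / fit$params$tau, mean(abs(x)), tolerance = 1e-6)
  expect_equal(fit$npar, 3L)  # 2C + 1 with fixed proportions
})

test_that("free proportions dominate any fixed-proportion fit", {
  set.seed(99)
  x <- c(rlaplace(150, 0.15), rnorm(100, 1.2, 0.25))
  free <- fit_mixture(x, C = 1)
  for (w in list(c(0.5, 0.5), c(0.8, 0.2), c(0.35, 0.65))) {
    fixed <- fit_mixture(x, C = 1, fixed_props = w)
    expect_gte(free$loglik, fixed$loglik - 1e-6)
  }
})

test_that("AIC bookkeeping matches the documented parameter counts", {
  set.seed(77)
  x <- c(rlaplace(100, 0.2), rnorm(100, 1, 0.3))
  free <- fit_mixture(x, C = 1)
  expect_equal(free$aic - (-2 * free$loglik), 2 * (3 * 1 + 1))
  fixed <- fit_mixture(x, C = 1, fixed_props = c(0.5, 0.5))
  expect_equal(fixed$aic - (-2 * fixed$loglik), 2 * (2 * 1 + 1))
})

test_that("tail-area proportions follow the closed forms", {
  p <- mixture_params(pi0 = 0.5, pi = 0.5, tau = 10, mu = 1, sigma = 0.2)
  # zeta = 0: full two-tailed mass
  pr0 <- estimate_proportions(p, 0)
  expect_equal(pr0$P_FP, 0.5)
  expect_equal(pr0$P_TP, 0.5)
  # Laplace two-tail mass at zeta = scale * log 2 is 1/2
  pr <- estimate_proportions(p, 0.1 * log(2))
  expect_equal(pr$P_FP, 0.25)
  # both vanish far out
  prf <- estimate_proportions(p, 1e6)
  expect_equal(prf$P_FP, 0)
  expect_equal(prf$P_TP, 0)
  # monotone nonincreasing in zeta
  zs <- seq(0, 3, by = 0.1)
  fp <- vapply(zs, function(z) estimate_proportions(p, z)$P_FP, numeric(1))
  tp <- vapply(zs, function(z) estimate_proportions(p, z)$P_TP, numeric(1))
  expect_true(all(diff(fp) <= 1e-12))
  expect_true(all(diff(tp) <= 1e-12))
})

test_that("count estimates conserve m exactly", {
  expect_equal(estimate_counts(0.5, 0.5, 10), list(FP_hat = 5, TP_hat = 5))
  expect_equal(estimate_counts(0, 0.3, 7), list(FP_hat = 0, TP_hat = 7))
  cnt <- estimate_counts(0.57, 0.43, 96)
  expect_equal(cnt$TP_hat, 0.43 * 96 / (0.57 + 0.43))
  expect_error(estimate_counts(0, 0, 5), "both zero")
  set.seed(3)
  for (i in 1:25) {
    a <- runif(1); b <- runif(1); m <- sample(0:200, 1)
    cnt <- estimate_counts(a, b, m)
    expect_identical(cnt$FP_hat + cnt$TP_hat, as.numeric(m))
    expect_gte(cnt$FP_hat, 0)
    expect_gte(cnt$TP_hat, 0)
  }
})

test_that("AIC-based component selection honours its contract", {
  d <- tiny_data(60, 15, seed = 404,
                 beta = c(rep(1.3, 3), rep(0, 12)))
  path <- compute_path(d, min_ratio = 0.15)
  # a single candidate is returned as-is
  set.seed(11)
  expect_equal(as.integer(select_C_by_aic(path, candidate_Cs = 2)), 2L)
  # coefficients from a Laplace + single-normal structure prefer C = 1
  set.seed(12)
  C_sel <- select_C_by_aic(path, candidate_Cs = 1:3)
  expect_equal(as.integer(C_sel), 1L)
  tab <- attr(C_sel, "aic_table")
  expect_true(all(tab$C %in% 1:3))
  expect_true(all(tab$m >= 5))
})
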