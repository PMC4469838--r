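test_that("hypothesis proportions implement the count-shift rules", {
  # gene enters, charged to FP: (2+1)/6 and 3/6
  expect_equal(hypothesis_proportions(c(2, 3), 6, 0), c(3 / 6, 3 / 6))
  # gene enters, charged to TP component 1: 2/6 and (3+1)/6
  expect_equal(hypothesis_proportions(c(2, 3), 6, 1), c(2 / 6, 4 / 6))
  # gene leaves, decrement of a zero count is infeasible
  expect_null(hypothesis_proportions(c(0, 1), 0, 0))
  expect_null(hypothesis_proportions(c(0, 3), 2, 0))
  expect_equal(hypothesis_proportions(c(0, 3), 2, 1), c(0, 1))
  expect_error(hypothesis_proportions(c(2, 3), 8, 0), "differ")
  expect_error(hypothesis_proportions(c(2, 3), 6, 5), "hypothesis")
})

test_that("hypothesis proportions always sum to one when feasible", {
  set.seed(2)
  for (i in 1:40) {
    C <- sample(1:3, 1)
    prev <- as.integer(rmultinom(1, sample(3:30, 1), runif(C + 1)))
    dir <- sample(c(-1L, 1L), 1)
    m_next <- sum(prev) + dir
    if (m_next < 1) next
    for (h in 0:C) {
      pr <- hypothesis_proportions(prev, m_next, h)
      if (!is.null(pr)) expect_equal(sum(pr), 1)
    }
  }
})

tracked_fixture <- function(seed = 303) {
  d <- tiny_data(60, 25, seed = seed, beta = c(rep(1.4, 4), rep(0, 21)))
  path <- compute_path(d, min_ratio = 0.1)
  list(d = d, path = path, trace = run_tracking(path, C = 1))
}

test_that("tracking conserves counts and moves one at a time", {
  fx <- tracked_fixture()
  s <- fx$trace$states
  expect_identical(s$FP_hat + s$TP_hat_1, s$m)
  expect_identical(s$TP_hat, s$TP_hat_1)
  steps <- diff(s$m)
  expect_true(all(abs(steps) == 1))
  # exactly one count changes by exactly one, in the direction of m
  dFP <- diff(s$FP_hat); dTP <- diff(s$TP_hat_1)
  expect_true(all(dFP + dTP == steps))
  expect_true(all((dFP == 0) | (dTP == 0)))
  expect_true(all(s$FP_hat >= 0 & s$TP_hat_1 >= 0))
})

test_that("tracking is deterministic", {
  fx <- tracked_fixture(seed = 304)
  t2 <- run_tracking(fx$path, C = 1)
  expect_identical(fx$trace$states, t2$states)
})

test_that("the candidate log-likelihoods drive the decisions", {
  fx <- tracked_fixture(seed = 305)
  s <- fx$trace$states[-1, ]
  decided <- !is.na(s$C_max) & s$fallback == 0
  # the chosen component attains the maximum recorded log-likelihood
  for (i in which(decided)) {
    lls <- as.numeric(s[i, c("L_0", "L_1")])
    if (all(is.finite(lls)))
      expect_equal(lls[s$C_max[i] + 1], max(lls), tolerance = 1e-9)
  }
})

test_that("optimal-lambda selection maximizes TP and breaks ties to sparser fits", {
  mk_trace <- function(tp, lam) {
    states <- data.frame(k = seq_along(tp) - 1, lambda = lam,
                         m = tp + 1, FP_hat = rep(1, length(tp)),
                         TP_hat_1 = tp, TP_hat = tp)
    structure(list(states = states, C = 1L), class = "tp_trace")
  }
  tr <- mk_trace(c(0, 1, 2, 2, 1), c(10, 8, 6, 4, 2))
  opt <- select_optimal_lambda(tr)
  expect_equal(opt$k_star, 2)
  expect_equal(opt$lam_star, 6)
  expect_equal(opt$fpr, 1 / 3)
  tr2 <- mk_trace(c(0, 1, 2, 3, 4), c(10, 8, 6, 4, 2))
  expect_equal(select_optimal_lambda(tr2)$lam_star, 2)
})

test_that("TP gene identification ranks by coefficient magnitude", {
  beta <- c(0.3, -0.5, 0.1)
  names(beta) <- c("a", "b", "c")
  id <- identify_tp_genes(beta, 2)
  expect_equal(id$genes, c("b", "a"))
  expect_gt(id$zeta, 0.1)
  expect_lt(id$zeta, 0.3)
  expect_equal(identify_tp_genes(beta, 3)$genes, c("b", "a", "c"))
  expect_equal(identify_tp_genes(beta, 0)$genes, character(0))
  # fractional estimates are rounded half away from zero
  expect_equal(identify_tp_genes(beta, 1.5)$n_tp, 2L)
  expect_equal(identify_tp_genes(beta, 1.49)$n_tp, 1L)
  expect_error(identify_tp_genes(beta, 5), "exceeds")
})

test_that("early-rule variants stay within the count invariants", {
  d <- tiny_data(50, 20, seed = 711, beta = c(rep(1.5, 3), rep(0, 17)))
  path <- compute_path(d, min_ratio = 0.15)
  for (rule in c("tp", "fp")) {
    tr <- run_tracking(path, C = 1,
                       config = tracking_control(early_rule = rule))
    s <- tr$states
    expect_identical(s$FP_hat + s$TP_hat_1, s$m)
    early <- s[s$m > 0 & s$m < 5 & c(0, diff(s$m)) > 0, ]
    if (nrow(early))
      expect_true(all(early$C_max == if (rule == "tp") 1 else 0))
  }
})
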