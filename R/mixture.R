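#' Parameters of the Laplace + normal mixture for lasso estimates
#'
#' The density assumed for a lasso estimate at a fixed penalty is
#' \deqn{f(b) = \frac{n}{p}\left[\pi_0 f_L(b; 0, 1/\tau) +
#'   \sum_{c=1}^C \pi_c f_N(b; \mu_c, \sigma_c^2)\right] +
#'   \left(1 - \frac{n}{p}\right) f_L(b; 0, \epsilon),}
#' where \eqn{f_L} is the Laplace density and \eqn{f_N} the normal
#' density.  The zero-centred Laplace component absorbs the false
#' positives (in the Bayesian reading of the lasso the estimates are a
#' posterior mode under a Laplace prior), the normal components the true
#' positives, and the near-degenerate Laplace spike with scale
#' \eqn{\epsilon} accounts for the `p - n` coefficients that are exactly
#' zero when `p > n`.
#'
#' @param pi0 Proportion of false positives among selected genes.
#' @param pi Proportions of the `C` true-positive components;
#'   `pi0 + sum(pi)` must equal 1.
#' @param tau Laplace rate (false-positive scale is `1/tau`).
#' @param mu Nonzero means of the normal components.
#' @param sigma Positive standard deviations of the normal components.
#' @param eps Scale of the exact-zero spike (default 1e-8).
#' @param n_over_p The `n/p` prefactor in `(0, 1]`; with the default 1 the
#'   density is that of the nonzero (selected) coefficients only.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi0, pi, tau, mu, sigma, eps = 1e-8,
                           n_over_p = 1) {
  C <- length(pi)
  stopifnot(length(mu) == C, length(sigma) == C)
  if (pi0 < 0 || any(pi < 0) || abs(pi0 + sum(pi) - 1) > 1e-8)
    stop("mixture proportions must be nonnegative and sum to 1")
  if (tau <= 0) stop("tau must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (n_over_p <= 0 || n_over_p > 1) stop("n_over_p must be in (0, 1]")
  structure(list(pi0 = pi0, pi = pi, tau = tau, mu = mu, sigma = sigma,
                 C = C, eps = eps, n_over_p = n_over_p),
            class = "mixture_params")
}

dlaplace_log <- function(x, scale) -log(2 * scale) - abs(x) / scale

logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Log-density of the mixture for lasso estimates
#'
#' Evaluates the log of the full mixture density (including the `n/p`
#' prefactor and the exact-zero spike) with log-sum-exp stabilization.
#'
#' @param value Numeric vector of coefficient values.
#' @param params A [mixture_params()] object.
#' @return Numeric vector of log-densities.
#' @export
mixture_logpdf <- function(value, params) {
  stopifnot(inherits(params, "mixture_params"))
  np <- params$n_over_p
  terms <- matrix(-Inf, length(value), params$C + 2L)
  if (params$pi0 > 0)
    terms[, 1L] <- log(np) + log(params$pi0) +
      dlaplace_log(value, 1 / params$tau)
  for (c in seq_len(params$C)) {
    if (params$pi[c] > 0)
      terms[, 1L + c] <- log(np) + log(params$pi[c]) +
        dnorm(value, params$mu[c], params$sigma[c], log = TRUE)
  }
  if (np < 1)
    terms[, params$C + 2L] <- log(1 - np) + dlaplace_log(value, params$eps)
  logsumexp_rows(terms)
}

#' Control parameters for mixture fitting
#'
#' @param m_min Minimum number of coefficients required for a free fit.
#' @param n_restarts Random restarts for the free-proportion fit.
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @param mu_floor Absolute lower bound on `|mu_c|` (the normal means are
#'   nonzero by assumption).
#' @param mu_scale_mult Optional separation of the true-positive means
#'   from the false-positive component: when positive, `|mu_c|` is kept at
#'   or above `mu_scale_mult` Laplace scale units (`mu_scale_mult / tau`)
#'   during fitting.  The default 0 imposes no separation beyond
#'   `mu_floor`, matching the model as stated (the means are merely
#'   nonzero); see the methods vignette for why a true-positive component
#'   may legitimately sit close to zero and what that implies for
#'   specificity when no real signal is present.
#' @param sigma_floor,scale_floor Lower bounds on the normal standard
#'   deviations and the Laplace scale, keeping the constrained fits used by
#'   the tracking algorithm well defined on very small active sets.
#' @return A named list of control values.
#' @export
mixture_control <- function(m_min = 5L, n_restarts = 10L, maxit = 500L,
                            tol = 1e-8, mu_floor = 1e-4,
                            mu_scale_mult = 0, sigma_floor = 1e-4,
                            scale_floor = 1e-8) {
  list(m_min = as.integer(m_min), n_restarts = as.integer(n_restarts),
       maxit = as.integer(maxit), tol = tol, mu_floor = mu_floor,
       mu_scale_mult = mu_scale_mult, sigma_floor = sigma_floor,
       scale_floor = scale_floor)
}

# Deterministic moment-based starting values: Laplace scale from the small
# half of |x|, normal moments from the large half (quantile-split into C
# chunks when C > 1).
mix_init <- function(x, C, control) {
  ax <- sort(abs(x))
  m <- length(x)
  lo <- ax[seq_len(max(1L, floor(m / 2)))]
  b0 <- max(mean(lo), control$scale_floor)
  hi_idx <- order(abs(x), decreasing = TRUE)[seq_len(max(C, ceiling(m / 2)))]
  hi <- x[hi_idx]
  if (C == 1L) {
    mu0 <- mean(hi)
    s0 <- if (length(hi) > 1) sd(hi) else abs(mu0) / 2
  } else {
    qs <- cut(rank(hi, ties.method = "first"), C, labels = FALSE)
    mu0 <- tapply(hi, qs, mean)
    s0 <- tapply(hi, qs, function(v) if (length(v) > 1) sd(v) else NA)
    s0[!is.finite(s0)] <- max(mean(s0[is.finite(s0)]), control$sigma_floor)
  }
  mu0[!is.finite(mu0)] <- control$mu_floor
  s0 <- pmax(s0, control$sigma_floor, na.rm = TRUE)
  mu0 <- ifelse(abs(mu0) < control$mu_floor,
                ifelse(mu0 >= 0, control$mu_floor, -control$mu_floor), mu0)
  c(b0, as.numeric(mu0), as.numeric(s0))
}

# One constrained EM run; props fixed when update_props = FALSE.
mix_em <- function(x, props, update_props, init, control) {
  mix_em_cpp(as.numeric(x), as.numeric(props), update_props,
             as.numeric(init), control$mu_floor, control$mu_scale_mult,
             control$sigma_floor, control$scale_floor, control$tol,
             control$maxit)
}

#' Maximum-likelihood fit of the mixture to nonzero lasso coefficients
#'
#' Fits the Laplace (false positive) + `C`-component normal (true
#' positive) mixture to the `m` nonzero coefficients by EM with
#' closed-form M-steps, refined over random restarts.  The exact-zero
#' spike term and the `n/p` prefactor are parameter-free on nonzero
#' values, so the fit maximizes the likelihood of the selected-gene
#' density with `pi0 + sum(pi_c) = 1`.
#'
#' @param coeffs Nonzero coefficient values.
#' @param C Number of normal (true-positive) components.
#' @param fixed_props Optional proportion vector `(pi0, pi_1, ..., pi_C)`;
#'   when given only `tau`, `mu`, `sigma` are optimized (the
#'   fixed-hypothesis fits of the tracking algorithm).
#' @param n_over_p The `n/p` prefactor used when reporting the full
#'   log-likelihood.
#' @param eps Exact-zero spike scale.
#' @param control See [mixture_control()].
#' @return An object of class `mixture_fit`: `params`
#'   ([mixture_params()]), `loglik`, `aic`, `n_obs`, `converged`,
#'   `iterations`.  The AIC uses `3C + 1` free parameters when proportions
#'   are free and `2C + 1` when they are fixed.
#' @export
fit_mixture <- function(coeffs, C = 1L, fixed_props = NULL, n_over_p = 1,
                        eps = 1e-8, control = mixture_control()) {
  coeffs <- as.numeric(coeffs)
  m <- length(coeffs)
  C <- as.integer(C)
  if (C < 1L) stop("C must be at least 1")
  if (m < max(control$m_min, 2L * C + 2L))
    stop("insufficient active set: need at least ",
         max(control$m_min, 2L * C + 2L), " coefficients, got ", m)
  if (var(coeffs) < 1e-20)
    stop("degenerate fit: all coefficients are numerically identical")
  if (!is.null(fixed_props)) {
    if (length(fixed_props) != C + 1L)
      stop("fixed_props must have length C + 1")
    if (any(fixed_props < 0) || abs(sum(fixed_props) - 1) > 1e-8)
      stop("fixed_props must be nonnegative and sum to 1")
  }

  base_init <- mix_init(coeffs, C, control)
  free <- is.null(fixed_props)
  props0 <- if (free) rep(1 / (C + 1), C + 1) else as.numeric(fixed_props)

  best <- NULL
  n_try <- if (free) max(1L, control$n_restarts) else 1L
  n_degen <- 0L
  for (r in seq_len(n_try)) {
    init <- base_init
    props <- props0
    if (r > 1L) {       # jittered restart
      init[1] <- base_init[1] * exp(runif(1, -1, 1))
      init[2:(C + 1)] <- base_init[2:(C + 1)] * runif(C, 0.5, 1.5) +
        rnorm(C, 0, 0.1 * max(abs(coeffs)))
      init[(C + 2):(2 * C + 1)] <-
        base_init[(C + 2):(2 * C + 1)] * exp(runif(C, -1, 1))
      w <- runif(C + 1, 0.1, 1)
      props <- w / sum(w)
    }
    fit <- mix_em(coeffs, props, free, init, control)
    if (free && any(fit$sigma <= control$sigma_floor * 1.000001)) {
      # a normal component collapsed onto (nearly) a single value; its
      # likelihood is floor-bound, not a genuine optimum
      n_degen <- n_degen + 1L
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("degenerate fit: every restart collapsed a normal component ",
         "(", n_degen, "/", n_try, " restarts, sigma at the floor ",
         control$sigma_floor, ")")

  params <- mixture_params(pi0 = best$props[1], pi = best$props[-1],
                           tau = 1 / best$b, mu = best$mu,
                           sigma = best$sigma, eps = eps,
                           n_over_p = n_over_p)
  loglik <- sum(mixture_logpdf(coeffs, params))
  npar <- if (free) 3L * C + 1L else 2L * C + 1L
  structure(list(params = params, loglik = loglik,
                 aic = -2 * loglik + 2 * npar, n_obs = m, npar = npar,
                 converged = best$converged,
                 iterations = best$iterations),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  p <- x$params
  cat("<mixture_fit> C = ", p$C, ", n_obs = ", x$n_obs,
      ", loglik = ", signif(x$loglik, 6), ", AIC = ", signif(x$aic, 6),
      "\n  pi0 = ", signif(p$pi0, 4), "  scale 1/tau = ",
      signif(1 / p$tau, 4), "\n", sep = "")
  for (c in seq_len(p$C))
    cat("  component ", c, ": pi = ", signif(p$pi[c], 4), ", mu = ",
        signif(p$mu[c], 4), ", sigma = ", signif(p$sigma[c], 4), "\n",
        sep = "")
  invisible(x)
}

#' Estimated proportions of false and true positives
#'
#' Two-tailed areas outside the cut-off `zeta` under the fitted Laplace
#' (false positive) and normal (true positive) components.
#'
#' @param fit A `mixture_fit` or [mixture_params()] object.
#' @param zeta Nonnegative coefficient-magnitude cut-off; with `zeta = 0`
#'   the proportions reduce to `pi0` and `sum(pi_c)` exactly.
#' @return List with elements `P_FP` and `P_TP`, both in `[0, 1]`.
#' @export
estimate_proportions <- function(fit, zeta = 0) {
  params <- if (inherits(fit, "mixture_fit")) fit$params else fit
  stopifnot(inherits(params, "mixture_params"), zeta >= 0)
  P_FP <- params$pi0 * exp(-params$tau * zeta)
  P_TP <- sum(params$pi *
                (pnorm((-zeta - params$mu) / params$sigma) +
                 pnorm((zeta - params$mu) / params$sigma,
                       lower.tail = FALSE)))
  list(P_FP = P_FP, P_TP = P_TP)
}

#' Estimated counts of false and true positives
#'
#' Splits the `m` selected genes proportionally to the estimated FP and TP
#' areas: `TP_hat = P_TP / (P_TP + P_FP) * m` and `FP_hat = m - TP_hat`,
#' so the two counts always sum to `m` exactly.
#'
#' @param P_FP,P_TP Estimated proportions (see [estimate_proportions()]).
#' @param m Number of selected genes.
#' @return List with elements `FP_hat` and `TP_hat`.
#' @export
estimate_counts <- function(P_FP, P_TP, m) {
  stopifnot(m >= 0, P_FP >= 0, P_TP >= 0)
  if (P_FP + P_TP <= 0)
    stop("P_FP and P_TP are both zero; counts are undefined")
  FP_hat <- P_FP / (P_TP + P_FP) * m
  list(FP_hat = FP_hat, TP_hat = m - FP_hat)
}

#' Choose the number of true-positive components by AIC
#'
#' Fits the free-proportion mixture with each candidate `C` at every path
#' step with enough active genes and returns the candidate with the best
#' (lowest) AIC on the largest number of steps; ties go to the smaller
#' `C`.
#'
#' @param path A [compute_path()] result.
#' @param candidate_Cs Candidate component counts (default 1:3).
#' @param n_over_p The `n/p` prefactor passed to [fit_mixture()].
#' @param control See [mixture_control()].
#' @return The selected `C`, with the per-step AIC table in attribute
#'   `aic_table`.
#' @export
select_C_by_aic <- function(path, candidate_Cs = 1:3, n_over_p = 1,
                            control = mixture_control()) {
  stopifnot(inherits(path, "lasso_path"), length(candidate_Cs) >= 1)
  candidate_Cs <- sort(unique(as.integer(candidate_Cs)))
  rows <- list()
  for (k in seq_len(nrow(path$steps))) {
    beta_k <- path$beta[, k]
    act <- active_set(beta_k, path$zero_tol)
    need <- max(control$m_min, 2L * max(candidate_Cs) + 2L)
    if (length(act) < need) next
    aics <- vapply(candidate_Cs, function(C) {
      fit <- tryCatch(fit_mixture(beta_k[act], C = C, n_over_p = n_over_p,
                                  control = control),
                      error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$aic
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(k = path$steps$k[k], m = length(act),
                 C = candidate_Cs, aic = aics)
  }
  if (!length(rows))
    stop("no path step has enough active genes for the mixture fit")
  tab <- do.call(rbind, rows)
  wins <- integer(length(candidate_Cs))
  names(wins) <- candidate_Cs
  for (kk in unique(tab$k)) {
    sub <- tab[tab$k == kk & is.finite(tab$aic), , drop = FALSE]
    if (!nrow(sub)) next
    best <- sub$C[which.min(sub$aic)]   # which.min: first = smallest C on ties
    wins[as.character(best)] <- wins[as.character(best)] + 1L
  }
  C_sel <- candidate_Cs[which.max(wins)]  # first max = smallest C on ties
  attr(C_sel, "aic_table") <- tab
  attr(C_sel, "wins") <- wins
  C_sel
}
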