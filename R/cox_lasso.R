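#' Cox log partial likelihood
#'
#' Evaluates the log partial likelihood
#' \deqn{l(\beta) = \sum_i \delta_i [x_i'\beta - \log \sum_{r \in R(t_i)}
#' \exp(x_r'\beta)]}
#' with risk sets \eqn{R(t_i) = \{r : t_r \ge t_i\}}; tied event times are
#' handled by the Breslow convention (tied events share one risk set).
#'
#' @param beta Coefficient vector of length `p`.
#' @param data A [survival_dataset()].
#' @return The log partial likelihood (a finite scalar for finite inputs).
#' @export
cox_partial_loglik <- function(beta, data) {
  prep <- check_cox_args(beta, data)
  cox_stats_cpp(prep$X, prep$delta, prep$grp, as.numeric(beta))$loglik
}

#' Gradient of the Cox log partial likelihood
#'
#' @inheritParams cox_partial_loglik
#' @return Numeric vector \eqn{\partial l/\partial\beta} of length `p`,
#'   named by gene id.
#' @export
cox_gradient <- function(beta, data) {
  prep <- check_cox_args(beta, data)
  g <- cox_stats_cpp(prep$X, prep$delta, prep$grp, as.numeric(beta))$gradient
  names(g) <- data$gene_ids
  g
}

check_cox_args <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$events) == 0) stop("no events")
  beta <- as.numeric(beta)
  if (length(beta) != data$p)
    stop("beta must have length p = ", data$p)
  if (anyNA(beta) || !all(is.finite(beta)))
    stop("beta contains non-finite values")
  cox_prep(data)
}

#' Entry value of the penalty parameter
#'
#' Computes \eqn{\lambda_0 = \max_j |\partial l/\partial\beta_j|} at
#' \eqn{\beta = 0}, the smallest penalty for which the all-zero vector
#' solves the L1-penalized problem.
#'
#' @inheritParams cox_partial_loglik
#' @return The scalar \eqn{\lambda_0 \ge 0}.
#' @export
compute_lambda0 <- function(data) {
  max(abs(cox_gradient(rep(0, data$p), data)))
}

#' Active set of a coefficient vector
#'
#' @param beta Coefficient vector.
#' @param zero_tol Magnitudes at or below this value count as zero.
#' @return Integer indices `j` with `|beta_j| > zero_tol`.
#' @export
active_set <- function(beta, zero_tol = 1e-10) {
  which(abs(beta) > zero_tol)
}

#' Control parameters for the path solver
#'
#' @param zero_tol Coefficient magnitude below which an estimate counts as
#'   zero (the solver itself produces exact zeros).
#' @param kkt_tol_rel KKT tolerance relative to `lambda0`; a fit is accepted
#'   only when every zero coefficient satisfies
#'   `|dl/dbeta_j| <= lambda + kkt_tol` and every nonzero one satisfies
#'   `|dl/dbeta_j - lambda * sign(beta_j)| <= kkt_tol`.
#' @param step_tol_rel Width of the bisection bracket around each
#'   active-set change point, relative to `lambda0`.  Changes that cannot
#'   be separated at this resolution are emitted as pseudo-steps at the
#'   same lambda, ordered by descending gradient magnitude.
#' @param max_outer,max_cycles Iteration caps for the penalized solver.
#' @param standardize Z-score the expression columns before fitting
#'   (default off: columns are used as provided).
#' @return A named list of control values.
#' @export
path_control <- function(zero_tol = 1e-10, kkt_tol_rel = 1e-6,
                         step_tol_rel = 1e-8, max_outer = 200L,
                         max_cycles = 50L, standardize = FALSE) {
  list(zero_tol = zero_tol, kkt_tol_rel = kkt_tol_rel,
       step_tol_rel = step_tol_rel, max_outer = as.integer(max_outer),
       max_cycles = as.integer(max_cycles), standardize = standardize)
}

#' L1-penalized Cox fit at a single penalty value
#'
#' Maximizes \eqn{l(\beta) - \lambda \sum_j |\beta_j|} by proximal-Newton
#' coordinate descent.  The returned estimate is certified against the KKT
#' system of the penalized problem (see [path_control()]); a warm start may
#' be supplied but the result is start-independent within tolerance.
#'
#' @param lam Positive penalty value.
#' @param data A [survival_dataset()].
#' @param beta_init Optional warm-start coefficient vector.
#' @param control See [path_control()].
#' @return Coefficient vector of length `p`, named by gene id, with
#'   attributes `m`, `loglik`, `kkt_zero`, `kkt_active`.
#' @export
fit_lasso_at <- function(lam, data, beta_init = NULL,
                         control = path_control()) {
  stopifnot(inherits(data, "survival_dataset"), lam > 0)
  if (sum(data$events) == 0) stop("no events")
  prep <- cox_prep(data)
  if (is.null(beta_init)) beta_init <- rep(0, data$p)
  lam0 <- max(abs(cox_stats_cpp(prep$X, prep$delta, prep$grp,
                                rep(0, data$p))$gradient))
  kkt_tol <- control$kkt_tol_rel * max(lam0, 1e-8)
  fit <- cox_cd_solve(prep$X, prep$delta, prep$grp, lam,
                      as.numeric(beta_init), kkt_tol,
                      control$max_outer, control$max_cycles)
  if (!fit$converged)
    stop(sprintf(paste0("penalized Cox solver did not converge at lambda=%g",
                        " (cycles=%d, kkt_zero=%g, kkt_active=%g)"),
                 lam, fit$cycles, fit$kkt_zero, fit$kkt_active))
  beta <- fit$beta
  names(beta) <- data$gene_ids
  attr(beta, "m") <- fit$m
  attr(beta, "loglik") <- fit$loglik
  attr(beta, "kkt_zero") <- fit$kkt_zero
  attr(beta, "kkt_active") <- fit$kkt_active
  beta
}

#' Solution path of the Cox lasso with one-gene-at-a-time steps
#'
#' Computes the lasso estimates \eqn{\hat\beta(\lambda_k)} for a decreasing
#' sequence \eqn{\lambda_0 > \lambda_1 > \dots} in which each step length
#' \eqn{\Delta_k = \lambda_k - \lambda_{k+1}} is the minimum decrement that
#' changes the set of selected genes, so that exactly one gene enters or
#' leaves the active set between consecutive steps.  Change points are
#' located by bisection; estimates at the current step warm-start the next.
#'
#' @param data A [survival_dataset()].
#' @param lambda_min Absolute terminal penalty (exclusive with
#'   `min_ratio`).
#' @param min_ratio Terminal penalty as a fraction of `lambda0`
#'   (default 0.05 when neither argument is given).
#' @param max_steps Stop after this many steps even if `lambda_min` has not
#'   been reached.
#' @param control See [path_control()].
#' @return An object of class `lasso_path`: a list with the per-step table
#'   `steps` (k, lambda, m, change_gene, change_dir), the `p x (K+1)`
#'   coefficient matrix `beta`, `lambda0`, `lambda_min`, `zero_tol` and
#'   solver `diagnostics`.
#' @export
compute_path <- function(data, lambda_min = NULL, min_ratio = NULL,
                         max_steps = Inf, control = path_control()) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$events) == 0) stop("no events")
  if (!is.null(lambda_min) && !is.null(min_ratio))
    stop("give exactly one of lambda_min / min_ratio")
  if (is.null(lambda_min) && is.null(min_ratio)) min_ratio <- 0.05
  if (control$standardize) {
    data <- survival_dataset(scale(data$expression), data$times, data$events,
                             data$gene_ids, data$patient_ids)
  }
  prep <- cox_prep(data)
  p <- data$p

  g0 <- cox_stats_cpp(prep$X, prep$delta, prep$grp, rep(0, p))$gradient
  lam0 <- max(abs(g0))
  if (lam0 <= control$zero_tol)
    stop("degenerate design: lambda0 is zero (no covariate carries signal)")
  lam_min <- if (!is.null(lambda_min)) lambda_min else min_ratio * lam0
  if (lam_min >= lam0)
    stop("lambda_min must be below lambda0 = ", signif(lam0, 6))
  if (lam_min <= 0) stop("lambda_min must be positive")

  kkt_tol <- control$kkt_tol_rel * lam0
  step_tol <- control$step_tol_rel * lam0
  solve_at <- function(lam, init) {
    fit <- cox_cd_solve(prep$X, prep$delta, prep$grp, lam, init, kkt_tol,
                        control$max_outer, control$max_cycles)
    if (!fit$converged)
      stop(sprintf("path solver did not converge at lambda=%g", lam))
    fit
  }

  K_alloc <- if (is.finite(max_steps)) max_steps + 1L else 64L
  beta_mat <- matrix(0, p, K_alloc)
  steps <- list(list(k = 0L, lambda = lam0, m = 0L,
                     change_gene = NA_integer_, change_dir = NA_integer_,
                     kkt_zero = 0, kkt_active = 0))
  grow <- function(mat, k) {
    if (k <= ncol(mat)) return(mat)
    cbind(mat, matrix(0, nrow(mat), ncol(mat)))
  }

  lam_cur <- lam0
  beta_cur <- rep(0, p)
  act_cur <- integer(0)
  k <- 0L
  n_solves <- 0L
  delta_try <- 0.01 * lam0
  max_kkt <- 0

  while (k < max_steps && lam_cur > lam_min + step_tol) {
    # --- expansion: find a trial lambda where the active set changes ---
    hi <- lam_cur
    beta_hi <- beta_cur
    fit_lo <- NULL
    repeat {
      # geometric cap keeps warm starts effective across long flat stretches
      trial <- max(hi - min(delta_try, 0.25 * hi), lam_min)
      fit <- solve_at(trial, beta_hi)
      n_solves <- n_solves + 1L
      act <- fit$active
      if (!identical(act, act_cur)) {
        lo <- trial
        fit_lo <- fit
        break
      }
      hi <- trial
      beta_hi <- fit$beta
      if (trial <= lam_min) break   # no further change above lambda_min
      delta_try <- delta_try * 2
    }
    if (is.null(fit_lo)) break

    # --- bisection on [lo, hi]: hi keeps the current set, lo differs ---
    while (hi - lo > step_tol) {
      mid <- (hi + lo) / 2
      fit <- solve_at(mid, beta_hi)
      n_solves <- n_solves + 1L
      if (!identical(fit$active, act_cur)) {
        lo <- mid
        fit_lo <- fit
      } else {
        hi <- mid
        beta_hi <- fit$beta
      }
    }

    act_lo <- fit_lo$active
    entered <- setdiff(act_lo, act_cur)
    left <- setdiff(act_cur, act_lo)
    changes <- c(entered, left)
    dirs <- c(rep(1L, length(entered)), rep(-1L, length(left)))
    if (length(changes) > 1L) {
      # simultaneous changes at numerically indistinguishable lambda:
      # emit pseudo-steps ordered by descending |gradient| at the last
      # unchanged solution
      gref <- abs(cox_stats_cpp(prep$X, prep$delta, prep$grp,
                                beta_hi)$gradient[changes])
      o <- order(gref, decreasing = TRUE)
      changes <- changes[o]
      dirs <- dirs[o]
    }
    beta_lo <- fit_lo$beta
    max_kkt <- max(max_kkt, fit_lo$kkt_zero, fit_lo$kkt_active)

    for (q in seq_along(changes)) {
      k <- k + 1L
      beta_mat <- grow(beta_mat, k + 1L)
      if (q == length(changes)) {
        bq <- beta_lo
      } else {
        # intermediate pseudo-step: later changes not yet applied
        bq <- beta_lo
        later <- changes[(q + 1L):length(changes)]
        later_dir <- dirs[(q + 1L):length(changes)]
        bq[later[later_dir > 0]] <- 0
        bq[later[later_dir < 0]] <- beta_hi[later[later_dir < 0]]
      }
      beta_mat[, k + 1L] <- bq
      steps[[k + 1L]] <- list(k = k, lambda = lo,
                              m = length(active_set(bq, control$zero_tol)),
                              change_gene = changes[q], change_dir = dirs[q],
                              kkt_zero = fit_lo$kkt_zero,
                              kkt_active = fit_lo$kkt_active)
      if (k >= max_steps) break
    }

    delta_try <- min(max(lam_cur - lo, 4 * step_tol), 0.25 * lo)
    lam_cur <- lo
    beta_cur <- beta_lo
    act_cur <- act_lo
  }

  steps_df <- do.call(rbind, lapply(steps, function(s)
    data.frame(k = s$k, lambda = s$lambda, m = s$m,
               change_gene = s$change_gene, change_dir = s$change_dir,
               kkt_zero = s$kkt_zero, kkt_active = s$kkt_active)))
  rownames(steps_df) <- NULL
  beta_mat <- beta_mat[, seq_len(k + 1L), drop = FALSE]
  dimnames(beta_mat) <- list(data$gene_ids, paste0("k", 0:k))
  structure(list(steps = steps_df, beta = beta_mat, lambda0 = lam0,
                 lambda_min = lam_min, zero_tol = control$zero_tol,
                 gene_ids = data$gene_ids,
                 diagnostics = list(n_solves = n_solves,
                                    max_kkt_violation = max_kkt,
                                    kkt_tol = kkt_tol,
                                    step_tol = step_tol)),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  K <- nrow(x$steps) - 1L
  cat("<lasso_path> ", K, " steps; lambda0 = ", signif(x$lambda0, 6),
      ", last lambda = ", signif(x$steps$lambda[K + 1L], 6),
      ", final m = ", x$steps$m[K + 1L], "\n", sep = "")
  cat("  solver: ", x$diagnostics$n_solves, " fits, max KKT violation ",
      signif(x$diagnostics$max_kkt_violation, 3), "\n", sep = "")
  invisible(x)
}
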