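#' Configuration of the Monte Carlo accuracy study
#'
#' The study conditions: `n` patients whose gene-expression rows are drawn
#' from a multivariate normal with mean zero and AR(1) covariance
#' `Sigma_kl = rho^|k-l|` (unit variances), `p1` outcome-predictive genes
#' chosen uniformly at random with Cox coefficient `effect` (all other
#' genes have coefficient zero), and survival times generated from the
#' exponential hazard model `t_i = -log(U_i) / exp(x_i' beta)` with
#' `U_i ~ Uniform(0, 1)`.  All events are observed by default (the
#' generator defines event times only); an optional censoring rate is
#' available for sensitivity work.
#'
#' @param n Number of patients (default 200).
#' @param p Number of genes (default 1000).
#' @param p1 Number of outcome-predictive genes (default 5; the study also
#'   uses 30).
#' @param effect Cox coefficient of the predictive genes (default 1.5).
#' @param rho AR(1) base correlation in `[0, 1)` (default 0; the study
#'   also uses 0.5).
#' @param lambda_min Terminal penalty of the path (default 5).
#' @param C Number of true-positive mixture components for tracking
#'   (default 1).
#' @param report_ks Path steps at which to summarize (default
#'   `c(5, 10, 50, 100, 150)`).
#' @param n_reps Number of Monte Carlo replicates (default 100; the full
#'   study uses 1000).
#' @param seed Master seed; per-replicate seeds are spawned from it so any
#'   subset of replicates is reproducible in isolation.
#' @param censor_rate Fraction of patients independently censored
#'   (default 0 = none).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 200L, p = 1000L, p1 = 5L, effect = 1.5,
                       rho = 0, lambda_min = 5, C = 1L,
                       report_ks = c(5L, 10L, 50L, 100L, 150L),
                       n_reps = 100L, seed = 1L, censor_rate = 0) {
  stopifnot(p1 <= p, p1 >= 0, rho >= 0, rho < 1, is.finite(effect),
            n_reps >= 1, lambda_min > 0, n >= 2,
            censor_rate >= 0, censor_rate < 1)
  structure(list(n = as.integer(n), p = as.integer(p), p1 = as.integer(p1),
                 effect = effect, rho = rho, lambda_min = lambda_min,
                 C = as.integer(C),
                 report_ks = sort(as.integer(report_ks)),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 censor_rate = censor_rate),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic survival dataset
#'
#' Draws expression and survival data under the study conditions of a
#' [sim_config()]; deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this dataset.
#' @return List with `data` (a [survival_dataset()]) and `true_support`
#'   (indices of the outcome-predictive genes).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n; p <- config$p
    X <- matrix(rnorm(n * p), n, p)
    if (config$rho > 0) {       # AR(1): x_j = rho x_{j-1} + sqrt(1-rho^2) z_j
      sq <- sqrt(1 - config$rho^2)
      for (j in 2:p) X[, j] <- config$rho * X[, j - 1L] + sq * X[, j]
    }
    true_support <- if (config$p1 > 0) sort(sample.int(p, config$p1))
                    else integer(0)
    eta <- if (config$p1 > 0)
      drop(X[, true_support, drop = FALSE] %*%
             rep(config$effect, config$p1)) else rep(0, n)
    U <- runif(n)
    times <- -log(U) / exp(eta)
    events <- rep(1, n)
    if (config$censor_rate > 0) {
      cens <- runif(n) < config$censor_rate
      times[cens] <- times[cens] * runif(sum(cens))
      events[cens] <- 0
    }
    list(data = survival_dataset(X, times, events),
         true_support = true_support)
  })
}

#' True number of true positives in an active set
#'
#' @param beta Coefficient vector.
#' @param true_support Indices of the genes that truly carry signal.
#' @param zero_tol See [active_set()].
#' @return Number of active genes belonging to the true support.
#' @export
true_tp_count <- function(beta, true_support, zero_tol = 1e-10) {
  length(intersect(active_set(beta, zero_tol), true_support))
}

#' Run the Monte Carlo accuracy study
#'
#' For each replicate: generate a dataset, compute the lasso solution path
#' with one-gene-at-a-time steps up to `max(report_ks)` steps (or until
#' the penalty reaches `lambda_min`), run the sequential tracking
#' algorithm with the configured `C`, and record the penalty, active-set
#' size, true TP count, and estimated TP/FP counts at every step.
#' Replicates whose path ends before a requested step contribute only to
#' the steps they reach; effective replicate counts are reported.
#'
#' @param config A [sim_config()].
#' @param path_ctl,track_ctl Solver and tracking controls.  The default
#'   path control uses a change-point bracket of `1e-3 * lambda0`, which
#'   localizes each reported penalty far below the precision at which the
#'   summaries are read.
#' @param progress Print a dot per replicate.
#' @return An object of class `sim_table`: the summary data frame `table`
#'   (one row per reported step: means, Monte Carlo standard errors,
#'   `n_eff`), the per-step mean curves over all steps in `per_k`, and
#'   `failures`.
#' @export
run_simulation <- function(config,
                           path_ctl = path_control(step_tol_rel = 1e-3),
                           track_ctl = tracking_control(),
                           progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  kmax <- max(config$report_ks)
  rep_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    config$n_reps))
  per_rep <- vector("list", config$n_reps)
  failures <- list()
  for (r in seq_len(config$n_reps)) {
    res <- tryCatch({
      gen <- generate_dataset(config, rep_seeds[r])
      path <- compute_path(gen$data, lambda_min = config$lambda_min,
                           max_steps = kmax, control = path_ctl)
      trace <- run_tracking(path, C = config$C,
                            n_over_p = config$n / config$p,
                            config = track_ctl)
      s <- trace$states
      ks <- s$k[-1L]
      true_tp <- vapply(seq_along(ks), function(i)
        true_tp_count(path$beta[, i + 1L], gen$true_support,
                      path$zero_tol), numeric(1))
      data.frame(rep = r, k = ks, lambda = s$lambda[-1L], m = s$m[-1L],
                 true_tp = true_tp, tp_hat = s$TP_hat[-1L],
                 fp_hat = s$FP_hat[-1L])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(rep = r, seed = rep_seeds[r], message = conditionMessage(res))
    } else {
      per_rep[[r]] <- res
    }
    if (progress) cat(if (inherits(res, "error")) "x" else ".")
    if (length(failures) > 0.05 * config$n_reps)
      stop("more than 5% of replicates failed; first error (replicate ",
           failures[[1L]]$rep, "): ", failures[[1L]]$message)
  }
  if (progress) cat("\n")
  long <- do.call(rbind, per_rep)
  agg <- function(kk) {
    sub <- long[long$k == kk, , drop = FALSE]
    n_eff <- nrow(sub)
    if (!n_eff) return(NULL)
    mean_se <- function(v) c(mean(v), if (n_eff > 1) sd(v) / sqrt(n_eff)
                                      else 0)
    lam <- mean_se(sub$lambda); m <- mean_se(sub$m)
    tt <- mean_se(sub$true_tp); tp <- mean_se(sub$tp_hat)
    fp <- mean_se(sub$fp_hat)
    data.frame(p1 = config$p1, rho = config$rho, k = kk,
               lambda = lam[1], m = m[1], true_tp = tt[1], tp_hat = tp[1],
               fp_hat = fp[1], se_lambda = lam[2], se_m = m[2],
               se_true_tp = tt[2], se_tp_hat = tp[2], se_fp_hat = fp[2],
               n_eff = n_eff)
  }
  table <- do.call(rbind, lapply(config$report_ks, agg))
  per_k <- do.call(rbind, lapply(sort(unique(long$k)), agg))
  rownames(table) <- rownames(per_k) <- NULL
  structure(list(table = table, per_k = per_k, failures = failures,
                 config = config, n_fail = length(failures)),
            class = "sim_table")
}

#' @export
print.sim_table <- function(x, ...) {
  cat("<sim_table> p1 = ", x$config$p1, ", rho = ", x$config$rho,
      ", ", x$config$n_reps - x$n_fail, "/", x$config$n_reps,
      " replicates\n", sep = "")
  print(x$table[, c("k", "lambda", "m", "true_tp", "tp_hat", "fp_hat",
                    "n_eff")], digits = 4, row.names = FALSE)
  invisible(x)
}
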