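#' Event-stratified cross-validation folds
#'
#' @param events 0/1 event indicator vector.
#' @param K Number of folds.
#' @param seed Fold-assignment seed.
#' @return Integer fold label per patient, each fold holding events in
#'   proportion.
#' @export
make_folds <- function(events, K = 5L, seed = 1L) {
  stopifnot(K >= 2L)
  n <- length(events)
  folds <- integer(n)
  with_seed(seed, {
    for (grp in unique(events)) {
      idx <- which(events == grp)
      folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  })
  folds
}

#' Cross-validated partial likelihood at one penalty value
#'
#' The K-fold cross-validated partial likelihood
#' \deqn{CV(\lambda) = \sum_k [l(\hat\beta^{(-k)}) -
#'   l_{(-k)}(\hat\beta^{(-k)})],}
#' where \eqn{\hat\beta^{(-k)}} is the lasso fit at `lambda` on the data
#' minus fold `k`, `l` the full-data log partial likelihood and
#' \eqn{l_{(-k)}} the likelihood excluding fold `k` (the
#' Verweij-van Houwelingen form).
#'
#' @param lam Penalty value.
#' @param data A [survival_dataset()].
#' @param K Number of folds (default 5).
#' @param fold_seed Fold-assignment seed.
#' @param folds Optional explicit fold labels (overrides `K`/`fold_seed`).
#' @param control See [path_control()].
#' @return The scalar CV value (larger is better).
#' @export
cv_score <- function(lam, data, K = 5L, fold_seed = 1L, folds = NULL,
                     control = path_control()) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(folds)) folds <- make_folds(data$events, K, fold_seed)
  total <- 0
  for (kf in sort(unique(folds))) {
    test <- folds == kf
    if (sum(data$events[test]) == 0)
      stop("degenerate fold: fold ", kf, " contains no events")
    train <- subset_patients(data, !test)
    if (sum(train$events) == 0) stop("degenerate fold: no training events")
    beta <- fit_lasso_at(lam, train, control = control)
    total <- total + cox_partial_loglik(beta, data) -
      cox_partial_loglik(beta, train)
  }
  total
}

#' Select the penalty by cross-validated partial likelihood
#'
#' Evaluates [cv_score()] at every distinct penalty value of a computed
#' path (warm-starting down the sequence within each fold) and returns the
#' maximizer; ties go to the larger penalty.
#'
#' @param data A [survival_dataset()].
#' @param path A [compute_path()] result.
#' @param K,fold_seed,control As in [cv_score()].
#' @return List with `lambda` (the selected penalty) and `cv` (data frame
#'   of lambda vs CV value).
#' @export
select_lambda_by_cv <- function(data, path, K = 5L, fold_seed = 1L,
                                control = path_control()) {
  stopifnot(inherits(path, "lasso_path"))
  lams <- sort(unique(path$steps$lambda), decreasing = TRUE)
  folds <- make_folds(data$events, K, fold_seed)
  cv <- numeric(length(lams))
  for (kf in sort(unique(folds))) {
    test <- folds == kf
    if (sum(data$events[test]) == 0)
      stop("degenerate fold: fold ", kf, " contains no events")
    train <- subset_patients(data, !test)
    beta <- rep(0, data$p)
    for (i in seq_along(lams)) {
      beta <- fit_lasso_at(lams[i], train, beta_init = beta,
                           control = control)
      cv[i] <- cv[i] + cox_partial_loglik(beta, data) -
        cox_partial_loglik(beta, train)
    }
  }
  best <- which.max(cv)    # first max = largest lambda on ties
  list(lambda = lams[best],
       cv = data.frame(lambda = lams, cv = cv))
}

#' Prognostic index and median dichotomy
#'
#' The prognostic index is the linear risk score `eta_i = x_i' beta`.
#' Patients at or below the median form the "better" prognostic group
#' (lower hazard), the rest the "worse" group.
#'
#' @param beta Coefficient vector.
#' @param data A [survival_dataset()].
#' @return List with `eta`, `median` and `group` (factor
#'   better/worse).
#' @export
prognostic_index <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  eta <- drop(data$expression %*% as.numeric(beta))
  med <- median(eta)
  group <- factor(ifelse(eta <= med, "better", "worse"),
                  levels = c("better", "worse"))
  list(eta = setNames(eta, data$patient_ids), median = med, group = group)
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square comparison of the survival curves of two
#' groups (delegates to [survival::survdiff()]).
#'
#' @param times,events Survival outcome vectors.
#' @param groups Two-level grouping factor; both groups must be nonempty.
#' @return The p-value, with the chi-square statistic in attribute
#'   `statistic`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L || any(table(groups) == 0))
    stop("logrank_test requires two nonempty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  attr(p, "statistic") <- sd$chisq
  p
}

#' Wald p-value for the prognostic index in a Cox model
#'
#' Fits the one-covariate Cox model `h(t | eta) = h0(t) exp(alpha * eta)`
#' by maximizing the package's partial likelihood and returns the Wald
#' p-value for `alpha`.
#'
#' @param eta Prognostic-index vector (must not be constant).
#' @param data A [survival_dataset()] providing the outcomes.
#' @return The p-value, with `alpha` and `se` as attributes.
#' @export
pi_cox_pvalue <- function(eta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sd(eta) == 0) stop("prognostic index is constant")
  d1 <- survival_dataset(matrix(eta, ncol = 1), data$times, data$events,
                         gene_ids = "eta",
                         patient_ids = data$patient_ids)
  fit <- optim(0, fn = function(a) -cox_partial_loglik(a, d1),
               gr = function(a) -cox_gradient(a, d1),
               method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-12))
  alpha <- fit$par
  se <- sqrt(1 / fit$hessian[1, 1])
  p <- 2 * pnorm(-abs(alpha / se))
  attr(p, "alpha") <- alpha
  attr(p, "se") <- se
  p
}

#' Validation deviance of a trained coefficient vector
#'
#' `-2 [l_val(beta_train) - l_val(0)]` on the validation partial
#' likelihood; zero for a null model, negative when the trained
#' coefficients improve the validation likelihood (lower is better).
#'
#' @param beta_train Coefficient vector estimated on training data.
#' @param validation A [survival_dataset()] of validation patients.
#' @return The deviance value.
#' @export
validation_deviance <- function(beta_train, validation) {
  -2 * (cox_partial_loglik(beta_train, validation) -
          cox_partial_loglik(rep(0, validation$p), validation))
}

# Ridge-stabilized Newton fit of an unpenalized Cox model on a gene
# subset; the small ridge keeps near-collinear subsets numerically sane
# and is applied identically to every subset being compared.
cox_subset_fit <- function(data, subset, ridge = 1e-4) {
  sub <- survival_dataset(data$expression[, subset, drop = FALSE],
                          data$times, data$events,
                          gene_ids = data$gene_ids[subset],
                          patient_ids = data$patient_ids)
  p <- sub$p
  fit <- optim(rep(0, p),
               fn = function(b) -cox_partial_loglik(b, sub) +
                 0.5 * ridge * sum(b^2),
               gr = function(b) -cox_gradient(b, sub) + ridge * b,
               method = "BFGS",
               control = list(maxit = 500L, reltol = 1e-12))
  list(beta = fit$par, loglik = cox_partial_loglik(fit$par, sub))
}

#' AIC of the ranking-based gene subset versus random subsets
#'
#' Refits (ridge-stabilized) unpenalized Cox models on (a) the
#' `subset_size` active genes with the largest `|beta|` and (b)
#' `n_random` uniformly sampled subsets of the same size, and returns the
#' fraction of random subsets whose AIC (`-2 loglik + 2 subset_size`)
#' beats the ranked subset.  Small fractions support the coefficient
#' ranking as a cheap stand-in for exhaustive subset search.
#'
#' @param beta Lasso coefficient vector at the chosen penalty.
#' @param data The [survival_dataset()] the model was fitted on.
#' @param subset_size Number of genes per subset (`<= m`).
#' @param n_random Number of random subsets.
#' @param seed Sampling seed.
#' @param ridge Ridge stabilizer applied to every refit.
#' @param zero_tol See [active_set()].
#' @return List with `fraction`, `aic_ranked`, `aic_random`.
#' @export
rank_vs_random_aic <- function(beta, data, subset_size, n_random = 1000L,
                               seed = 1L, ridge = 1e-4,
                               zero_tol = 1e-10) {
  act <- active_set(beta, zero_tol)
  m <- length(act)
  if (subset_size > m)
    stop("subset_size exceeds the number of active genes (", m, ")")
  ranked <- act[order(abs(beta[act]), decreasing = TRUE)][seq_len(subset_size)]
  aic_of <- function(subset)
    -2 * cox_subset_fit(data, subset, ridge)$loglik + 2 * length(subset)
  aic_ranked <- aic_of(ranked)
  aic_random <- with_seed(seed, {
    vapply(seq_len(n_random), function(i)
      aic_of(sort(sample(act, subset_size))), numeric(1))
  })
  list(fraction = mean(aic_random < aic_ranked),
       aic_ranked = aic_ranked, aic_random = aic_random)
}

#' Kaplan-Meier curves per group as a plain table
#'
#' @param times,events Survival outcome vectors.
#' @param groups Grouping factor.
#' @return Data frame with columns `group`, `time`, `n_risk`,
#'   `survival` suitable for TSV export and external plotting.
#' @export
km_curves <- function(times, events, groups) {
  groups <- as.factor(groups)
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  data.frame(group = sub("^groups=", "", strata), time = sf$time,
             n_risk = sf$n.risk, survival = sf$surv)
}

#' Train/validation comparison report for a fitted model
#'
#' Computes the three validation criteria on held-out patients: the
#' log-rank p-value comparing the median-split prognostic groups, the Wald
#' p-value of the prognostic index in a one-covariate Cox model, and the
#' validation deviance.
#'
#' @param beta_train Coefficient vector estimated on the training data.
#' @param validation A [survival_dataset()] of validation patients.
#' @return An object of class `eval_report`.
#' @export
evaluate_model <- function(beta_train, validation) {
  pi <- prognostic_index(beta_train, validation)
  lr <- logrank_test(validation$times, validation$events, pi$group)
  pc <- pi_cox_pvalue(pi$eta, validation)
  structure(list(logrank_p = as.numeric(lr),
                 logrank_chisq = attr(lr, "statistic"),
                 pi_cox_p = as.numeric(pc),
                 alpha = attr(pc, "alpha"), alpha_se = attr(pc, "se"),
                 deviance = validation_deviance(beta_train, validation),
                 median_pi = pi$median,
                 group_sizes = as.list(table(pi$group)),
                 km = km_curves(validation$times, validation$events,
                                pi$group)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n",
      "  log-rank p       = ", signif(x$logrank_p, 4), "\n",
      "  prognostic-index p = ", signif(x$pi_cox_p, 4),
      " (alpha = ", signif(x$alpha, 4), ")\n",
      "  deviance         = ", signif(x$deviance, 6), "\n", sep = "")
  invisible(x)
}
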