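#' Hypothesis proportion vector for one path transition
#'
#' When a gene enters (or leaves) the active set between consecutive path
#' steps, each hypothesis `c` in `0, ..., C` attributes the change to the
#' false-positive component (`c = 0`) or true-positive component `c`.  The
#' hypothesized proportions are the previous integer counts with the
#' chosen component incremented (entry) or decremented (exit), divided by
#' the new active-set size.
#'
#' @param prev Integer count vector `(FP_hat, TP_hat_1, ..., TP_hat_C)`
#'   at the previous step.
#' @param m_next Active-set size at the next step; must differ from
#'   `sum(prev)` by exactly 1.
#' @param hypothesis Component charged with the change, in `0:C`.
#' @return Proportion vector of length `C + 1` summing to 1, or `NULL`
#'   when the hypothesis would decrement a zero count (infeasible).
#' @export
hypothesis_proportions <- function(prev, m_next, hypothesis) {
  prev <- as.integer(prev)
  m_prev <- sum(prev)
  dir <- m_next - m_prev
  if (abs(dir) != 1L)
    stop("m_next must differ from the previous active-set size by 1")
  C <- length(prev) - 1L
  if (hypothesis < 0L || hypothesis > C)
    stop("hypothesis must be in 0:", C)
  counts <- prev
  counts[hypothesis + 1L] <- counts[hypothesis + 1L] + dir
  if (any(counts < 0L)) return(NULL)
  if (m_next == 0L) return(NULL)   # no mixture over an empty active set
  counts / m_next
}

#' Control parameters for the tracking algorithm
#'
#' @param early_rule How to classify changes while the active set is
#'   smaller than `m_min`: `"likelihood"` (default) runs the
#'   fixed-proportion likelihood comparison from the first step, with the
#'   variance/scale floors of [mixture_control()] keeping the constrained
#'   fits well defined; `"tp"` assigns early entrants to component 1;
#'   `"fp"` assigns them to the false-positive count.
#' @param m_min Active-set size below which `early_rule` applies (ignored
#'   for `"likelihood"`).
#' @param mixture See [mixture_control()]; `n_restarts` is not used here
#'   (the hypothesis fits use one deterministic moment start so traces are
#'   reproducible without a seed).
#' @return A named list of control values.
#' @export
tracking_control <- function(early_rule = c("likelihood", "tp", "fp"),
                             m_min = 5L, mixture = mixture_control()) {
  list(early_rule = match.arg(early_rule), m_min = as.integer(m_min),
       mixture = mixture)
}

#' Sequential classification of path changes as true or false positives
#'
#' Walks the solution path step by step.  For every transition the `C + 1`
#' hypothesis proportion vectors are built with
#' [hypothesis_proportions()]; for each feasible hypothesis the mixture is
#' fitted to the active coefficients of the new step with proportions
#' fixed at that hypothesis (only `tau`, `mu`, `sigma` are optimized), and
#' the hypothesis with the largest log-likelihood wins (ties prefer the
#' false-positive component).  Integer counts are updated by one and the
#' running totals satisfy `FP_hat + sum(TP_hat_c) = m` at every step.
#'
#' @param path A [compute_path()] result with at least 2 steps.
#' @param C Number of true-positive mixture components.
#' @param n_over_p Optional `n/p` prefactor recorded with the trace.
#' @param config See [tracking_control()].
#' @return An object of class `tp_trace`: a per-step data frame `states`
#'   with columns `k`, `lambda`, `m`, `FP_hat`, `TP_hat_1..C`, `TP_hat`,
#'   `C_max` and the candidate log-likelihoods, plus `C` and diagnostic
#'   flags.
#' @export
run_tracking <- function(path, C = 1L, n_over_p = 1,
                         config = tracking_control()) {
  stopifnot(inherits(path, "lasso_path"))
  C <- as.integer(C)
  if (C < 1L) stop("C must be at least 1")
  K <- nrow(path$steps) - 1L
  if (K < 1L) stop("path must have at least 2 steps")
  mctl <- config$mixture

  counts <- integer(C + 1L)      # (FP, TP_1, ..., TP_C)
  ll_names <- paste0("L_", 0:C)
  states <- vector("list", K + 1L)
  states[[1L]] <- c(k = 0L, lambda = path$steps$lambda[1L], m = 0L,
                    FP_hat = 0L, setNames(integer(C), paste0("TP_hat_", 1:C)),
                    TP_hat = 0L, C_max = NA_integer_,
                    setNames(rep(NA_real_, C + 1L), ll_names),
                    fallback = 0L)

  for (k in seq_len(K)) {
    m_next <- path$steps$m[k + 1L]
    beta_k <- path$beta[, k + 1L]
    act <- active_set(beta_k, path$zero_tol)
    coeffs <- beta_k[act]
    dir <- m_next - sum(counts)
    if (abs(dir) != 1L)
      stop("path step ", k, " changes the active set by ", dir,
           " genes; tracking requires one change per step")

    lls <- rep(NA_real_, C + 1L)
    feasible <- logical(C + 1L)
    fallback <- FALSE
    forced <- NA_integer_
    if (m_next == 0L) {
      forced <- which(counts > 0L)[1L] - 1L   # empty set: undo the last count
    } else if (config$early_rule != "likelihood" &&
               m_next < config$m_min && dir > 0L) {
      forced <- if (config$early_rule == "tp") 1L else 0L
    }
    if (is.na(forced)) {
      for (h in 0:C) {
        props <- hypothesis_proportions(counts, m_next, h)
        if (is.null(props)) next
        feasible[h + 1L] <- TRUE
        if (m_next >= 1L) {
          fit <- tryCatch(
            mix_em(coeffs, props, FALSE, mix_init(coeffs, C, mctl), mctl),
            error = function(e) NULL)
          if (!is.null(fit) && is.finite(fit$loglik))
            lls[h + 1L] <- fit$loglik
        }
      }
      if (!any(feasible))
        stop("no feasible hypothesis at step ", k,
             " (count invariants violated)")
      if (all(is.na(lls[feasible]))) {
        # mixture fits failed: fail safe towards the false-positive count
        fallback <- TRUE
        cand <- which(feasible) - 1L
        cmax <- cand[1L]
      } else {
        ok <- which(feasible & !is.na(lls))
        best <- max(lls[ok])
        cmax <- min(ok[lls[ok] >= best - 1e-9]) - 1L   # ties prefer c = 0
      }
    } else if (m_next > 0L) {
      cmax <- forced
      if (is.null(hypothesis_proportions(counts, m_next, cmax)))
        cmax <- which(!vapply(0:C, function(h)
          is.null(hypothesis_proportions(counts, m_next, h)),
          logical(1)))[1L] - 1L
    } else {
      cmax <- forced
    }

    counts[cmax + 1L] <- counts[cmax + 1L] + dir
    states[[k + 1L]] <- c(k = k, lambda = path$steps$lambda[k + 1L],
                          m = m_next, FP_hat = counts[1L],
                          setNames(counts[-1L], paste0("TP_hat_", 1:C)),
                          TP_hat = sum(counts[-1L]), C_max = cmax,
                          setNames(lls, ll_names),
                          fallback = as.integer(fallback))
  }

  states <- as.data.frame(do.call(rbind, states))
  structure(list(states = states, C = C, n_over_p = n_over_p,
                 lambda0 = path$lambda0, gene_ids = path$gene_ids),
            class = "tp_trace")
}

#' @export
print.tp_trace <- function(x, ...) {
  s <- x$states
  K <- nrow(s) - 1L
  cat("<tp_trace> ", K, " steps, C = ", x$C, "; final m = ", s$m[K + 1L],
      ", TP_hat = ", s$TP_hat[K + 1L], ", FP_hat = ", s$FP_hat[K + 1L],
      "\n", sep = "")
  invisible(x)
}

#' Penalty value maximizing the estimated true-positive count
#'
#' Returns the path step (and its penalty value) at which the estimated
#' number of true positives is largest; ties are broken towards larger
#' penalty (the sparser model).  The false-positive rate
#' `FP_hat / (TP_hat + FP_hat)` at the optimum is reported alongside, for
#' users who want to trade TP yield against FP contamination.
#'
#' @param trace A [run_tracking()] result.
#' @return List with `lam_star`, `k_star`, `TP_hat`, `FP_hat`, `m`, `fpr`.
#' @export
select_optimal_lambda <- function(trace) {
  stopifnot(inherits(trace, "tp_trace"))
  s <- trace$states
  if (!nrow(s)) stop("empty trace")
  i <- which.max(s$TP_hat)   # first maximum = largest lambda
  fpr <- if (s$m[i] > 0) s$FP_hat[i] / s$m[i] else 0
  list(lam_star = s$lambda[i], k_star = s$k[i], TP_hat = s$TP_hat[i],
       FP_hat = s$FP_hat[i], m = s$m[i], fpr = fpr)
}

#' Identify the putative true-positive genes by coefficient ranking
#'
#' Ranks the active genes by decreasing `|beta_j|` and returns the first
#' `round(TP_hat)` of them, together with the implied magnitude cut-off
#' `zeta` (the midpoint between the last included and first excluded
#' `|beta_j|`).
#'
#' @param beta Coefficient vector at the chosen penalty value.
#' @param TP_hat Estimated number of true positives (`<= m`); rounded half
#'   away from zero.
#' @param gene_ids Gene identifiers (default: names of `beta`).
#' @param zero_tol See [active_set()].
#' @return List with `genes` (ids in rank order), `ranks` (data frame of
#'   all active genes with `|beta|`), `n_tp` and `zeta`.
#' @export
identify_tp_genes <- function(beta, TP_hat, gene_ids = names(beta),
                              zero_tol = 1e-10) {
  act <- active_set(beta, zero_tol)
  m <- length(act)
  if (TP_hat > m + 1e-9) stop("TP_hat exceeds the number of active genes")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(beta))
  r <- floor(abs(TP_hat) + 0.5)          # round half away from zero
  o <- act[order(abs(beta[act]), decreasing = TRUE)]
  mags <- abs(beta[o])
  zeta <- if (r == 0L) {
    if (m > 0) mags[1L] else 0
  } else if (r >= m) {
    mags[m] / 2
  } else {
    (mags[r] + mags[r + 1L]) / 2
  }
  list(genes = gene_ids[o[seq_len(min(r, m))]],
       ranks = data.frame(gene = gene_ids[o], beta = beta[o],
                          abs_beta = mags, row.names = NULL),
       n_tp = min(r, m), raw_TP_hat = TP_hat, zeta = zeta)
}
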