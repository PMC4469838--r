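#' Construct a survival dataset
#'
#' Bundles a gene-expression matrix with right-censored survival outcomes,
#' the unit consumed by every fitting function in the package.
#'
#' @param expression Numeric matrix, `n` patients (rows) by `p` genes
#'   (columns).  No missing values are allowed; the file readers substitute
#'   0.0 for missing cells before construction.
#' @param times Positive event or censoring time per patient.
#' @param events Event indicator per patient: 1 if the survival time was
#'   observed, 0 if censored.
#' @param gene_ids Unique gene identifiers (default: column names or
#'   `g<j>`).
#' @param patient_ids Patient identifiers (default: row names or `s<i>`).
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(expression, times, events,
                             gene_ids = NULL, patient_ids = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  p <- ncol(expression)
  if (n < 2L || p < 1L)
    stop("need at least 2 patients and 1 gene")
  if (anyNA(expression) || !all(is.finite(expression)))
    stop("expression matrix contains missing or non-finite values")
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (length(times) != n || length(events) != n)
    stop("times/events length must equal the number of expression rows")
  if (anyNA(times) || any(times <= 0))
    stop("all survival times must be strictly positive")
  if (!all(events %in% c(0, 1)))
    stop("events must be 0 (censored) or 1 (observed)")
  if (is.null(gene_ids)) gene_ids <- colnames(expression)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p) stop("gene_ids length must equal p")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (is.null(patient_ids)) patient_ids <- rownames(expression)
  if (is.null(patient_ids)) patient_ids <- sprintf("s%04d", seq_len(n))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != n) stop("patient_ids length must equal n")
  dimnames(expression) <- list(patient_ids, gene_ids)
  structure(list(expression = expression, times = times, events = events,
                 gene_ids = gene_ids, patient_ids = patient_ids,
                 n = n, p = p),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> ", x$n, " patients x ", x$p, " genes; ",
      sum(x$events), " events (", round(100 * mean(x$events), 1),
      "%)\n", sep = "")
  invisible(x)
}

#' Subset a survival dataset by patients
#' @param data A `survival_dataset`.
#' @param idx Patient indices (or logical vector) to keep.
#' @return A `survival_dataset` restricted to the selected patients.
#' @export
subset_patients <- function(data, idx) {
  survival_dataset(data$expression[idx, , drop = FALSE],
                   data$times[idx], data$events[idx],
                   gene_ids = data$gene_ids,
                   patient_ids = data$patient_ids[idx])
}

# Sorted representation for the partial-likelihood kernels: patients ordered
# by increasing time, tie groups marked by the 0-based index of their first
# member (Breslow risk sets).
cox_prep <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  ord <- order(data$times)
  t_sorted <- data$times[ord]
  first <- match(t_sorted, t_sorted)  # first index of each tie group
  list(X = data$expression[ord, , drop = FALSE],
       delta = as.integer(data$events[ord]),
       grp = as.integer(first - 1L),
       ord = ord)
}
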