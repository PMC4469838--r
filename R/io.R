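delim_of <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

missing_tokens <- c("", "NA", "NaN", "nan", "na", "N/A")

#' Read a gene-expression matrix from delimited text
#'
#' Reads a TSV or CSV file (auto-detected by extension) with one header
#' row and one id column.  Missing cells (empty, `NA`, `NaN`) are replaced
#' by 0.0 and the substitution count is reported; any other non-numeric
#' cell is an error naming its location.
#'
#' @param path File path.
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the matrix is transposed on
#'   load).
#' @return Numeric samples-by-genes matrix with id dimnames and attribute
#'   `n_imputed`.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- read.delim(path, sep = delim_of(path), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[] <- trimws(cells)
  is_missing <- is.na(cells) | cells %in% missing_tokens
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !is_missing)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(cells))
    stop("non-numeric cell in ", path, " at row ", rc[1L], " (id ",
         ids[rc[1L]], "), column ", colnames(cells)[rc[2L]], ": '",
         cells[bad[1L]], "'")
  }
  n_imputed <- sum(is_missing)
  vals[is.na(vals)] <- 0.0
  mat <- matrix(vals, nrow(cells), ncol(cells),
                dimnames = list(ids, colnames(cells)))
  if (orientation == "genes_by_samples") mat <- t(mat)
  if (n_imputed > 0)
    message("read_expression: substituted 0.0 for ", n_imputed,
            " missing cells")
  attr(mat, "n_imputed") <- n_imputed
  mat
}

#' Read a survival table from delimited text
#'
#' Expects columns `id`, `time`, `event` (case-insensitive).
#'
#' @param path File path (TSV or CSV by extension).
#' @return Data frame with columns `id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  raw <- read.delim(path, sep = delim_of(path), header = TRUE,
                    check.names = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("id", "time", "event")
  if (!all(need %in% names(raw)))
    stop("survival file must have columns id, time, event; found: ",
         paste(names(raw), collapse = ", "))
  out <- raw[, need]
  out$id <- trimws(as.character(out$id))
  out$time <- as.numeric(out$time)
  out$event <- as.numeric(out$event)
  bad_t <- which(!is.finite(out$time) | out$time <= 0)
  if (length(bad_t))
    stop("nonpositive or missing time at row ", bad_t[1L], " (id ",
         out$id[bad_t[1L]], ")")
  bad_e <- which(!out$event %in% c(0, 1))
  if (length(bad_e))
    stop("event must be 0 or 1 at row ", bad_e[1L], " (id ",
         out$id[bad_e[1L]], ")")
  out
}

#' Read and align an expression matrix and survival table
#'
#' @param expression_path,survival_path File paths.
#' @param orientation See [read_expression()].
#' @return A [survival_dataset()] with survival rows aligned to the
#'   expression sample order by id.
#' @export
read_survival_dataset <- function(expression_path, survival_path,
                                  orientation = "samples_by_genes") {
  mat <- read_expression(expression_path, orientation)
  surv <- read_survival(survival_path)
  samples <- rownames(mat)
  extra <- setdiff(surv$id, samples)
  if (length(extra))
    stop("survival ids not present in the expression matrix: ",
         paste(extra, collapse = ", "))
  missing <- setdiff(samples, surv$id)
  if (length(missing))
    stop("expression samples without survival rows: ",
         paste(missing, collapse = ", "))
  surv <- surv[match(samples, surv$id), ]
  survival_dataset(mat, surv$time, surv$event,
                   gene_ids = colnames(mat), patient_ids = samples)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", signif(x, 6))

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a solution path
#'
#' Writes a long-format TSV (`k`, `lambda`, `gene_id`, `beta`, nonzero
#' coefficients only) and a JSON summary (lambda0, terminal lambda,
#' per-step sizes and change events, KKT diagnostics).
#'
#' @param path A [compute_path()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
export_path <- function(path, dir, prefix = "path") {
  stopifnot(inherits(path, "lasso_path"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nrow(path$steps)), function(i) {
    act <- active_set(path$beta[, i], path$zero_tol)
    if (!length(act)) return(NULL)
    data.frame(k = path$steps$k[i], lambda = path$steps$lambda[i],
               gene_id = path$gene_ids[act], beta = path$beta[act, i])
  }))
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  write_tsv(rows, tsv)
  json <- file.path(dir, paste0(prefix, ".json"))
  summary <- list(
    lambda0 = path$lambda0, lambda_min = path$lambda_min,
    zero_tol = path$zero_tol, n_steps = nrow(path$steps) - 1L,
    steps = path$steps[, c("k", "lambda", "m")],
    changes = data.frame(k = path$steps$k,
                         gene = ifelse(is.na(path$steps$change_gene), NA,
                                       path$gene_ids[path$steps$change_gene]),
                         direction = path$steps$change_dir),
    diagnostics = path$diagnostics)
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(c(tsv = tsv, json = json))
}

#' Export a tracking trace
#'
#' Writes the per-step trace as TSV and a JSON report with the optimal
#' penalty, the ranked putative true-positive genes, the implied magnitude
#' cut-off and the false-positive rate at the optimum.
#'
#' @param trace A [run_tracking()] result.
#' @param path The [compute_path()] result it was computed from.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
export_trace <- function(trace, path, dir, prefix = "trace") {
  stopifnot(inherits(trace, "tp_trace"), inherits(path, "lasso_path"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  write_tsv(trace$states, tsv)
  opt <- select_optimal_lambda(trace)
  beta_star <- path$beta[, which(path$steps$k == opt$k_star)[1L]]
  tp <- identify_tp_genes(beta_star, opt$TP_hat, path$gene_ids,
                          path$zero_tol)
  json <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(lam_star = opt$lam_star, k_star = opt$k_star,
         TP_hat = opt$TP_hat, FP_hat = opt$FP_hat, m = opt$m,
         fpr = opt$fpr, zeta = tp$zeta, tp_genes = tp$genes,
         ranks = tp$ranks),
    json, auto_unbox = TRUE, digits = NA, na = "null",
    dataframe = "columns")
  invisible(c(tsv = tsv, json = json))
}

#' Write a simulation summary table as TSV
#'
#' @param sim A [run_simulation()] result.
#' @param file Output file.
#' @return Invisibly, the file path.
#' @export
write_sim_table <- function(sim, file) {
  stopifnot(inherits(sim, "sim_table"))
  write_tsv(sim$table, file)
  invisible(file)
}

#' Write a run manifest
#'
#' Records the command, configuration, seeds, package version and
#' timestamp needed to rerun an analysis.
#'
#' @param dir Output directory.
#' @param command Subcommand or description.
#' @param config Named list of configuration values.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command, config = config,
    package = "lassotp",
    version = as.character(utils::packageVersion("lassotp")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
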