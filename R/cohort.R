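#' Case-control cohort matrix
#'
#' Container for a binary patient x comorbidity indicator matrix together
#' with a per-patient case/control outcome label. This is the universal input
#' of every analysis stage: rows are patients, columns are comorbidity
#' indicators (1 = comorbidity present), and `outcome` is 1 for cases
#' (readmitted within 30 days) and 0 for matched controls.
#'
#' @param X binary matrix (patients x comorbidities) with distinct column
#'   names; entries must be 0/1.
#' @param outcome integer/numeric vector of 0/1 labels, one per row of `X`.
#' @param patient_ids character vector of distinct patient identifiers;
#'   defaults to the rownames of `X` or `P<row>` when absent.
#' @return An object of class `cohort_matrix`: a list with elements
#'   `patient_ids`, `outcome` (integer 0/1) and `X` (integer matrix with
#'   `patient_ids` as rownames).
#' @export
cohort_matrix <- function(X, outcome, patient_ids = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)) > 0L) {
    stop("comorbidity columns must carry distinct names", call. = FALSE)
  }
  bad <- which(!(X %in% c(0, 1)))
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1L], dim(X))
    stop(sprintf("non-binary indicator value %s at row %d, column '%s'",
                 format(X[bad[1L]]), i[1L], colnames(X)[i[2L]]), call. = FALSE)
  }
  if (length(outcome) != nrow(X)) {
    stop("outcome length must equal the number of patients", call. = FALSE)
  }
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome labels must be 0 (control) or 1 (case)", call. = FALSE)
  }
  if (is.null(patient_ids)) {
    patient_ids <- rownames(X)
    if (is.null(patient_ids)) patient_ids <- sprintf("P%06d", seq_len(nrow(X)))
  }
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(X) || anyDuplicated(patient_ids) > 0L) {
    stop("patient_ids must be distinct, one per row", call. = FALSE)
  }
  storage.mode(X) <- "integer"
  rownames(X) <- patient_ids
  structure(
    list(patient_ids = patient_ids, outcome = as.integer(outcome), X = X),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d patients (%d cases / %d controls), %d comorbidities\n",
              n_patients(x), sum(x$outcome == 1L), sum(x$outcome == 0L),
              ncol(x$X)))
  invisible(x)
}

#' @rdname cohort_matrix
#' @param cohort a `cohort_matrix`.
#' @export
n_patients <- function(cohort) length(cohort$patient_ids)

#' @rdname cohort_matrix
#' @export
comorbidity_names <- function(cohort) colnames(cohort$X)

#' Subset a cohort by patients and/or comorbidity columns
#'
#' @param cohort a `cohort_matrix`.
#' @param patients logical/integer/character index over patients.
#' @param comorbidities logical/integer/character index over columns.
#' @return A `cohort_matrix` restricted to the selected rows/columns.
#' @export
subset_cohort <- function(cohort, patients = NULL, comorbidities = NULL) {
  X <- cohort$X
  out <- cohort$outcome
  ids <- cohort$patient_ids
  if (!is.null(patients)) {
    X <- X[patients, , drop = FALSE]
    out <- out[patients]
    ids <- ids[patients]
  }
  if (!is.null(comorbidities)) X <- X[, comorbidities, drop = FALSE]
  cohort_matrix(X, out, ids)
}

#' Write a cohort to CSV
#'
#' Writes the standard exchange format: one header row
#' `patient_id,outcome,<comorbidity...>`, UTF-8, no index column.
#'
#' @param cohort a `cohort_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(patient_id = cohort$patient_ids,
                   outcome = cohort$outcome,
                   cohort$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]: validates the header, the 0/1 indicator
#' entries and patient-id uniqueness, and reports the offending row/column on
#' failure. `read_cohort(write_cohort(c))` reproduces `c` exactly.
#'
#' @param path CSV file as written by [write_cohort()].
#' @return A `cohort_matrix`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) character())
  if (length(first) == 0L || !nzchar(trimws(first))) {
    stop("no header: file is empty", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("patient_id", "outcome"))) {
    stop("missing header: expected columns 'patient_id,outcome,<comorbidity...>'",
         call. = FALSE)
  }
  if (anyDuplicated(df$patient_id) > 0L) {
    dup <- df$patient_id[duplicated(df$patient_id)][1L]
    stop(sprintf("duplicated patient_id '%s'", dup), call. = FALSE)
  }
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  bad <- which(!(X %in% c(0, 1)))
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1L], dim(X))
    stop(sprintf("non-binary indicator value '%s' at row %d, column '%s'",
                 format(X[bad[1L]]), i[1L], colnames(X)[i[2L]]), call. = FALSE)
  }
  cohort_matrix(X, df$outcome, df$patient_id)
}

#' Summarize a cohort
#'
#' @param cohort a `cohort_matrix`.
#' @return A list with `n_patients`, `n_cases`, `n_controls`, `prevalence`
#'   (named per-comorbidity fraction of patients carrying it),
#'   `median_comorbidities` (NA with `median_defined = FALSE` on an empty
#'   cohort).
#' @export
cohort_summary <- function(cohort) {
  n <- n_patients(cohort)
  if (n == 0L) {
    prev <- rep(NA_real_, ncol(cohort$X))
    names(prev) <- comorbidity_names(cohort)
    return(list(n_patients = 0L, n_cases = 0L, n_controls = 0L,
                prevalence = prev,
                median_comorbidities = NA_real_, median_defined = FALSE))
  }
  counts <- rowSums(cohort$X)
  list(n_patients = n,
       n_cases = sum(cohort$outcome == 1L),
       n_controls = sum(cohort$outcome == 0L),
       prevalence = colMeans(cohort$X),
       median_comorbidities = stats::median(counts),
       median_defined = TRUE)
}
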