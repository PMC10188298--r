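# Property datasets: SMILES with (possibly missing) task labels.

#' Construct a property dataset
#'
#' Holds `n` molecules with an `n x T` label matrix and an observation
#' mask; missing labels are carried in the mask, never imputed.
#' Classification labels must be 0/1 wherever observed; regression labels
#' must be finite wherever observed.
#'
#' @param smiles Character vector of SMILES strings.
#' @param labels Numeric `n x T` matrix (or vector for one task); `NA`
#'   entries are treated as unobserved.
#' @param task_type `"classification"` or `"regression"`.
#' @param observed Optional logical `n x T` mask; defaults to
#'   `!is.na(labels)`.
#' @return An object of class `claps_dataset` with elements `smiles`,
#'   `labels`, `observed`, `task_type`.
#' @export
property_dataset <- function(smiles, labels,
                             task_type = c("classification", "regression"),
                             observed = NULL) {
  task_type <- match.arg(task_type)
  if (!is.matrix(labels)) labels <- matrix(labels, ncol = 1L)
  storage.mode(labels) <- "double"
  if (length(smiles) != nrow(labels)) {
    stop("property_dataset: labels must have one row per molecule")
  }
  if (is.null(observed)) observed <- !is.na(labels)
  if (!identical(dim(observed), dim(labels))) {
    stop("property_dataset: observed mask shape mismatch")
  }
  obs_vals <- labels[observed]
  if (task_type == "classification" && !all(obs_vals %in% c(0, 1))) {
    stop("property_dataset: observed classification labels must be 0 or 1")
  }
  if (task_type == "regression" && any(!is.finite(obs_vals))) {
    stop("property_dataset: observed regression labels must be finite")
  }
  structure(list(smiles = smiles, labels = labels, observed = observed,
                 task_type = task_type),
            class = "claps_dataset")
}

#' @export
print.claps_dataset <- function(x, ...) {
  cat(sprintf("<claps_dataset> %d molecules, %d %s task%s (%.1f%% labels observed)\n",
              length(x$smiles), ncol(x$labels), x$task_type,
              if (ncol(x$labels) > 1) "s" else "",
              100 * mean(x$observed)))
  invisible(x)
}

#' @export
length.claps_dataset <- function(x) length(x$smiles)

#' Subset a property dataset by molecule indices
#'
#' @param ds A `claps_dataset`.
#' @param idx Integer indices.
#' @return A `claps_dataset` restricted to `idx`.
#' @export
dataset_subset <- function(ds, idx) {
  property_dataset(ds$smiles[idx], ds$labels[idx, , drop = FALSE],
                   task_type = ds$task_type,
                   observed = ds$observed[idx, , drop = FALSE])
}

#' Read a property dataset from CSV
#'
#' Expects a header row, one SMILES column and one or more label columns
#' (the MoleculeNet-style layout).  Blank or `NA` label cells become
#' unobserved entries; rows whose SMILES do not parse are dropped with a
#' logged count.
#'
#' @param path CSV file path.
#' @param smiles_column Name of the SMILES column (default `"smiles"`).
#' @param label_columns Character vector of label column names; default:
#'   every column except the SMILES column.
#' @param task_type `"classification"` or `"regression"`.
#' @return A `claps_dataset`.
#' @export
read_property_csv <- function(path, smiles_column = "smiles",
                              label_columns = NULL,
                              task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop(sprintf("read_property_csv: no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!smiles_column %in% names(df)) {
    stop(sprintf("read_property_csv: missing SMILES column '%s'", smiles_column))
  }
  if (is.null(label_columns)) {
    label_columns <- setdiff(names(df), smiles_column)
  }
  missing_cols <- setdiff(label_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("read_property_csv: missing label column%s: %s",
                 if (length(missing_cols) > 1) "s" else "",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!length(label_columns)) stop("read_property_csv: no label columns")
  smiles <- as.character(df[[smiles_column]])
  labels <- as.matrix(data.frame(lapply(df[label_columns], function(col) {
    if (is.character(col)) col[!nzchar(trimws(col))] <- NA
    suppressWarnings(as.numeric(col))
  }), check.names = FALSE))
  colnames(labels) <- label_columns
  ok <- is_valid_smiles(smiles)
  if (any(!ok)) {
    message(sprintf("read_property_csv: dropped %d of %d rows with unparsable SMILES",
                    sum(!ok), length(ok)))
  }
  property_dataset(smiles[ok], labels[ok, , drop = FALSE], task_type = task_type)
}
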