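#' Construct a QSAR dataset
#'
#' A `qsar_dataset` bundles a chemicals-by-descriptors numeric matrix with
#' chemical identifiers, optional 0/1 activity labels (1 = binder,
#' 0 = non-binder) and the min-max scaling state of the descriptor values.
#'
#' @param descriptors numeric matrix, one row per chemical, one column per
#'   descriptor; column names are the descriptor names.
#' @param chemical_ids character vector of unique chemical identifiers, one
#'   per row.
#' @param labels optional integer vector of 0/1 activity labels aligned with
#'   `chemical_ids`; `NULL` for prediction-only data.
#' @param scaling `NULL` while the values are raw, or the per-descriptor
#'   min/max table (as returned by [fit_minmax_scaling()]) that was applied.
#' @return An object of class `qsar_dataset` with elements `chemical_ids`,
#'   `descriptors`, `labels` and `scaling`.
#' @examples
#' X <- matrix(c(1, 2, 3, 4), 2, dimnames = list(NULL, c("D1", "D2")))
#' qsar_dataset(X, c("a", "b"), labels = c(1L, 0L))
#' @export
qsar_dataset <- function(descriptors, chemical_ids, labels = NULL,
                         scaling = NULL) {
  descriptors <- as.matrix(descriptors)
  storage.mode(descriptors) <- "double"
  chemical_ids <- as.character(chemical_ids)
  if (nrow(descriptors) != length(chemical_ids))
    stop("number of rows (", nrow(descriptors),
         ") does not match number of chemical ids (", length(chemical_ids), ")")
  dup <- unique(chemical_ids[duplicated(chemical_ids)])
  if (length(dup))
    stop("duplicate chemical ids: ", paste(dup, collapse = ", "))
  if (is.null(colnames(descriptors)))
    stop("descriptor matrix must have column names")
  if (anyDuplicated(colnames(descriptors)))
    stop("duplicate descriptor names")
  if (anyNA(descriptors))
    stop("missing descriptor values are not allowed; clean the table first")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(chemical_ids))
      stop("labels must align one-to-one with chemical ids")
    if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
      stop("labels must take only the values 0 and 1")
  }
  rownames(descriptors) <- chemical_ids
  structure(list(chemical_ids = chemical_ids, descriptors = descriptors,
                 labels = labels, scaling = scaling),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("qsar_dataset:", nrow(x$descriptors), "chemicals x",
      ncol(x$descriptors), "descriptors;",
      if (is.null(x$scaling)) "raw" else "min-max scaled", "values;",
      if (is.null(x$labels)) "unlabeled"
      else paste0(sum(x$labels == 1L), " binders / ",
                  sum(x$labels == 0L), " non-binders"), "\n")
  invisible(x)
}

#' @export
dim.qsar_dataset <- function(x) dim(x$descriptors)

#' Read a descriptor table from CSV/TSV
#'
#' Reads a delimited text table whose rows are chemicals: one identifier
#' column, numeric molecular-descriptor columns (e.g. Mold2 output exported
#' as CSV) and optionally a 0/1 activity-label column. Structure files (SDF)
#' are not parsed here; compute descriptors with an external tool such as
#' Mold2 and export the numeric table.
#'
#' @param path path to the delimited file (header row required, `.` decimal
#'   separator).
#' @param label_column name of the 0/1 label column, or `NULL` when the table
#'   carries no activity data.
#' @param id_column name of the chemical-identifier column; default is the
#'   first column.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return A [qsar_dataset()] with `scaling = NULL` (raw values), preserving
#'   the file's row order.
#' @export
read_descriptor_table <- function(path, label_column = NULL, id_column = NULL,
                                  sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("table must have an id column and >=1 descriptor")
  if (is.null(id_column)) id_column <- names(tab)[1]
  if (!id_column %in% names(tab)) stop("id column not found: ", id_column)
  ids <- as.character(tab[[id_column]])
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(tab))
      stop("label column not found: ", label_column)
    raw <- tab[[label_column]]
    if (!all(raw %in% c(0, 1)))
      stop("label column '", label_column, "' contains values outside {0, 1}")
    labels <- as.integer(raw)
  }
  desc_cols <- setdiff(names(tab), c(id_column, label_column))
  X <- as.matrix(tab[desc_cols])
  if (!is.numeric(X)) {
    bad <- desc_cols[!vapply(tab[desc_cols], is.numeric, logical(1))]
    for (cn in bad) {
      row <- which(is.na(suppressWarnings(as.numeric(tab[[cn]]))))[1]
      stop("non-numeric descriptor value at row ", row, ", column '", cn, "'")
    }
  }
  if (anyNA(X)) {
    w <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing descriptor value at row ", w[1], ", column '",
         desc_cols[w[2]], "'")
  }
  qsar_dataset(X, ids, labels = labels)
}

#' Write a dataset to CSV/TSV
#'
#' Inverse of [read_descriptor_table()]: writes the identifier column,
#' descriptor columns and (when present) the label column.
#'
#' @param data a [qsar_dataset()].
#' @param path output file path.
#' @param label_column name for the label column when labels are present.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path, label_column = "activity",
                                   sep = ",") {
  stopifnot(inherits(data, "qsar_dataset"))
  out <- data.frame(id = data$chemical_ids, data$descriptors,
                    check.names = FALSE, row.names = NULL)
  if (!is.null(data$labels)) out[[label_column]] <- data$labels
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove constant descriptor columns
#'
#' Drops every descriptor whose value is identical across all chemicals, the
#' standard cleanup step before min-max scaling (a constant column carries no
#' class information and has an undefined scaling range).
#'
#' @param data a [qsar_dataset()] with at least one chemical.
#' @return The filtered dataset; the character vector of removed descriptor
#'   names is attached as attribute `"removed"`. Surviving column order is
#'   preserved.
#' @export
remove_constant_descriptors <- function(data) {
  stopifnot(inherits(data, "qsar_dataset"))
  if (nrow(data$descriptors) < 1) stop("dataset has no chemicals")
  rng <- apply(data$descriptors, 2, function(v) max(v) - min(v))
  constant <- rng == 0
  if (all(constant)) stop("no variable descriptors remain")
  removed <- colnames(data$descriptors)[constant]
  out <- qsar_dataset(data$descriptors[, !constant, drop = FALSE],
                      data$chemical_ids, labels = data$labels,
                      scaling = data$scaling)
  attr(out, "removed") <- removed
  out
}

#' Fit per-descriptor min-max scaling parameters
#'
#' @param data a [qsar_dataset()] without constant columns (run
#'   [remove_constant_descriptors()] first).
#' @return A data frame with columns `descriptor`, `min`, `max` — the scaling
#'   parameters mapping each training-set column onto \[0, 1\].
#' @export
fit_minmax_scaling <- function(data) {
  stopifnot(inherits(data, "qsar_dataset"))
  mins <- apply(data$descriptors, 2, min)
  maxs <- apply(data$descriptors, 2, max)
  if (any(mins == maxs))
    stop("constant descriptor(s) present: ",
         paste(colnames(data$descriptors)[mins == maxs], collapse = ", "))
  data.frame(descriptor = colnames(data$descriptors), min = unname(mins),
             max = unname(maxs), stringsAsFactors = FALSE)
}

#' Apply min-max scaling parameters
#'
#' Maps each value v to (v - min) / (max - min) using parameters fitted on
#' the training set. Chemicals outside the training range map outside
#' \[0, 1\]; they are deliberately not clipped — the trees split on
#' thresholds, so the monotone linear extrapolation is harmless and avoids an
#' undocumented transformation.
#'
#' @param data a [qsar_dataset()] whose descriptors are all covered by
#'   `params`.
#' @param params scaling parameters from [fit_minmax_scaling()].
#' @return The scaled dataset with `scaling = params` recorded.
#' @export
apply_minmax_scaling <- function(data, params) {
  stopifnot(inherits(data, "qsar_dataset"))
  nms <- colnames(data$descriptors)
  missing <- setdiff(nms, params$descriptor)
  if (length(missing))
    stop("no scaling parameters for descriptor(s): ",
         paste(missing, collapse = ", "))
  idx <- match(nms, params$descriptor)
  mins <- params$min[idx]
  maxs <- params$max[idx]
  X <- sweep(sweep(data$descriptors, 2, mins, "-"), 2, maxs - mins, "/")
  qsar_dataset(X, data$chemical_ids, labels = data$labels, scaling = params)
}

#' Preprocess a training dataset
#'
#' Convenience pipeline: remove constant descriptors, fit min-max scaling on
#' the remaining columns and apply it. Preprocessing is fitted on the data
#' given (normally the training set only); reuse the returned `scaling` table
#' via [apply_minmax_scaling()] to transform external chemicals without
#' leaking their ranges into the parameters.
#'
#' @param data a raw [qsar_dataset()].
#' @return The cleaned, scaled dataset (attributes `"removed"` and element
#'   `scaling` record what was done).
#' @export
preprocess_dataset <- function(data) {
  cleaned <- remove_constant_descriptors(data)
  params <- fit_minmax_scaling(cleaned)
  out <- apply_minmax_scaling(cleaned, params)
  attr(out, "removed") <- attr(cleaned, "removed")
  out
}
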