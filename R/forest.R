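#' Fit a Decision Forest
#'
#' A Decision Forest is a consensus of several classification trees that is
#' forced to be heterogeneous: tree 1 is grown and pruned on the full
#' descriptor pool, and each subsequent tree on the pool minus every
#' descriptor already used by earlier trees, so the trees' descriptor sets
#' are pairwise disjoint. Fitting stops early when the pool is exhausted or
#' when the next tree degenerates to a bare leaf (a constant tree would only
#' dilute the consensus). The whole procedure is deterministic for a fixed
#' input.
#'
#' @param data a labeled, preprocessed [qsar_dataset()] (see
#'   [preprocess_dataset()]).
#' @param n_trees maximum number of trees (default 5).
#' @param control a [df_tree_control()].
#' @return An object of class `df_forest`: `trees` (list of `df_tree`),
#'   `used_descriptors_per_tree`, `scaling` (copied from `data`), `n_trees`
#'   requested and `control`.
#' @export
df_fit <- function(data, n_trees = 5L, control = df_tree_control()) {
  stopifnot(inherits(data, "qsar_dataset"))
  if (is.null(data$labels)) stop("forest fitting requires labeled data")
  if (nrow(data$descriptors) < control$min_split_size)
    stop("fewer chemicals than min_split_size")
  pool <- colnames(data$descriptors)
  trees <- list()
  for (k in seq_len(n_trees)) {
    if (length(pool) == 0) break
    tr <- df_tree_fit(data, candidate_descriptors = pool, control = control)
    if (length(tr$used_descriptors) == 0) break  # bare leaf: stop
    trees[[k]] <- tr
    pool <- setdiff(pool, tr$used_descriptors)
  }
  if (length(trees) == 0) stop("no tree could be grown on this data")
  structure(list(trees = trees,
                 used_descriptors_per_tree =
                   lapply(trees, `[[`, "used_descriptors"),
                 scaling = data$scaling,
                 n_trees = as.integer(n_trees),
                 control = control),
            class = "df_forest")
}

#' @export
print.df_forest <- function(x, ...) {
  cat("df_forest:", length(x$trees), "heterogeneous trees;",
      length(unlist(x$used_descriptors_per_tree)), "descriptors used\n")
  invisible(x)
}

#' Prediction confidence from a consensus probability
#'
#' `|p - 0.5| / 0.5`: 0 at the decision boundary, 1 for a unanimous
#' prediction; symmetric in `p` and `1 - p`.
#'
#' @param p consensus probability/probabilities in \[0, 1\].
#' @return Confidence value(s) in \[0, 1\].
#' @export
confidence_of <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  abs(p - 0.5) / 0.5
}

#' Predict with a Decision Forest
#'
#' The consensus probability `p` is the unweighted arithmetic mean of the
#' trees' leaf binder proportions (or of their hard 0/1 leaf classes with
#' `vote = "hard"`); a chemical is called a binder when `p >= 0.5`, and each
#' prediction carries the confidence `|p - 0.5| / 0.5`.
#'
#' Input must be on the scale the forest was trained on: a raw
#' `qsar_dataset` is rejected when the forest carries scaling parameters —
#' use [df_predict()] to scale and predict in one step.
#'
#' @param object a fitted `df_forest`.
#' @param newdata a [qsar_dataset()] or numeric matrix with all used
#'   descriptors.
#' @param vote `"proportion"` (default) averages leaf class proportions,
#'   `"hard"` averages the leaves' 0/1 class labels.
#' @param ... unused.
#' @return A data frame with columns `chemical_id`, `p`, `call`,
#'   `confidence`.
#' @export
predict.df_forest <- function(object, newdata, vote = c("proportion", "hard"),
                              ...) {
  vote <- match.arg(vote)
  if (inherits(newdata, "qsar_dataset")) {
    if (!is.null(object$scaling) && is.null(newdata$scaling))
      stop("descriptor values are raw but the forest expects min-max scaled ",
           "input; use df_predict() or apply_minmax_scaling() first")
    ids <- newdata$chemical_ids
  } else {
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  }
  per_tree <- vapply(object$trees, function(tr) {
    pb <- predict(tr, newdata)
    if (vote == "hard") as.numeric(pb >= 0.5) else pb
  }, numeric(if (inherits(newdata, "qsar_dataset")) nrow(newdata$descriptors)
             else nrow(newdata)))
  per_tree <- matrix(per_tree, ncol = length(object$trees))
  p <- rowMeans(per_tree)
  data.frame(chemical_id = ids, p = p, call = as.integer(p >= 0.5),
             confidence = confidence_of(p), stringsAsFactors = FALSE)
}

#' Train on raw data and predict raw external chemicals
#'
#' [df_train()] runs the preprocessing pipeline (constant-column removal,
#' min-max scaling fitted on the training chemicals only) and fits the
#' forest; [df_predict()] applies the forest's stored scaling to raw external
#' chemicals before predicting, without clipping values that fall outside the
#' training range.
#'
#' @param data a raw labeled [qsar_dataset()].
#' @param n_trees,control forwarded to [df_fit()].
#' @return `df_train()`: a `df_forest` carrying the fitted scaling
#'   parameters.
#' @export
df_train <- function(data, n_trees = 5L, control = df_tree_control()) {
  df_fit(preprocess_dataset(data), n_trees = n_trees, control = control)
}

#' @rdname df_train
#' @param forest a forest from [df_train()].
#' @param newdata a raw or already-scaled [qsar_dataset()].
#' @param ... forwarded to [predict.df_forest()].
#' @return `df_predict()`: the prediction data frame of
#'   [predict.df_forest()].
#' @export
df_predict <- function(forest, newdata, ...) {
  stopifnot(inherits(forest, "df_forest"), inherits(newdata, "qsar_dataset"))
  if (is.null(newdata$scaling) && !is.null(forest$scaling)) {
    keep <- intersect(colnames(newdata$descriptors),
                      forest$scaling$descriptor)
    needed <- unique(unlist(forest$used_descriptors_per_tree))
    missing <- setdiff(needed, keep)
    if (length(missing))
      stop("missing descriptor: ", paste(missing, collapse = ", "))
    newdata <- qsar_dataset(newdata$descriptors[, keep, drop = FALSE],
                            newdata$chemical_ids, labels = newdata$labels)
    newdata <- apply_minmax_scaling(newdata, forest$scaling)
  }
  predict(forest, newdata, ...)
}

node_to_list <- function(node) {
  if (node$kind == "leaf")
    return(list(kind = "leaf", n_binders = node$n_binders,
                n_nonbinders = node$n_nonbinders))
  list(kind = "split", descriptor = node$descriptor,
       threshold = node$threshold, n_binders = node$n_binders,
       n_nonbinders = node$n_nonbinders,
       left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(lst) {
  if (lst$kind == "leaf") return(new_leaf(lst$n_binders, lst$n_nonbinders))
  list(kind = "split", descriptor = lst$descriptor,
       threshold = lst$threshold, n_binders = lst$n_binders,
       n_nonbinders = lst$n_nonbinders,
       left = node_from_list(lst$left), right = node_from_list(lst$right))
}

#' Serialize / restore a Decision Forest as JSON
#'
#' The model file is a versioned JSON bundle holding the control parameters,
#' the min-max scaling table and the nested tree nodes, so a trained model
#' can be archived or shipped and reloaded elsewhere.
#'
#' @param forest a `df_forest`.
#' @param path file path for the JSON bundle.
#' @return `df_write_model()` returns `path` invisibly; `df_read_model()`
#'   returns the restored `df_forest`.
#' @export
df_write_model <- function(forest, path) {
  stopifnot(inherits(forest, "df_forest"))
  bundle <- list(
    format = "dfqsar-model", version = 1L,
    n_trees = forest$n_trees,
    control = unclass(forest$control),
    scaling = if (is.null(forest$scaling)) NULL else
      list(descriptor = forest$scaling$descriptor,
           min = forest$scaling$min, max = forest$scaling$max),
    trees = lapply(forest$trees, function(tr) node_to_list(tr$root)))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname df_write_model
#' @export
df_read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  bundle <- jsonlite::read_json(path)
  if (is.null(bundle$format) || bundle$format != "dfqsar-model")
    stop("not a dfqsar model file: ", path)
  control <- do.call(df_tree_control, bundle$control)
  trees <- lapply(bundle$trees, function(lst) {
    root <- node_from_list(lst)
    structure(list(root = root, used_descriptors = node_descriptors(root),
                   training_misclassified = node_misclassified(root),
                   n_leaves = (node_count(root) + 1L) %/% 2L,
                   control = control),
              class = "df_tree")
  })
  scaling <- if (is.null(bundle$scaling)) NULL else
    data.frame(descriptor = vapply(bundle$scaling$descriptor,
                                   as.character, character(1)),
               min = vapply(bundle$scaling$min, as.numeric, numeric(1)),
               max = vapply(bundle$scaling$max, as.numeric, numeric(1)),
               stringsAsFactors = FALSE)
  structure(list(trees = trees,
                 used_descriptors_per_tree =
                   lapply(trees, `[[`, "used_descriptors"),
                 scaling = scaling,
                 n_trees = as.integer(bundle$n_trees),
                 control = control),
            class = "df_forest")
}
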