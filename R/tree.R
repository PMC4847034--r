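#' Tree-growing control parameters
#'
#' Defaults reproduce the standard Decision Forest parameterisation for this
#' endpoint: minimum node size to split 10, at most 3 levels pruned from the
#' bottom of the tree, Gini's diversity index as the split criterion.
#'
#' @param min_split_size smallest node (training chemicals) eligible for
#'   splitting.
#' @param max_prune_levels pruning may collapse subtrees whose height is at
#'   most this many levels; 0 disables pruning.
#' @param split_criterion only `"gini"` is implemented.
#' @return A list of class `df_tree_control`.
#' @export
df_tree_control <- function(min_split_size = 10L, max_prune_levels = 3L,
                            split_criterion = "gini") {
  stopifnot(min_split_size >= 1, max_prune_levels >= 0)
  split_criterion <- match.arg(split_criterion, "gini")
  structure(list(min_split_size = as.integer(min_split_size),
                 max_prune_levels = as.integer(max_prune_levels),
                 split_criterion = split_criterion),
            class = "df_tree_control")
}

#' Two-class Gini diversity index
#'
#' `1 - p1^2 - p0^2` for a node holding `n_binders` chemicals of class 1 and
#' `n_nonbinders` of class 0; ranges from 0 (pure) to 0.5 (balanced).
#'
#' @param n_binders,n_nonbinders non-negative class counts; their sum must be
#'   at least 1.
#' @return Gini impurity in \[0, 0.5\].
#' @examples
#' gini_impurity(5, 5)  # 0.5
#' gini_impurity(10, 0) # 0
#' @export
gini_impurity <- function(n_binders, n_nonbinders) {
  n <- n_binders + n_nonbinders
  if (n < 1) stop("empty node")
  p1 <- n_binders / n
  1 - p1^2 - (1 - p1)^2
}

#' Best single split of a node
#'
#' Evaluates, for every candidate descriptor, thresholds at the midpoints
#' between consecutive distinct sorted values, and returns the split with the
#' largest weighted Gini decrease. A value equal to the threshold is routed
#' left ("meets the criterion", `<=`). Ties are broken towards the lowest
#' descriptor column index, then the smallest threshold, so the search is
#' fully deterministic.
#'
#' @param X numeric matrix of candidate-descriptor columns for the node's
#'   chemicals.
#' @param y 0/1 labels for the rows of `X`.
#' @param min_split_size nodes smaller than this are not split.
#' @return `NULL` when no split is admissible (node too small, pure, or no
#'   impurity-decreasing threshold), otherwise a list with `descriptor`,
#'   `threshold` and `decrease`.
#' @export
df_best_split <- function(X, y, min_split_size = 10L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty node or candidate set")
  res <- best_split_cpp(X, as.integer(y), as.integer(min_split_size))
  if (res$col == 0L) return(NULL)
  list(descriptor = colnames(X)[res$col], threshold = res$threshold,
       decrease = res$decrease)
}

new_leaf <- function(n1, n0) {
  p <- n1 / (n1 + n0)
  list(kind = "leaf", n_binders = n1, n_nonbinders = n0, p_binder = p,
       class_label = if (p >= 0.5) 1L else 0L)
}

grow_node <- function(X, y, control) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  sp <- df_best_split(X, y, control$min_split_size)
  if (is.null(sp)) return(new_leaf(n1, n0))
  go_left <- X[, sp$descriptor] <= sp$threshold
  list(kind = "split", descriptor = sp$descriptor, threshold = sp$threshold,
       n_binders = n1, n_nonbinders = n0,
       left = grow_node(X[go_left, , drop = FALSE], y[go_left], control),
       right = grow_node(X[!go_left, , drop = FALSE], y[!go_left], control))
}

node_height <- function(node) {
  if (node$kind == "leaf") return(0L)
  1L + max(node_height(node$left), node_height(node$right))
}

node_misclassified <- function(node) {
  if (node$kind == "leaf")
    return(if (node$class_label == 1L) node$n_nonbinders else node$n_binders)
  node_misclassified(node$left) + node_misclassified(node$right)
}

node_count <- function(node) {
  if (node$kind == "leaf") return(1L)
  1L + node_count(node$left) + node_count(node$right)
}

node_descriptors <- function(node) {
  if (node$kind == "leaf") return(character(0))
  unique(c(node$descriptor, node_descriptors(node$left),
           node_descriptors(node$right)))
}

# Bottom-up bounded pruning: after pruning the children, a subtree whose
# height is <= max_prune_levels is collapsed to a majority leaf whenever the
# collapse does not increase the training misclassification count (ties go to
# the smaller tree).
prune_node <- function(node, max_levels) {
  if (node$kind == "leaf") return(node)
  node$left <- prune_node(node$left, max_levels)
  node$right <- prune_node(node$right, max_levels)
  if (node_height(node) <= max_levels) {
    leaf <- new_leaf(node$n_binders, node$n_nonbinders)
    collapsed_err <- if (leaf$class_label == 1L) leaf$n_nonbinders
                     else leaf$n_binders
    if (collapsed_err <= node_misclassified(node)) return(leaf)
  }
  node
}

#' Grow a single Decision Forest tree
#'
#' Recursive CART-style growth under Gini splitting (see [df_best_split()]),
#' stopping at pure nodes, nodes below `min_split_size`, or nodes with no
#' impurity-decreasing split, followed by bounded bottom-up pruning guided by
#' the training misclassification count: a subtree within the bottom
#' `max_prune_levels` levels is collapsed when the majority-class leaf
#' misclassifies no more training chemicals than the subtree's leaves do.
#'
#' @param data a labeled [qsar_dataset()].
#' @param candidate_descriptors descriptor names the tree may split on;
#'   default all.
#' @param control a [df_tree_control()].
#' @param prune collapse redundant bottom-level subtrees (default `TRUE`).
#' @return An object of class `df_tree` with elements `root` (nested nodes),
#'   `used_descriptors`, `training_misclassified`, `n_leaves` and `control`.
#' @export
df_tree_fit <- function(data, candidate_descriptors = NULL,
                        control = df_tree_control(), prune = TRUE) {
  stopifnot(inherits(data, "qsar_dataset"))
  if (is.null(data$labels)) stop("tree fitting requires labeled data")
  if (is.null(candidate_descriptors))
    candidate_descriptors <- colnames(data$descriptors)
  if (length(candidate_descriptors) == 0) stop("empty candidate descriptor set")
  missing <- setdiff(candidate_descriptors, colnames(data$descriptors))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  X <- data$descriptors[, candidate_descriptors, drop = FALSE]
  root <- grow_node(X, data$labels, control)
  if (prune) root <- prune_node(root, control$max_prune_levels)
  structure(list(root = root,
                 used_descriptors = node_descriptors(root),
                 training_misclassified = node_misclassified(root),
                 n_leaves = (node_count(root) + 1L) %/% 2L,
                 control = control),
            class = "df_tree")
}

#' @export
print.df_tree <- function(x, ...) {
  cat("df_tree:", length(x$used_descriptors), "descriptors used,",
      x$n_leaves, "leaves,", x$training_misclassified,
      "training chemicals misclassified\n")
  invisible(x)
}

route_row <- function(node, row) {
  while (node$kind == "split") {
    v <- row[[node$descriptor]]
    if (is.null(v) || is.na(v))
      stop("missing descriptor: ", node$descriptor)
    node <- if (v <= node$threshold) node$left else node$right
  }
  node
}

#' Predict binder probability with a single tree
#'
#' Routes each chemical down the tree (value equal to a threshold goes left)
#' and returns the training class proportion `p_binder` of the leaf reached.
#'
#' @param object a fitted `df_tree`.
#' @param newdata a [qsar_dataset()] or numeric matrix providing every
#'   descriptor the tree splits on.
#' @param ... unused.
#' @return Numeric vector of leaf binder proportions in \[0, 1\].
#' @export
predict.df_tree <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "qsar_dataset")) newdata$descriptors
       else as.matrix(newdata)
  missing <- setdiff(object$used_descriptors, colnames(X))
  if (length(missing))
    stop("missing descriptor: ", paste(missing, collapse = ", "))
  vapply(seq_len(nrow(X)),
         function(i) route_row(object$root, as.list(X[i, ]))$p_binder,
         numeric(1))
}
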