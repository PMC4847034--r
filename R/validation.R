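# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so validation helpers do not disturb the session stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

dataset_subset <- function(data, idx) {
  qsar_dataset(data$descriptors[idx, , drop = FALSE],
               data$chemical_ids[idx],
               labels = if (is.null(data$labels)) NULL else data$labels[idx],
               scaling = data$scaling)
}

#' Random k-fold partition of chemicals
#'
#' Randomly divides `n_chemicals` into `n_folds` disjoint, exhaustive folds
#' whose sizes differ by at most one. With `labels` given, the split is
#' stratified: each class is partitioned separately so class balance is
#' preserved per fold.
#'
#' @param n_chemicals number of chemicals (must be `>= n_folds`).
#' @param n_folds number of folds (default 5).
#' @param labels optional 0/1 vector enabling stratified folds.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return A list of `n_folds` integer index vectors.
#' @export
make_folds <- function(n_chemicals, n_folds = 5L, labels = NULL, seed = NULL) {
  if (n_chemicals < n_folds)
    stop("fewer chemicals (", n_chemicals, ") than folds (", n_folds, ")")
  draw <- function() {
    assign_fold <- function(idx)
      split(idx, sample(rep(seq_len(n_folds), length.out = length(idx))))
    if (is.null(labels)) {
      out <- assign_fold(seq_len(n_chemicals))
    } else {
      stopifnot(length(labels) == n_chemicals)
      parts <- lapply(split(seq_len(n_chemicals), labels), function(idx)
        split(idx, sample(rep(seq_len(n_folds), length.out = length(idx)))))
      out <- lapply(seq_len(n_folds), function(k)
        sort(unlist(lapply(parts, function(p) p[[as.character(k)]]),
                    use.names = FALSE)))
      names(out) <- as.character(seq_len(n_folds))
    }
    lapply(seq_len(n_folds), function(k) {
      v <- out[[as.character(k)]]
      if (is.null(v)) integer(0) else unname(v)
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

metric_names <- c("accuracy", "sensitivity", "specificity", "mcc",
                  "balanced_accuracy")

# One n_fold cross-validation pass over `data` using the current RNG stream.
# Returns fold-averaged metrics, pooled predictions and per-model descriptor
# usage sets.
cv_once <- function(data, n_folds, n_trees, control, stratified, preprocess) {
  n <- length(data$chemical_ids)
  folds <- make_folds(n, n_folds,
                      labels = if (stratified) data$labels else NULL)
  fold_metrics <- matrix(NA_real_, n_folds, length(metric_names),
                         dimnames = list(NULL, metric_names))
  preds <- vector("list", n_folds)
  usage <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test_idx <- folds[[k]]
    train <- dataset_subset(data, setdiff(seq_len(n), test_idx))
    test <- dataset_subset(data, test_idx)
    if (preprocess == "per_split") {
      forest <- df_train(train, n_trees = n_trees, control = control)
      pr <- df_predict(forest, test)
    } else {
      forest <- df_fit(train, n_trees = n_trees, control = control)
      pr <- predict(forest, test)
    }
    m <- score_predictions(test$labels, pr$call)
    fold_metrics[k, ] <- unlist(m)[metric_names]
    pr$fold <- k
    pr$actual <- test$labels
    preds[[k]] <- pr
    usage[[k]] <- unique(unlist(forest$used_descriptors_per_tree))
  }
  list(metrics = colMeans(fold_metrics, na.rm = TRUE),
       fold_metrics = fold_metrics,
       predictions = do.call(rbind, preds),
       usage = usage)
}

#' Repeated k-fold cross-validation of a Decision Forest
#'
#' For each repeat the chemicals are randomly divided into `n_folds`
#' portions; each portion is held out once while a forest is fitted on the
#' remainder (including, by default, fold-internal constant-column removal
#' and min-max scaling, so no information leaks from the held-out portion)
#' and predicts it. Fold metrics are averaged within each repeat, and the
#' run-level summary is the mean and standard deviation over repeats.
#'
#' @param data a raw labeled [qsar_dataset()].
#' @param n_repeats number of independent k-fold repeats.
#' @param n_folds folds per repeat (default 5).
#' @param seed master seed; the whole run is reproducible from it.
#' @param n_trees,control forest parameters, see [df_fit()].
#' @param stratified preserve class balance within folds (default `FALSE`,
#'   plain random division).
#' @param preprocess `"per_split"` (default) refits cleanup/scaling on each
#'   training split; `"global"` preprocesses the full dataset once before
#'   splitting, reproducing the literal single-preprocess protocol at the
#'   cost of a small leak.
#' @return An object of class `df_cv`: `repeat_metrics` (data frame, one row
#'   per repeat), `summary` (mean and sd per metric), `predictions` (pooled:
#'   repeat, fold, chemical_id, actual, p, call, confidence) and
#'   `model_descriptors` (one descriptor-name set per fitted forest,
#'   `n_repeats * n_folds` in all).
#' @export
cross_validate <- function(data, n_repeats = 10L, n_folds = 5L, seed = 1L,
                           n_trees = 5L, control = df_tree_control(),
                           stratified = FALSE,
                           preprocess = c("per_split", "global")) {
  stopifnot(inherits(data, "qsar_dataset"))
  if (is.null(data$labels)) stop("cross-validation requires labeled data")
  preprocess <- match.arg(preprocess)
  if (preprocess == "global") data <- preprocess_dataset(data)
  with_seed(seed, {
    reps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      res <- tryCatch(
        cv_once(data, n_folds, n_trees, control, stratified, preprocess),
        error = function(e) stop("repeat ", r, ": ", conditionMessage(e),
                                 call. = FALSE))
      res$predictions$repeat_index <- r
      reps[[r]] <- res
    }
    repeat_metrics <- as.data.frame(do.call(rbind,
                                            lapply(reps, `[[`, "metrics")))
    predictions <- do.call(rbind, lapply(reps, `[[`, "predictions"))
    predictions <- predictions[, c("repeat_index", "fold", "chemical_id",
                                   "actual", "p", "call", "confidence")]
    structure(list(
      repeat_metrics = repeat_metrics,
      summary = data.frame(metric = metric_names,
                           mean = colMeans(as.matrix(repeat_metrics)),
                           sd = apply(as.matrix(repeat_metrics), 2, sd),
                           row.names = NULL),
      predictions = predictions,
      model_descriptors = unlist(lapply(reps, `[[`, "usage"),
                                 recursive = FALSE),
      config = list(n_repeats = n_repeats, n_folds = n_folds, seed = seed,
                    n_trees = n_trees, control = control,
                    stratified = stratified, preprocess = preprocess)),
      class = "df_cv")
  })
}

#' @export
print.df_cv <- function(x, ...) {
  cat("df_cv:", x$config$n_repeats, "repeats of", x$config$n_folds,
      "-fold cross-validation\n")
  print(transform(x$summary, mean = round(mean, 3), sd = round(sd, 3)))
  invisible(x)
}

#' Label-permutation (y-scrambling) null distribution
#'
#' Each permutation randomly shuffles the activity labels — preserving the
#' binder/non-binder counts while detaching labels from the descriptors —
#' and runs one full `n_folds` cross-validation on the scrambled data. The
#' per-permutation fold-averaged metrics form the chance-performance null
#' against which the real cross-validation is compared.
#'
#' @inheritParams cross_validate
#' @param n_permutations number of label shuffles (>= 1).
#' @return An object of class `df_permutation`: `metrics` (data frame, one
#'   row per permutation), `model_descriptors` (one set per fitted forest,
#'   `n_permutations * n_folds` in all) and `config`.
#' @export
permutation_test <- function(data, n_permutations = 100L, n_folds = 5L,
                             seed = 1L, n_trees = 5L,
                             control = df_tree_control(), stratified = FALSE,
                             preprocess = c("per_split", "global")) {
  stopifnot(inherits(data, "qsar_dataset"))
  if (is.null(data$labels)) stop("permutation testing requires labeled data")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  preprocess <- match.arg(preprocess)
  if (preprocess == "global") data <- preprocess_dataset(data)
  with_seed(seed, {
    perms <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      shuffled <- data
      shuffled$labels <- sample(data$labels)
      perms[[b]] <- tryCatch(
        cv_once(shuffled, n_folds, n_trees, control, stratified, preprocess),
        error = function(e) stop("permutation ", b, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    structure(list(
      metrics = as.data.frame(do.call(rbind, lapply(perms, `[[`, "metrics"))),
      model_descriptors = unlist(lapply(perms, `[[`, "usage"),
                                 recursive = FALSE),
      config = list(n_permutations = n_permutations, n_folds = n_folds,
                    seed = seed, n_trees = n_trees, control = control,
                    stratified = stratified, preprocess = preprocess)),
      class = "df_permutation")
  })
}

#' @export
print.df_permutation <- function(x, ...) {
  cat("df_permutation:", x$config$n_permutations,
      "label permutations; null mean accuracy",
      round(mean(x$metrics$accuracy), 3), "\n")
  invisible(x)
}

#' Empirical permutation p-value
#'
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)` — the add-one form
#' avoids reporting an exact zero from a finite number of permutations.
#'
#' @param null_values per-permutation metric values (e.g. accuracies).
#' @param observed the metric observed on the real labels.
#' @return The empirical p-value.
#' @export
perm_p_value <- function(null_values, observed) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Confidence-binned accuracy profile
#'
#' Pools all cross-validation predictions and places them into 20 even
#' confidence bins — `[i/20, (i+1)/20)` for the first 19 and the closed
#' `[0.95, 1]` for the last — counting correct and incorrect calls per bin.
#' On data with real signal the per-bin accuracy rises with confidence:
#' high-confidence predictions are the trustworthy ones.
#'
#' @param run a `df_cv` object (or any data frame with `confidence`, `call`
#'   and `actual` columns).
#' @return A 20-row data frame: `bin`, `lower`, `upper`, `n`, `n_correct`,
#'   `n_incorrect`, `accuracy` (`NA` for empty bins).
#' @export
confidence_profile <- function(run) {
  preds <- if (inherits(run, "df_cv")) run$predictions else run
  stopifnot(all(c("confidence", "call", "actual") %in% names(preds)))
  bin <- pmin(floor(preds$confidence * 20) + 1L, 20L)
  correct <- preds$call == preds$actual
  n <- tabulate(bin, 20L)
  n_correct <- vapply(1:20, function(b) sum(correct[bin == b]), integer(1))
  data.frame(bin = 1:20, lower = (0:19) / 20, upper = (1:20) / 20,
             n = n, n_correct = n_correct, n_incorrect = n - n_correct,
             accuracy = ifelse(n > 0, n_correct / n, NA_real_))
}

#' Informative descriptors against a permutation background
#'
#' Counts, for every descriptor, in how many fitted models (forests) it was
#' used — once per model regardless of how many nodes split on it — in the
#' real cross-validation and in the label-permutation runs. The permutation
#' frequencies form the chance background: the threshold is the smallest
#' frequency `f` such that at most `alpha` of the background frequencies
#' exceed it, and a descriptor is flagged informative when its
#' cross-validation frequency strictly exceeds `f`.
#'
#' @param cv_usage,perm_usage lists of descriptor-name sets, one per fitted
#'   model (the `model_descriptors` element of [cross_validate()] and
#'   [permutation_test()] results).
#' @param alpha background tail probability (default 0.05, the top-5%
#'   frequency criterion).
#' @param descriptors the descriptor universe; defaults to the union of all
#'   used names. Every used name must belong to it.
#' @return A data frame with columns `descriptor`, `cv_models`,
#'   `perm_models`, `informative`, ordered by decreasing `cv_models`; the
#'   background threshold is attached as attribute `"threshold"`.
#' @export
informative_descriptors <- function(cv_usage, perm_usage, alpha = 0.05,
                                    descriptors = NULL) {
  if (!length(cv_usage) || !length(perm_usage))
    stop("both usage collections must be non-empty")
  used <- unique(c(unlist(cv_usage), unlist(perm_usage)))
  if (is.null(descriptors)) descriptors <- sort(used)
  extra <- setdiff(used, descriptors)
  if (length(extra))
    stop("used descriptor(s) outside the stated universe: ",
         paste(extra, collapse = ", "))
  count_models <- function(usage)
    vapply(descriptors,
           function(d) sum(vapply(usage, function(s) d %in% s, logical(1))),
           integer(1))
  cv_freq <- count_models(cv_usage)
  perm_freq <- count_models(perm_usage)
  cand <- sort(unique(c(0L, perm_freq)))
  threshold <- cand[which(vapply(cand, function(f) mean(perm_freq > f),
                                 numeric(1)) <= alpha)[1]]
  out <- data.frame(descriptor = descriptors, cv_models = cv_freq,
                    perm_models = perm_freq,
                    informative = cv_freq > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$cv_models, out$descriptor), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
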