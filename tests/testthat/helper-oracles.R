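# Independent oracles and small fixture builders used across the suite.

# Brute-force split search: every column, every midpoint between consecutive
# distinct sorted values, plain arithmetic. Kept deliberately independent of
# the package's compiled search.
brute_force_split <- function(X, y, min_split_size) {
  n <- nrow(X)
  if (n < min_split_size || length(unique(y)) < 2) return(NULL)
  gini <- function(lab) {
    p1 <- mean(lab == 1)
    1 - p1^2 - (1 - p1)^2
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (thr in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- X[, j] <= thr
      dec <- gini(y) - mean(left) * gini(y[left]) -
        mean(!left) * gini(y[!left])
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(descriptor = colnames(X)[j], threshold = thr,
                     decrease = dec)
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

# MCC oracle: the Pearson correlation of the two 0/1 vectors (phi
# coefficient), computed by stats::cor rather than the confusion-table
# formula.
mcc_oracle <- function(actual, predicted) {
  r <- suppressWarnings(cor(actual, predicted))
  if (is.na(r)) 0 else r
}

# Expand a confusion table into aligned actual/predicted vectors.
expand_confusion <- function(tp, tn, fp, fn) {
  list(actual = c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn)),
       predicted = c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn)))
}

# Tiny labeled dataset from a descriptor matrix.
make_dataset <- function(X, labels = NULL, scaled = FALSE) {
  d <- qsar_dataset(X, sprintf("c%02d", seq_len(nrow(X))), labels = labels)
  if (scaled) d$scaling <- fit_minmax_scaling(d)
  d
}

# Small synthetic spec used where the default 125 x 777 scale is overkill.
small_spec <- function(...) {
  args <- list(n_chemicals = 60L, n_raw_descriptors = 40L, n_constant = 5L,
               n_informative = 5L, class_balance = 0.5,
               signal_strength = 2, correlation_block_size = 2L,
               label_noise = 0, seed = 42L)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}
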