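test_that("Gini impurity follows the two-class formula", {
  expect_equal(gini_impurity(5, 5), 0.5)
  expect_equal(gini_impurity(10, 0), 0)
  expect_equal(gini_impurity(3, 1), 0.375)
  expect_error(gini_impurity(0, 0), "empty node")
})

test_that("best split matches the brute-force oracle on random nodes", {
  X <- matrix(c(1, 2, 3, 4), 4, dimnames = list(NULL, "D1"))
  sp <- df_best_split(X, c(0, 0, 1, 1), min_split_size = 2)
  expect_equal(sp$descriptor, "D1")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$decrease, 0.5)

  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    p <- sample(1:5, 1)
    X <- matrix(round(rnorm(n * p), 2), n,
                dimnames = list(NULL, paste0("D", seq_len(p))))
    y <- rbinom(n, 1, 0.5)
    got <- df_best_split(X, y, min_split_size = 2)
    want <- brute_force_split(X, y, min_split_size = 2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$decrease, want$decrease, tolerance = 1e-10)
      # the oracle scans columns then thresholds in the same order, so the
      # tie-break (lowest column, smallest threshold) must agree too
      expect_equal(got$descriptor, want$descriptor)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("degenerate nodes yield no split", {
  X <- matrix(1:9, 9, dimnames = list(NULL, "D1"))
  expect_null(df_best_split(X, rep(1, 9), min_split_size = 2))   # pure
  expect_null(df_best_split(X, rep(c(0, 1), length.out = 9),
                            min_split_size = 10))                # too small
  Xc <- matrix(5, 6, 1, dimnames = list(NULL, "D1"))
  expect_null(df_best_split(Xc, rep(c(0, 1), 3), min_split_size = 2))
})

test_that("separable data grows a single pure split; constant data a leaf", {
  X <- matrix(c(1:20, rnorm(20)), 20, dimnames = list(NULL, c("D1", "D2")))
  d <- make_dataset(X, labels = c(rep(0L, 10), rep(1L, 10)))
  tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 2))
  expect_equal(tr$used_descriptors, "D1")
  expect_equal(tr$training_misclassified, 0L)
  expect_equal(tr$n_leaves, 2L)

  flat <- make_dataset(matrix(1, 10, 2, dimnames = list(NULL, c("A", "B"))),
                       labels = c(rep(1L, 7), rep(0L, 3)))
  leaf_tree <- df_tree_fit(flat, control = df_tree_control(min_split_size = 2))
  expect_equal(leaf_tree$root$kind, "leaf")
  expect_equal(leaf_tree$root$class_label, 1L)
  expect_equal(leaf_tree$training_misclassified, 3L)
})

test_that("an XOR structure is learned to zero training error", {
  # XOR-labeled quadrants with unequal counts (12/8/8/12): a greedy Gini
  # tree needs interacting splits to reach zero error, and the imbalance
  # gives the first split a strictly positive impurity decrease (a fully
  # balanced XOR has none and is unlearnable greedily)
  quadrant <- function(n, a_hi, b_hi)
    data.frame(a = seq(0.1, 0.4, length.out = n) + 0.5 * a_hi,
               b = seq(0.1, 0.4, length.out = n) + 0.5 * b_hi)
  grid <- rbind(quadrant(12, 0, 0), quadrant(8, 1, 1),
                quadrant(8, 0, 1), quadrant(12, 1, 0))
  y <- as.integer(xor(grid$a > 0.5, grid$b > 0.5))
  d <- make_dataset(as.matrix(grid), labels = y)
  tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 2))
  expect_equal(tr$training_misclassified, 0L)
  n_splits <- function(node) {
    if (node$kind == "leaf") return(0L)
    1L + n_splits(node$left) + n_splits(node$right)
  }
  expect_gte(n_splits(tr$root), 3L)
})

test_that("leaf class counts conserve the training set and errors match", {
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("D", 1:4)))
    y <- rbinom(30, 1, 0.4)
    d <- make_dataset(X, labels = as.integer(y))
    tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 5))
    counts <- local({
      acc <- c(0L, 0L)
      walk <- function(node) {
        if (node$kind == "leaf")
          acc <<- acc + c(node$n_binders, node$n_nonbinders)
        else { walk(node$left); walk(node$right) }
      }
      walk(tr$root)
      acc
    })
    expect_equal(counts, c(sum(y == 1), sum(y == 0)))
    pred <- as.integer(predict(tr, d) >= 0.5)
    expect_equal(sum(pred != y), tr$training_misclassified)
  }
})

test_that("tree matches exhaustive-search zero-error fits on tiny data", {
  # On separable instances with min_split_size 2 the grown tree must reach
  # zero training error, like an exhaustive threshold classifier would.
  set.seed(19)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    x <- sort(rnorm(n))
    cut <- sample(2:(n - 1), 1)
    y <- as.integer(seq_len(n) > cut)
    d <- make_dataset(matrix(x, n, dimnames = list(NULL, "D1")), labels = y)
    tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 2))
    expect_equal(tr$training_misclassified, 0L)
  }
})

test_that("rows at a threshold route left and missing descriptors error", {
  X <- matrix(c(1, 2, 3, 4), 4, dimnames = list(NULL, "D1"))
  d <- make_dataset(X, labels = c(0L, 0L, 1L, 1L))
  tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 2))
  # threshold is 2.5; a row exactly at the threshold meets the criterion
  expect_equal(predict(tr, matrix(2.5, 1, 1, dimnames = list(NULL, "D1"))), 0)
  expect_equal(predict(tr, matrix(2.51, 1, 1, dimnames = list(NULL, "D1"))), 1)
  expect_error(predict(tr, matrix(1, 1, 1, dimnames = list(NULL, "Z"))),
               "missing descriptor: D1")
})

test_that("pruning collapses redundant bottom splits but is depth-bounded", {
  # D1 separates the classes except for one mislabeled chemical; D2 can
  # carve that chemical out, but the extra splits fix no training error the
  # parent majority doesn't already get, so pruning removes them.
  set.seed(5)
  X <- cbind(D1 = c(seq(0, 0.4, length.out = 10),
                    seq(0.6, 1, length.out = 10)),
             D2 = runif(20))
  y <- c(rep(0L, 10), rep(1L, 10))
  d <- make_dataset(X, labels = y)
  unpruned <- df_tree_fit(d, control = df_tree_control(min_split_size = 2),
                          prune = FALSE)
  pruned <- df_tree_fit(d, control = df_tree_control(min_split_size = 2))
  expect_equal(pruned$n_leaves, 2L)
  expect_lte(pruned$n_leaves, unpruned$n_leaves)
  expect_equal(pruned$training_misclassified, unpruned$training_misclassified)

  # a perfectly separating split is never collapsed
  expect_equal(pruned$used_descriptors, "D1")

  # the bound: a deep chain of useful splits keeps its root even though its
  # bottom levels are within pruning reach
  xs <- seq(0, 1, length.out = 64)
  ys <- as.integer((floor(xs * 8) %% 2) == 1)  # alternating blocks of 8
  deep <- make_dataset(matrix(xs, dimnames = list(NULL, "D1")), labels = ys)
  dt <- df_tree_fit(deep, control = df_tree_control(min_split_size = 2,
                                                    max_prune_levels = 3))
  expect_equal(dt$root$kind, "split")
  expect_equal(dt$training_misclassified, 0L)
})

test_that("root split agrees with an independent CART implementation", {
  skip_if_not_installed("rpart")
  set.seed(23)
  X <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("D1", "D2", "D3")))
  y <- as.integer(X[, 2] + 0.3 * rnorm(60) > 0)
  d <- make_dataset(X, labels = y)
  tr <- df_tree_fit(d, control = df_tree_control(min_split_size = 10))
  rp <- rpart::rpart(factor(y) ~ ., data = as.data.frame(X),
                     method = "class",
                     control = rpart::rpart.control(minsplit = 10, cp = 0))
  expect_equal(tr$root$descriptor,
               as.character(rp$frame$var[1]))
  expect_equal(tr$root$threshold, unname(rp$splits[1, "index"]),
               tolerance = 1e-8)
})
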