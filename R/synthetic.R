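#' Specification for a synthetic AFP-like descriptor dataset
#'
#' Describes a synthetic chemicals-by-descriptors matrix with the structure
#' a 2D-descriptor QSAR table typically shows: constant columns (dropped by
#' cleanup), a small planted subset of class-informative descriptors,
#' correlated blocks of redundant noise descriptors, heterogeneous raw
#' scales, and an imbalanced binary endpoint. The defaults mirror the rat
#' AFP binding study conditions: 125 chemicals (53 binders / 72 non-binders),
#' 777 raw descriptors of which 265 are constant so cleanup leaves 512, and
#' 16 informative descriptors.
#'
#' @param n_chemicals number of chemicals (default 125).
#' @param n_raw_descriptors raw descriptor columns (default 777).
#' @param n_constant constant columns among them (default 265).
#' @param n_informative planted class-informative columns (default 16).
#' @param class_balance binder fraction (default 53/125).
#' @param signal_strength class-mean separation on informative columns, in
#'   latent standard-deviation units (default 1.5).
#' @param correlation_block_size noise descriptors are grouped into blocks of
#'   this size sharing a latent factor (default 4; 1 disables correlation).
#' @param label_noise probability that an emitted label is flipped relative
#'   to the ground-truth class (default 0.1).
#' @param seed seed from which the generator layout and the training draw
#'   are derived.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chemicals = 125L, n_raw_descriptors = 777L,
                           n_constant = 265L, n_informative = 16L,
                           class_balance = 53 / 125, signal_strength = 1.5,
                           correlation_block_size = 4L, label_noise = 0.1,
                           seed = 1L) {
  if (n_constant + n_informative > n_raw_descriptors)
    stop("infeasible spec: n_constant + n_informative exceeds ",
         "n_raw_descriptors")
  stopifnot(n_chemicals >= 2, class_balance > 0, class_balance < 1,
            signal_strength >= 0, label_noise >= 0, label_noise <= 1,
            correlation_block_size >= 1)
  structure(list(n_chemicals = as.integer(n_chemicals),
                 n_raw_descriptors = as.integer(n_raw_descriptors),
                 n_constant = as.integer(n_constant),
                 n_informative = as.integer(n_informative),
                 class_balance = class_balance,
                 signal_strength = signal_strength,
                 correlation_block_size = as.integer(correlation_block_size),
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# The generator layout (column roles, per-column location/scale, shift
# directions, noise-block membership, constant values) is a deterministic
# function of the spec seed, so training and external draws share one
# generative law.
synthetic_blueprint <- function(spec) {
  with_seed(spec$seed, {
    p <- spec$n_raw_descriptors
    names <- sprintf("D%03d", seq_len(p))
    roles <- rep("noise", p)
    special <- sample(p, spec$n_constant + spec$n_informative)
    roles[special[seq_len(spec$n_constant)]] <- "constant"
    roles[special[spec$n_constant + seq_len(spec$n_informative)]] <-
      "informative"
    const_value <- round(runif(p, 0, 5))       # used for constant cols only
    mu <- runif(p, -5, 5)                      # heterogeneous raw locations
    scale <- runif(p, 0.5, 2)                  # heterogeneous raw scales
    delta <- rep(0, p)
    inf_idx <- which(roles == "informative")
    delta[inf_idx] <- spec$signal_strength *
      rep_len(c(1, -1), length(inf_idx))       # shift direction alternates
    noise_idx <- which(roles == "noise")
    block <- rep(NA_integer_, p)
    block[noise_idx] <- ceiling(seq_along(noise_idx) /
                                  spec$correlation_block_size)
    list(names = names, roles = roles, const_value = const_value, mu = mu,
         scale = scale, delta = delta, block = block,
         n_blocks = if (length(noise_idx)) max(block, na.rm = TRUE) else 1L,
         rho = 0.5)
  })
}

draw_labels <- function(spec, n) {
  n1 <- round(spec$class_balance * n)
  true <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  flip <- runif(n) < spec$label_noise
  list(true = true, observed = as.integer(ifelse(flip, 1L - true, true)))
}

draw_rows <- function(blueprint, spec, n, true_labels) {
  p <- spec$n_raw_descriptors
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, blueprint$names))
  latent <- matrix(rnorm(n * blueprint$n_blocks), n, blueprint$n_blocks)
  for (j in seq_len(p)) {
    X[, j] <- switch(blueprint$roles[j],
      constant = rep(blueprint$const_value[j], n),
      informative = blueprint$mu[j] + blueprint$scale[j] *
        (X[, j] + blueprint$delta[j] * true_labels),
      noise = {
        b <- blueprint$block[j]
        blueprint$mu[j] + blueprint$scale[j] *
          (sqrt(blueprint$rho) * latent[, b] +
             sqrt(1 - blueprint$rho) * X[, j])
      })
  }
  X
}

#' Generate a synthetic training dataset
#'
#' Draws a raw descriptor matrix and labels from the generative law described
#' by a [synthetic_spec()]. Informative descriptors are location-shifted
#' between classes by `signal_strength` latent standard deviations (in
#' alternating directions), noise descriptors are class-independent with
#' block-wise correlation, constant columns are constant, and emitted labels
#' are the ground-truth classes flipped with probability `label_noise`.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_qsar`: `dataset` (a raw labeled
#'   [qsar_dataset()]) and `truth` (informative descriptor names, constant
#'   column names, ground-truth labels before noise, flip indicator).
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  blueprint <- synthetic_blueprint(spec)
  with_seed(spec$seed + 1L, {
    lab <- draw_labels(spec, spec$n_chemicals)
    X <- draw_rows(blueprint, spec, spec$n_chemicals, lab$true)
    ids <- sprintf("chem_%03d", seq_len(spec$n_chemicals))
    list(dataset = qsar_dataset(X, ids, labels = lab$observed),
         truth = list(informative = blueprint$names[
                        blueprint$roles == "informative"],
                      constant = blueprint$names[
                        blueprint$roles == "constant"],
                      true_labels = lab$true,
                      flipped = lab$observed != lab$true))
  })
}

#' Generate a synthetic external validation set
#'
#' New chemicals drawn from the same generative law (same [synthetic_spec()]
#' layout) as a training set produced by [generate_synthetic_dataset()],
#' with disjoint chemical identifiers — a stand-in for an externally curated
#' validation set.
#'
#' @param spec the [synthetic_spec()] the training set was generated from.
#' @param n_external number of external chemicals (default 22).
#' @param seed seed for the external draw; defaults to `spec$seed + 1000`.
#' @return A list of class `synthetic_qsar` as in
#'   [generate_synthetic_dataset()], with ids `ext_001`, `ext_002`, ...
#' @export
synthetic_external_dataset <- function(spec, n_external = 22L,
                                       seed = spec$seed + 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_external >= 0)
  blueprint <- synthetic_blueprint(spec)
  with_seed(seed, {
    lab <- if (n_external > 0) draw_labels(spec, n_external)
           else list(true = integer(0), observed = integer(0))
    X <- draw_rows(blueprint, spec, n_external, lab$true)
    ids <- if (n_external > 0) sprintf("ext_%03d", seq_len(n_external))
           else character(0)
    list(dataset = qsar_dataset(X, ids, labels = lab$observed),
         truth = list(informative = blueprint$names[
                        blueprint$roles == "informative"],
                      constant = blueprint$names[
                        blueprint$roles == "constant"],
                      true_labels = lab$true,
                      flipped = lab$observed != lab$true))
  })
}
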