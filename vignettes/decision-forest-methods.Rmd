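---
title: "Decision Forest consensus models for binary QSAR endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision Forest consensus models for binary QSAR endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfqsar)
```

## The modelling problem

Rat α-fetoprotein (AFP) is a serum transport protein that competitively
binds estrogens and estrogen-like chemicals, sequestering them away from
hormone receptors in target cells. Whether an environmental chemical binds
AFP is therefore a useful input to endocrine-disruption risk assessment,
but experimental competitive-binding data exist for only a few hundred
chemicals. `dfqsar` builds quantitative structure–activity relationship
(QSAR) models that predict the binary endpoint — binder (1) versus
non-binder (0) — from numerical 2D molecular descriptors such as the ~777
values produced by the Mold² program. Descriptor computation itself is out
of scope: the package consumes the exported numeric table.

## The Decision Forest model

A Decision Forest (DF) is a consensus of `n_trees` (default 5)
classification trees that is forced to be *heterogeneous*: the first tree
is grown on the full descriptor pool, and each subsequent tree is grown on
the pool minus every descriptor used by the earlier trees. The trees'
descriptor sets are therefore pairwise disjoint, so each tree must explain
the activity with different structural features, and variable selection is
wrapped inside model construction. Fitting stops early when the pool is
exhausted or when the next tree degenerates to a single leaf.

Each tree is a binary CART-style classifier:

* **Splitting.** Candidate thresholds are midpoints between consecutive
  distinct sorted values of each candidate descriptor; the split maximising
  the weighted decrease of the two-class Gini diversity index
  $G = 1 - p_1^2 - p_0^2$ is chosen. A chemical whose value equals the
  threshold goes to the left ("meets the criterion", $\le$) child.
* **Stopping.** A node is not split when it is pure, holds fewer than
  `min_split_size` chemicals (default 10), or admits no split with strictly
  positive Gini decrease.
* **Pruning.** Growth is followed by bounded bottom-up pruning guided by
  the training misclassification count: a subtree whose height is at most
  `max_prune_levels` (default 3) is collapsed to its majority-class leaf
  whenever the collapse does not increase the number of misclassified
  training chemicals. Ties always go to the smaller tree. The bound keeps
  pruning a local simplification — the upper structure of a deep tree is
  untouchable.
* **Determinism.** Ties between equally good splits are broken towards the
  lowest descriptor column index, then the smallest threshold, so a fit is
  a pure function of its input.

The consensus prediction for a chemical is the unweighted arithmetic mean
$p$ of the trees' leaf binder *proportions*. Using class proportions rather
than hard 0/1 leaf votes preserves a continuous $p$ (five hard votes would
quantise it to six values); a hard-vote mode is available via
`predict(..., vote = "hard")` for comparison. The chemical is called a
binder when $p \ge 0.5$, and every prediction carries the confidence

$$\mathrm{confidence} = \frac{|p - 0.5|}{0.5} \in [0, 1],$$

which is 0 at the decision boundary and 1 for a unanimous forest, and is
symmetric under $p \mapsto 1 - p$.

An aside on greedy growth: a perfectly balanced XOR arrangement of two
descriptors has zero marginal Gini decrease for every single split, so no
strictly-improving greedy tree can enter it. Interaction structure is
learnable only when the class proportions are at least slightly asymmetric;
the test suite demonstrates both sides of this boundary.

## Preprocessing

Descriptor tables are cleaned by removing columns that are constant across
all chemicals and then min-max scaling each surviving column to $[0, 1]$.
Two choices deserve a note:

* **Scope.** Cleanup and scaling are fitted on the *training* chemicals
  only and the frozen parameters are applied to external chemicals; this is
  the leakage-free protocol, and it matches the deployment situation where
  the model exists before external data does. A `preprocess = "global"`
  mode is available in `cross_validate()` for literal reproduction of the
  single-pass protocol. Inside cross-validation the default refits
  preprocessing per training split for the same reason.
* **No clipping.** External values outside the training range scale to
  values outside $[0, 1]$ and are left there: the trees are
  threshold-based, so the monotone linear extrapolation cannot change a
  routing decision incorrectly, whereas clipping would be an undocumented
  transformation. Missing values are rejected at load time rather than
  imputed.

## Validation machinery

* **Repeated k-fold cross-validation.** Each repeat randomly divides the
  chemicals into `n_folds` (default 5) portions of near-equal size
  (unstratified by default; stratification is an option). Each portion is
  predicted once by a forest fitted on the remainder. Fold metrics are
  averaged within a repeat; the run summary is the mean ± standard
  deviation across repeats. All predictions are pooled with their
  confidence values, and each fitted forest's used-descriptor set is
  recorded.
* **Metrics.** Accuracy, sensitivity, specificity, the Matthews
  correlation coefficient (MCC) and balanced accuracy are computed from the
  TP/TN/FP/FN confusion counts. Conventions: MCC is 0 when a denominator
  factor vanishes; sensitivity and specificity are `NA` (not 0) when there
  are no actual positives or negatives, so aggregates are never silently
  distorted.
* **Label permutation (y-scrambling).** Each permutation shuffles the
  activity labels — preserving the class counts while severing the
  descriptor–activity link — and runs one full k-fold cross-validation.
  The per-permutation averaged metrics form the chance-performance null;
  the empirical p-value is reported as
  $(1 + \#\{\text{null} \ge \text{observed}\}) / (1 + B)$, which cannot be
  exactly zero for finite $B$.
* **Confidence profile.** Pooled predictions are placed into 20 even
  confidence bins, $[i/20, (i+1)/20)$ with a closed last bin
  $[0.95, 1]$, and per-bin accuracy is computed. On real signal the
  profile rises with confidence, which is what justifies trusting
  high-confidence calls in screening practice.
* **Informative descriptors.** For every descriptor the number of fitted
  models (forests) that used it — once per model, however many nodes split
  on it — is counted in the cross-validation arm and in the permutation
  arm. The permutation frequencies form the chance background; the
  threshold is the smallest frequency $f$ such that at most $\alpha$
  (default 0.05, the top-5% criterion) of the background frequencies
  exceed $f$, and a descriptor is informative when its cross-validation
  frequency *strictly* exceeds $f$. The quantile is taken across the
  background frequency distribution of all descriptors; this reading of
  the top-5% rule is a documented choice.

## The synthetic-data generator

The real AFP descriptor matrix is not distributed, so the package ships a
generator whose defaults mirror the study conditions: 125 chemicals with a
53:72 binder:non-binder split, 777 raw descriptors of which 265 are
constant (cleanup leaves 512), and 16 planted informative descriptors.
Informative columns are class-conditionally location-shifted by
`signal_strength` latent standard deviations (alternating shift direction
across the planted set); the remaining noise columns are class-independent
and grouped into blocks of `correlation_block_size` sharing a latent factor
(within-block correlation 0.5), emulating the heavy redundancy of 2D
descriptor families; columns have heterogeneous raw locations and scales so
min-max scaling does real work; emitted labels are the ground-truth classes
flipped with probability `label_noise`. Ground truth (planted descriptors,
pre-noise labels) is returned alongside the data so recovery tests never
have to re-derive it.

Defaults chosen once for the unspecified knobs: `signal_strength = 1.5`
and `label_noise = 0.1`, a moderately noisy assay regime in which
cross-validated accuracy sits clearly above chance without being
trivially separable — the regime the method is designed for;
`correlation_block_size = 4` as a typical redundancy granularity.

What passing tests on this generator do *not* show: real descriptor
distributions are discrete, skewed and collinear in ways a Gaussian latent
model does not reproduce, and real structure–activity signal is not an
additive location shift. The synthetic results validate the machinery —
fold accounting, null calibration, confidence monotonicity, frequency-based
descriptor recovery — not the achievable accuracy on laboratory data.

## Numerical and design choices

* Gini impurity uses exact class counts; a split is accepted only when its
  decrease exceeds $10^{-12}$, so floating-point ties collapse to "no
  split".
* `p = 0.5` is called a binder (the $\ge$ convention) with confidence 0.
* Fold assignment uses a length-balanced random permutation, so fold sizes
  differ by at most one.
* One master seed drives each validation run; runs restore the caller's
  RNG state, and identically seeded reruns are bit-identical.
* Problem sizes used by the shipped verification runs: 100 cross-validation
  repeats and 100 permutations on the default 125 × 777 synthetic table
  (500 fitted forests per arm) — enough for stable means and a p-value
  resolution of about 0.01, and comparable in spirit to the 1000-iteration
  protocol of the original study design at a tenth of the cost.

## Known limitations

* Greedy Gini growth cannot discover perfectly balanced interaction
  structure (the XOR boundary above).
* The bounded-pruning semantics ("collapse within the bottom 3 levels")
  is one of several readings of the historical DF software's pruning
  parameter; it is fixed here, documented, and bounded so it can never
  remove the upper structure of a deep tree.
* Unstratified 5-fold division of a 53:72 endpoint occasionally yields a
  test fold with few binders; fold metrics that are undefined in such a
  fold are averaged over the defined folds only.
* The consensus is unweighted; no applicability-domain geometry beyond the
  confidence value is provided.
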