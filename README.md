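# dfqsar

Decision Forest consensus models for binary QSAR endpoints, built around
the rat α-fetoprotein (AFP) binding problem in endocrine-disruption
screening.

AFP is a major serum transport protein in the rat that competitively binds
estrogens and estrogen-like environmental chemicals, sequestering them
before they reach hormone receptors. Whether a chemical binds AFP is
therefore valuable context when assessing its endocrine-disruption
potential, but experimental binding data are scarce. `dfqsar` is for
computational toxicologists and cheminformaticians who want to predict the
binary endpoint — binder (1) vs non-binder (0) — from numerical 2D
molecular descriptors (e.g. the ~777-column Mold² table exported as CSV),
and to validate such models rigorously.

## The model

A **Decision Forest** (DF) is a consensus of `n_trees` (default 5)
CART-style classification trees forced to be heterogeneous: tree *k* may
only split on descriptors unused by trees 1..*k−1*, so the trees'
descriptor sets are pairwise disjoint. Each tree is grown by maximising the
weighted decrease of the two-class Gini index *G* = 1 − p₁² − p₀²
(minimum node size to split 10), then pruned bottom-up within its bottom 3
levels, guided by the training misclassification count. The consensus
probability *p* is the mean of the trees' leaf binder proportions; the
call is binder iff *p* ≥ 0.5, and each prediction carries

```
confidence = |p − 0.5| / 0.5  ∈ [0, 1]
```

Validation machinery: repeated 5-fold cross-validation, label-permutation
(y-scrambling) nulls, 20-bin confidence–accuracy profiles, and
informative-descriptor identification by comparing per-descriptor
model-usage frequencies against the top-5% of the permutation background.
A seeded synthetic-data generator reproduces the structure of the study's
(undistributed) descriptor matrix — 125 chemicals, 53:72 class split, 777
raw descriptors with 265 constant and 16 planted informative ones — so the
whole pipeline is testable end to end.

## Worked example

Reproduce the external-validation performance from the published
experimental and predicted calls of the 22-chemical external set shipped
with the package:

```r
library(dfqsar)
calls <- afp_external_calls()
score_predictions(calls$experiment, calls$prediction)
#> accuracy           0.545
#> sensitivity        0.412
#> specificity        1
#> mcc                0.37
#> balanced_accuracy  0.706
```

Of the 17 experimental binders 7 are recovered (sensitivity 0.412) while
all 5 non-binders are recognised (specificity 1), for a balanced accuracy
of 0.706.

Train and evaluate on synthetic data with the default study-shaped
conditions:

```r
spec <- synthetic_spec()                      # 125 x 777, 16 informative
g <- generate_synthetic_dataset(spec)
forest <- df_train(g$dataset)                 # cleanup + scaling + 5 trees
forest
#> df_forest: 5 heterogeneous trees; 49 descriptors used

ext <- synthetic_external_dataset(spec, n_external = 22)
pred <- df_predict(forest, ext$dataset)       # applies the stored scaling
head(pred, 4)
#>   chemical_id         p call confidence
#> 1     ext_001 1.0000000    1 1.00000000
#> 2     ext_002 0.5750000    1 0.15000000
#> 3     ext_003 0.4761905    0 0.04761905
#> 4     ext_004 0.8000000    1 0.60000000

cv <- cross_validate(g$dataset, n_repeats = 10, seed = 7)
cv
#> df_cv: 10 repeats of 5 -fold cross-validation
#>              metric  mean    sd
#> 1          accuracy 0.777 0.033
#> 2       sensitivity 0.738 0.030
#> 3       specificity 0.811 0.053
#> 4               mcc 0.556 0.066
#> 5 balanced_accuracy 0.774 0.031
```

The `p` column is the consensus binder probability, `call` its 0.5
threshold, and `confidence` the distance from the decision boundary folded
onto [0, 1]; the cross-validation summary is the fold-averaged metric mean
± standard deviation over repeats. `permutation_test()`,
`confidence_profile()` and `informative_descriptors()` complete the
validation suite; see the methods vignette
(`vignettes/decision-forest-methods.Rmd`) for the model, its assumptions
and the design choices.

A command-line front end (`inst/cli/dfqsar`) wraps the same functions as
`train | predict | crossval | permtest | confidence | importance | synth`
subcommands, each writing CSV/JSON artifacts plus a run manifest.

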