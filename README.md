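# ckainit

Supervised pretraining of feedforward classifiers by **centered kernel
alignment (CKA)**, for tabular biomedical features — written for the
neuroimaging use case of staging dementia (normal control / mild cognitive
impairment / Alzheimer's disease) from FreeSurfer-style morphometric
measurements, but applicable to any numeric feature table with class
labels.

## The method

A one-hidden-layer softmax network usually starts from random weights, or
from an unsupervised projection (PCA, autoencoder). `ckainit` instead
learns the first layer *supervised*, before backpropagation ever runs.
Given samples `x_i ∈ R^D` and labels `t_i ∈ {1..C}`, a projection
`W ∈ R^{m1×D}` induces Mahalanobis distances
`d²_W(x_i,x_j) = ||W x_i − W x_j||²` and hence a Gaussian kernel
`K_W`. Label structure enters as the binary co-membership kernel `B`
(`b_ij = 1` iff `t_i = t_j`). The pretraining maximizes the centered kernel
alignment

    ρ(K_W, B) = <H K_W H, H B H>_F / (||H K_W H||_F ||H B H||_F),
    H = I − N⁻¹ 1 1ᵀ,   ρ ∈ [0, 1]

by gradient ascent (analytic gradient, backtracking step halving, monotone
by construction), and the optimum `W*` initializes the hidden layer; biases
and the output layer stay random. The mean squared weight per column of
`W*`, `ϱ_d = (1/m1) Σ_u w²_ud`, ranks features by how much the learned
embedding depends on them — a built-in biomarker relevance analysis.

The package also ships the unsupervised baselines (PCA loadings,
single-hidden-layer autoencoder encoder), the full evaluation stack
(confusion matrix, accuracy α, class-wise recall τ^c, one-vs-rest
trapezoidal AUC β^c and their class-weighted average β), stratified
cross-validation tuning of the hidden size by the mean-to-deviation
criterion, a seeded generator of morphometric-like synthetic cohorts
(N = 1993, D = 324 by default, with an intermediate, heterogeneous MCI
class), and a command-line interface.

## Worked example

```r
library(ckainit)

# a small synthetic cohort: 324 features, 3 classes, signal in 20
# subcortical-volume columns
ds <- generate_synthetic(synthetic_spec(
  n_per_class = c(NC = 197L, MCI = 248L, AD = 154L), seed = 3))

# learn the projection (z-scoring is internal; W acts on the z-scored scale)
model <- fit_cka_projection(ds$X, ds$t, m1 = 14, optimizer_config(seed = 3))
model
#> CKA projection model
#>   W: 14 x 324
#>   final alignment rho: 0.872313
#>   accepted steps: 120

# which feature families drive the embedding?
round(group_relevance(model$relevance, feature_groups(ds)), 3)
#>    CV    SV    SA    TA    TS
#> 0.065 0.253 0.054 0.052 0.050
```

The alignment climbs from its PCA start to ρ ≈ 0.87: the projected
geometry agrees strongly with the label partition. The grouped relevance
singles out the subcortical-volume (SV) block — exactly where the generator
planted the class signal — with every noise family sitting several-fold
lower.

Initialize and train the classifier, then evaluate:

```r
Z <- scale(ds$X)                      # the network sees z-scored features
net <- init_network("cka", Z, ds$t, m1 = 14, seed = 3, projection = model$W)
fit <- train_network(net, Z, ds$t, train_config(epochs = 150, seed = 3))
evaluate_classifier(ds$t, predict(fit$params, Z, type = "prob"))
#> Multiclass evaluation (N = 599 )
#>   accuracy alpha: 1
#>   weighted AUC beta: 1
#>   tau:  NC=1.000  MCI=1.000  AD=1.000
#> ...
```

(The network memorizes its own 599-sample training set — these are
training-set numbers. For honest estimates use a held-out split, as
`run_init_experiment()` and the `compare` CLI subcommand do: there, test
accuracy sits around 0.72–0.75 at this effect size.)

The same pipeline from a shell:

```sh
ckainit simulate --out cohort.csv --seed 7
ckainit split --data cohort.csv --out-train train.csv --out-test test.csv --seed 7
ckainit fit-projection --data train.csv --m1 14 --out proj.json --relevance-out rel.csv
ckainit train --data train.csv --projection proj.json --out net.json --seed 7
ckainit evaluate --model net.json --data test.csv --out report.json --csv-out report.csv
```

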