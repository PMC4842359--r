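---
title: "Supervised pretraining by centered kernel alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised pretraining by centered kernel alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckainit)
```

## The problem

Computer-aided dementia staging from structural MRI reduces each scan to a
table of morphometric features — per-structure cortical volumes (CV),
subcortical volumes (SV), surface areas (SA), cortical thickness averages
(TA) and thickness standard deviations (TS) — and asks a classifier to
assign one of three diagnostic groups: normal control (NC), mild cognitive
impairment (MCI) or Alzheimer's disease (AD). The task is hard mainly
because MCI is an intermediate and heterogeneous category: its members sit
between the other two groups and may progress to AD or revert to normal
cognition, so classifiers trained naively tend to sacrifice MCI recall for
NC/AD accuracy (class biasing).

`ckainit` implements a supervised pretraining strategy for a one-hidden-layer
feedforward softmax classifier on such feature tables: before
backpropagation starts, the first layer is set to a linear projection
learned to make the geometry of the projected data agree with the geometry
of the class labels.

## The alignment model

Given samples $x_i \in \mathbb{R}^D$ with labels $t_i \in \{1,\dots,C\}$, a
projection $W \in \mathbb{R}^{m_1 \times D}$ ($m_1 \le D$) induces the
squared Mahalanobis distance

$$d_W^2(x_i, x_j) = (x_i - x_j)^\top W^\top W (x_i - x_j)
                  = \lVert W x_i - W x_j \rVert^2,$$

which feeds a Gaussian kernel $k_{ij} = \exp(-d_W^2(x_i,x_j)/2\sigma^2)$,
giving the feature kernel matrix $K_W$. Label knowledge enters through the
binary co-membership kernel $B$, $b_{ij} = \delta(t_i - t_j)$. The quality
of $W$ is scored by centered kernel alignment,

$$\rho(K_W, B) =
  \frac{\langle HK_WH,\; HBH\rangle_F}{\lVert HK_WH\rVert_F\,\lVert HBH\rVert_F}
  \in [0, 1],
  \qquad H = I - N^{-1}\mathbf{1}\mathbf{1}^\top,$$

and the pretraining solves $W^\star = \arg\max_W \rho(K_W, B)$. $W^\star$
becomes the initial first-layer weight matrix; biases and the output layer
remain randomly initialized, so pretraining decides only where the hidden
representation starts. The projection also yields a per-feature relevance
$\varrho_d = \frac{1}{m_1}\sum_u w_{ud}^2$: since the embedding depends most
on columns of $W$ with large weights, ranking $\varrho$ identifies the
measurements (biomarkers) driving class separation.

### Design choices in the objective

* **Kernel form.** Any positive definite, infinitely divisible kernel fits
  the framework; we fix the Gaussian and, further, fix $\sigma = 1$. The
  bandwidth is redundant during optimization: rescaling $W$ rescales every
  $d_W$, so the ascent can realize any effective bandwidth through the scale
  of $W$. One hyperparameter fewer.
* **Objective scale.** We ascend $\rho$ itself rather than $\log\rho$; both
  have the same maximizers and the gradient check (below) validates the
  implementation directly on $\rho$.
* **Centering.** $HKH$ is computed by row/column/grand-mean subtraction,
  never by materializing $H$, keeping the cost at $O(N^2)$ per kernel.

## The optimizer

`fit_cka_projection()` runs full-batch gradient ascent with backtracking
step halving: a proposed step is accepted only if it increases $\rho$,
otherwise the step is halved (up to 20 times) and retried. Accepted-step
traces are therefore non-decreasing by construction — this is asserted
in the test suite on every seeded run. Defaults: `max_iter = 500`,
`tol = 1e-6` (relative $\Delta\rho$), initial step 1 with cautious
re-expansion (doubling) after each accepted step.

The analytic gradient follows the chain rule through the Gaussian kernel.
With $K_c = HKH$, $B_c = HBH$,
$G = (B_c - \rho \frac{\lVert B_c\rVert}{\lVert K_c\rVert} K_c) /
(\lVert K_c\rVert \lVert B_c\rVert)$ and $M = G \circ K$,

$$\frac{\partial \rho}{\partial W} = -\frac{2}{\sigma^2}\,W X^\top L X,
\qquad L = \operatorname{diag}(M\mathbf{1}) - M,$$

an $O(N^2 D)$ graph-Laplacian contraction. The suite verifies it against
central finite differences (relative error below $10^{-5}$, in practice
$\sim 10^{-9}$) on twenty random instances, and verifies stationarity at a
constructed $\rho = 1$ optimum.

Remaining numerical choices:

* **Initialization.** PCA loadings of the standardized data (deterministic),
  rescaled so the median projected squared distance is 1 — this puts the
  unit-bandwidth Gaussian in its sensitive regime, where kernel entries
  spread over $(0,1)$ instead of saturating. A seeded random start is
  available (`optimizer_config(init = "random")`), and a custom matrix can
  be supplied for controlled experiments.
* **Standardization.** Features are z-scored with training-set statistics
  before projection learning (the model stores center/scale); morphometric
  families live on very different numeric scales (mm, mm², mm³), and an
  isotropic kernel on raw units would be dominated by the largest family.
* **Degenerate inputs.** A constant kernel (e.g. $W = 0$, or all samples
  identical) has zero centered norm; the alignment is undefined and the
  package raises an explicit degenerate-input error rather than returning
  0/0. Relevance of an all-zero projection is an all-zero vector with a
  warning. Relevance ties are broken by ascending feature index when
  ranking.
* **Constraints.** $m_1 \le D$ (the projection must reduce dimension —
  discrimination should come from alignment, not from inflating the space)
  and $N > m_1$ (with fewer samples than output dimensions the projection
  memorizes the sample); both are hard errors.

## The classifier

The network is $D \to m_1 \to C$: hidden sigmoid layer
$\phi(z) = (\tanh z + 1)/2$, softmax output read as
$P(t = c \mid x)$, trained by minibatch SGD on the mean negative conditional
log-likelihood $-\frac{1}{N}\sum_i \log P(t_i \mid x_i)$ (probability floor
$10^{-12}$). A formulation of the softmax loss sometimes written as
$-\log \sum_c P(t=c\mid x)$ is identically zero because the probabilities
sum to one; the per-target conditional form is what training minimizes
here. Backpropagation is verified against finite differences like the CKA
gradient. Defaults: learning rate 0.05, batch 32, 300 epochs, optional
patience-based early stopping on a seeded 10% held-out split. Random
parameters are uniform $(-1/\sqrt{f}, 1/\sqrt{f})$ with $f$ the fan-in.
Labels are 1-based at every user-facing surface.

Unsupervised baselines implement the same `m1 × D` contract: `pca_projection()`
(top principal-axis loadings, sign-fixed so each row's largest-magnitude
entry is positive) and `aen_fit()` (single-hidden-layer autoencoder:
sigmoid encoder, linear decoder, untied weights, MSE loss, seeded SGD,
200 epochs at learning rate 0.05 — the classical reconstruction-based
initialization).

## Evaluation

`evaluate_classifier()` reports the confusion matrix, accuracy
$\alpha = \operatorname{tr}(\text{confusion})/N$, class-wise true positive
rate $\tau^c = t_p^c / N^c$, per-class one-vs-rest AUC $\beta^c$
(trapezoidal, over all score thresholds, tied scores grouped — equal to the
normalized Mann–Whitney $U$ statistic, which the tests assert), and the
class-size-weighted $\beta = \sum_c \beta^c N^c / \sum_c N^c$. Note a
one-vs-rest accuracy of the form $\sum_c (t_p^c + t_n^c) / \sum_c N^c$
would exceed 1 for $C > 2$ (every correct sample is also a true negative
for the other classes), so the trace form is the meaningful multiclass
accuracy and the one implemented.

Hidden-size tuning (`tune_hidden_size()`) is an exhaustive grid search
under stratified 5-fold cross-validation, selecting the size with the
highest mean-to-deviation ratio mean/(sd + 1e-8) of fold accuracies — the
most accurate *and* stable configuration — with ties broken toward the
smaller network. The tuned size is data-dependent output, not a constant of
the method.

## The synthetic generator

Restricted clinical data cannot ship with a package, so `synthetic_spec()` /
`generate_synthetic()` emulate the shape of the real problem: 324 features
in families of 70/42/72/70/70 (CV/SV/SA/TA/TS), three classes of
655/825/513 samples ($N = 1993$), class-conditional Gaussian draws. Only a
designated informative block (default: the first 20 SV columns) carries
signal: NC and AD means separated by 1.5 within-class standard deviations
per informative feature, the MCI mean midway (`mci_position = 0.5`), and
MCI's standard deviation inflated 2× on those features — an explicit,
controllable rendering of "intermediate and heterogeneous". The 1.5σ
per-feature effect across ~20 features makes NC vs AD nearly separable
while leaving MCI genuinely overlapping, which reproduces the qualitative
error structure of the clinical task (MCI absorbs most confusion). An
optional low-rank noise mode (`noise_cov = "lowrank"`) adds shared factors
for correlated-measurement realism.

What the generator does **not** emulate: real anatomical covariance
structure, site/scanner effects, head-size normalization artifacts,
demographic covariates, label noise in clinical diagnoses. Passing tests on
this generator therefore demonstrate correctness and the qualitative
behavior of the method, not clinical performance; the headline accuracies
reported on restricted cohorts are not reproducible from synthetic data and
the package does not attempt to match them numerically.

## Experiment sizes

The shipped experiments run at sizes chosen to keep a laptop-class full run
comfortable while leaving the effects resolvable:

* Gradient checks: $N \le 10$, $D \le 5$, twenty instances.
* Relevance recovery: 10 informative of 50 features, effect 1.5σ,
  $N \approx 210$ per draw, twenty seeds; top-10 precision is averaged.
* Initialization comparison (`run_init_experiment()`): one full-size cohort
  ($N = 1993$, $D = 324$), stratified 70/30 split, $m_1 = 14$, CKA vs
  random initialization over twenty training seeds with 150 epochs each.
  The comparison deliberately fixes the cohort and varies only the seeded
  randomness of the non-pretrained parameters and the minibatch order: the
  CKA and PCA projections are deterministic given the data, so refitting
  them per seed would re-measure the same matrix, and the full cohort keeps
  the projection in its intended operating regime — the method assumes
  clearly more training samples than input dimensions (here
  $N_{\text{train}} \approx 1395 > 4D$ would fail at small fractions of the
  cohort). The experiment reports seed-averaged accuracy, per-class recall
  and one-vs-rest AUC per strategy, plus the recall spread
  $\max_c \bar\tau^c - \min_c \bar\tau^c$ as the class-biasing summary.
  The 150-epoch schedule (half the single-fit default) keeps the 40-network
  run comfortable on one core.

## Known limitations

* The CKA fit is full-batch: $O(N^2)$ kernels and an $O(N^2 D)$ gradient
  per iteration make $N$ in the low thousands the practical ceiling; no
  Nyström or minibatch approximation is provided.
* $\rho$ is non-concave in $W$; the ascent finds a local maximum that
  depends on the (deterministic) initialization. The backtracking contract
  guarantees monotone improvement, not global optimality.
* One hidden layer only, plain SGD; deep stacks, momentum/Adam and learning
  the kernel bandwidth jointly are out of scope, as is using alignment as
  the training loss itself rather than for initialization.
* The evaluation assumes softmax probabilities; margin-based classifiers
  would need a score convention before the ROC machinery applies.
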