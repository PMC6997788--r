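---
title: "Capsule networks for hERG blockade classification: models and methods"
author: "hergcaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule networks for hERG blockade classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blockade of the hERG potassium channel prolongs cardiac repolarization
(long QT syndrome) and is a major cause of drug withdrawal, so candidate
molecules are screened in silico for hERG liability early. `hergcaps`
implements two capsule-network classifiers of hERG blockers (IC~50~ < 10
µM) versus nonblockers, trained on a 179-component molecular
characterization: the 166 MACCS structural keys plus 13 physicochemical
descriptors, min-max scaled to [0, 1] on the training set.

Two architectures share one capsule head and differ only in the feature
extractor:

* **Conv-CapsNet** — 1-d convolution (32 filters, width 3, stride 1, no
  padding) over the 179-vector, ReLU, batch normalization, a 128-node
  dense hidden feature layer (ReLU, batch normalization), a 64-node dense
  PrimaryCaps layer reshaped into 8 capsules of 8 dimensions.
* **RBM-CapsNet** — two dense layers 179→256→128 initialized from a
  greedily pretrained stack of two restricted Boltzmann machines, the
  128-node layer reshaped into 16 capsules of 8 dimensions.

## Capsule head

Each primary capsule $u_i$ contributes a prediction vector
$\hat{u}_{j|i} = W_{ij} u_i$ to each of the two output (digit) capsules.
Dynamic routing assigns these contributions by agreement: logits
$b_{ij}$ start at zero every forward pass, and each pass computes

$$c_{ij} = \frac{\exp b_{ij}}{\sum_k \exp b_{ik}}, \qquad
  s_j = \sum_i c_{ij}\,\hat{u}_{j|i}, \qquad
  v_j = \frac{\lVert s_j\rVert^2}{1+\lVert s_j\rVert^2}
        \frac{s_j}{\lVert s_j\rVert},$$

followed by the agreement update
$b_{ij} \leftarrow b_{ij} + \hat{u}_{j|i}\cdot v_j$, which runs inside
every pass including the last (it is simply unused after the final pass).
Both architectures use 2 routing iterations. The length of each output
capsule is the class probability; prediction takes the longer capsule
(exact ties go to class 0) and the length of the blocker capsule is the
ROC score.

Training minimizes the margin loss on capsule lengths,

$$L_k = T_k \max(0, m^+ - \lVert v_k\rVert)^2
      + \lambda (1-T_k)\max(0, \lVert v_k\rVert - m^-)^2,$$

with $m^+ = 0.9$, $m^- = 0.1$, $\lambda = 0.5$ (the originating
capsule-network defaults; exposed in `margin_loss_params()`), summed over
classes and averaged over the mini-batch. Conv-CapsNet adds an L2 penalty
`l2 * sum(CW^2)` on the convolution weights (coefficient 0.001; the scope
can be widened to all weights via `l2_scope = "all"`).

Gradients flow through the *unrolled* routing iterations — through the
softmax, the weighted sums, the squash, and the agreement updates — not
just through the final pass. The backward pass is hand-derived and checked
against central finite differences on small networks in the test suite.

### Numerical choices

* The squash forward needs no epsilon: $s\,\lVert s\rVert /
  (1+\lVert s\rVert^2)$ contains no division, so `squash(0)` is exactly 0
  and capsule lengths are exact. Guards of $10^{-12}$ appear only in
  backward-pass denominators (the $1/\lVert s\rVert$ factor of the squash
  Jacobian and the $1/\lVert v\rVert$ of the length gradient). An
  epsilon placed *inside* the norm would dominate at initialization,
  where squash outputs are $\sim 10^{-4}$ (the map is quadratic near the
  origin), and measurably corrupt gradients.
* Batch normalization sits after each of the convolution and hidden-layer
  ReLUs; batch statistics (biased variance) are used in training,
  exponential running averages (momentum 0.9, $\epsilon = 10^{-5}$) in
  inference.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$.
* Weights are initialized from a truncated normal (sd 0.01, truncated at
  $\pm 2$ sd, inverse-CDF sampling so seeds reproduce exactly); biases are
  zero; batch-norm scales are one.
* The last partial mini-batch of each epoch is used, not dropped; the
  sample order is reshuffled each epoch from the run seed.

## RBM pretraining

An RBM with visible biases $a$, hidden biases $b$, and weights $\omega$
has energy $E(v,h) = -(a^\top v + b^\top h + v^\top \omega h)$. The stack
is pretrained greedily by one-step contrastive divergence (CD-1): logistic
hidden probabilities, Bernoulli hidden samples, mean-field visible
reconstruction, and the gradient
$\langle v h^\top\rangle_{\text{data}} -
 \langle v h^\top\rangle_{\text{recon}}$ applied by plain SGD at the RBM
learning rate (0.001, 100 epochs). Min-max-scaled features in [0, 1] are
treated as Bernoulli probabilities on the visible units — standard
practice for continuous inputs in this range. The second RBM trains on
the first RBM's hidden probabilities. At assembly, each dense layer takes
$(\omega, b)$ from its RBM (visible biases have no feed-forward analogue
and are dropped), the routing weights are drawn fresh, and the whole
network fine-tunes end-to-end with ReLU activations (the sigmoids are a
pretraining device only) under Adam at 0.005 for up to 200 epochs.

A note on shapes: the 128-node PrimaryCaps layer with 8-dimensional
capsules yields 16 primary capsules, so the routing-weight array is
16×2×8×2. (A figure caption in the source material says 8×8×2×2, which is
inconsistent with its own node counts; the node-count arithmetic wins.)

## Training protocol

Early stopping holds out a stratified validation fifth (4:1) when no
validation set is supplied, monitors the validation margin loss, and stops
after `patience` consecutive epochs without a new best, restoring the
best epoch's parameters. The default patience is 5: under Adam the
validation loss fluctuates transiently on the initial plateau (the first
epochs in which the network still predicts the majority class), and a
patience of 1 reproducibly halts there with an untrained model —
observable directly in the training history. Patience remains fully
configurable, including 1 for the strictest reading of
"stop at the first non-improving epoch".

Model selection uses stratified five-fold cross-validation
(`kfold_cv()`): each fold is held out once, per-fold Q/SE/SP/MCC/AUC are
reported with their mean and standard deviation, and `grid_search()`
ranks hyperparameter combinations by mean Q (ties: mean MCC, then
declaration order). Folds are stratified by class — random fold sizes on
a few hundred compounds otherwise make small-fold metrics noisy — with a
round-robin counter that continues across classes so total fold sizes
differ by at most one.

## Molecular characterization

`compute_maccs()` computes the 166 MACCS keys with Open Babel's SMARTS
definitions (via ChemmineOB); the benzene bit pattern matches an
independent MACCS implementation exactly, and the suite asserts it.
`compute_descriptors()` produces, in fixed order: logP, logD~7.4~, logS,
molecular weight (Da), H-bond donors, H-bond acceptors, rotatable bonds,
rings, aromatic rings, N+O count, polar surface area (Å²), fractional
PSA, and molecular surface area (Å²). Three descriptors that commercial
tools compute with proprietary algorithms are replaced by documented open
estimates:

* **logD~7.4~** — Crippen logP with a Henderson–Hasselbalch single-group
  ionization correction: −3.4 for a carboxylic acid (pK~a~ ≈ 4), −2.6 for
  a basic aliphatic amine (pK~a~ ≈ 10), detected by SMARTS.
* **logS** — the ESOL estimate
  $0.16 - 0.63\,\text{logP} - 0.0062\,\text{MW} + 0.066\,\text{RotB}
  - 0.74\,\text{AP}$ with AP the aromatic fraction of heavy atoms.
* **Molecular surface area** — an additive per-element contribution model
  (a Labute-style accessible surface area), with coefficients fit once by
  least squares against a reference accessible-surface implementation on
  a 46-molecule panel (R² ≈ 0.999) and frozen in the package.

These estimates preserve the rank information the classifier consumes;
users needing exact commercial descriptor values can supply a precomputed
feature CSV (`id,f001..f179`), which every command accepts in place of
SMILES. Ring counts are the smallest set of smallest rings (ChemmineR
perception). Min-max scaling (`fit_scaler()`/`apply_scaler()`) is fitted
on training rows only; constant features map to 0 (the division would
otherwise be 0/0), and unseen-data values outside the training range are
clipped to [0, 1] so network inputs stay in the trained range. All 179
features are scaled; bits present in both states pass through unchanged.

## Synthetic data

The reference hERG corpus (2,389 training compounds, 1,004 blockers; test
n = 255; external n = 60) is distributed on request only, so the package
carries a generator (`generate_dataset()`) that emulates the *statistical
shape* of its inputs: 166 Bernoulli bits plus 13 descriptors in [0, 1],
with a class-separability dial. Informative bits (default 40) have class
rates $0.5 \pm \delta$, $\delta = \min(\text{separation}/4,\,0.45)$;
uninformative bits are Bernoulli(0.3); informative descriptors (default
6) are Gaussian with class means $\pm\text{separation}/2$ at unit
variance, min-max scaled; the rest are Uniform(0, 1). The default
composition mirrors the corpus (positive fraction 1004/2389); the default
separation of 3 gives a clearly learnable problem, and separation 0
removes all signal (a trained model must fall to chance). The generator
writes the same CSV dialect as the featurizer, so synthetic and real data
are interchangeable downstream.

What it does **not** emulate: real fingerprint bit correlations,
substructure logic, descriptor covariance, or activity cliffs. Passing
the learnability checks therefore demonstrates that the architectures,
gradients, and training protocol work — not that the published accuracy
on the real corpus is reproduced. With user-supplied real data,
`cv`/`evaluate` compute every column the reference tables report
(SE/SP/MCC/SD/Q and AUC).

## Problem sizes and verification

The test suite verifies the routing implementation against an independent
straight-line transcription (100 random small tensors, 1e-9), all
analytic gradients against central finite differences on reduced
architectures, the rank AUC against a brute-force pairwise count and
against pROC, and the scalar metrics against the published confusion
counts of both models on the reference test and external-validation sets.
Learnability runs use n = 2000 at separation 3 and 0 with a 25% holdout,
the scale at which both architectures comfortably separate signal from
noise within a couple of minutes on one CPU; `scripts/acceptance.R`
re-runs those conditions from scratch.

## Known limitations

* Descriptor values are open approximations, not PaDEL/commercial
  replicas; absolute values of logD/logS/MSA differ from those tools even
  though ranks are similar (Non-goal: exact numeric replication).
* OpenBabel and other MACCS implementations can disagree on a few keys
  for fused heteroaromatics (aromaticity models differ).
* The published headline accuracies on the reference corpus cannot be
  checked without the request-only data; the harness computes them when
  the data are supplied.
* Training is plain R + BLAS; it is sized for thousands of compounds, not
  millions.
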