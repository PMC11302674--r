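---
title: "Semi-supervised switching dynamical systems for action segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised switching dynamical systems for action segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s3lds)
```

## The problem

Action segmentation assigns a discrete behavior class to every frame of a
behavioral recording — a fly walking, grooming or standing still; a mouse
rearing; a human walking or sitting. Dense manual annotation does not scale,
so this package implements a family of models that can exploit the large
unlabeled majority of frames alongside a sparse set of hand labels:

* a fully supervised dilated **temporal convolutional network (TCN)**
  classifier;
* a semi-supervised **switching (non)linear dynamical system** (S³LDS /
  S³NLDS) trained by amortized variational inference on labeled and unlabeled
  frames together;
* the static **Gaussian-mixture deep generative model** (GMDGM) and the
  GMDGM-TCN hybrid, which ablate the temporal structure of the generative
  model and of the posterior respectively.

## Generative model

Let `y_t ∈ {0, …, K−1}` be the discrete behavior state, `z_t ∈ R^Dz` a
continuous latent, and `x_t ∈ R^Dx` the observed behavioral features. The
switching model factorizes as

```
p(x_1:T, y_1:T, z_1:T) = p(x_1|z_1) p(z_1) p(y_1)
                         ∏_t p(x_t|z_t) p(z_t|z_{t−1}, y_t) p(y_t|y_{t−1}, z_{t−1})
```

with

* `p(y_1) = Cat(π)`, `p(z_1) = N(0, I)`;
* latent dynamics `p(z_t|z_{t−1}, y_t) = N(A_{y_t} z_{t−1} + b_{y_t}, Q_{y_t})`;
* recurrent transitions
  `p(y_t|y_{t−1}, z_{t−1}) = Cat(softmax(R_{y_{t−1}} z_{t−1} + r_{y_{t−1}}))`;
* a shared emission `p(x_t|z_t) = N(g(z_t), S)`, where `g` is linear or a
  one-hidden-layer network.

Setting `R_k = 0` recovers the plain switching linear dynamical system;
replacing the dynamics and transition maps with one-hidden-layer networks
gives the nonlinear variant. Every generative nonlinearity uses exactly one
hidden layer whose width equals `Dz`. The emission noise `S` is shared across
states, matching the emission factor of the switching model as implemented.

The static GMDGM drops all temporal coupling:
`p(x, y, z) = p(x|z) p(z|y) p(y)` with `p(z|y) = N(f(y), diag σ²(y))` — an
explicit per-class clustering mechanism in the latent space.

## Amortized posteriors

The joint posterior factorizes per frame as
`q(y_t, z_t | x) = q(y_t | x_W(t)) q(z_t | x_W(t), y_t)`, where `x_W(t)` is a
window of frames centered at `t`. Both factors are heads of dilated TCNs:
the classifier head outputs K logits per frame, and the encoder outputs a
`(μ, log σ²)` pair *per class* via K parallel heads on a shared trunk, so a
single forward pass provides all class-conditional Gaussians the unlabeled
objective needs. The classifier factor doubles as the frame classifier used
at prediction time. The static ablation replaces the TCN trunk with a
per-frame dense network; the GMDGM-TCN hybrid keeps the temporal posteriors
with the static generative model.

The default backbone has 2 dilation blocks of 2 sub-blocks (convolution →
leaky ReLU → dropout 0.10) with 32 filters, symmetric kernels spanning ±4
lags, dilation doubling per block, and a residual connection per block. Its
receptive field half-width is

```
τ = lags × sublayers × Σ_b 2^(b−1) = 4 × 2 × 3 = 24 frames,
```

i.e. a 49-frame window: 0.70 s at 70 Hz, 1.96 s at 25 Hz, 0.82 s at 60 Hz.
Sequence edges are zero-padded so every frame gets an output.

## Objectives

With every frame labeled, the evidence lower bound is the usual sum of a
reconstruction term (one reparameterized sample per frame), the KL of
`q(z_1)` from the standard-normal initial prior, the KLs of `q(z_t)` from the
state-conditional dynamics prior evaluated at the previous frame's sample,
and the initial-state and transition log probabilities. With no labels, each
term is marginalized over the classifier posterior, at a cost of K² KL
evaluations per frame for the dynamics term.

The semi-supervised loss substitutes, at every labeled frame, a one-hot
vector for the classifier posterior inside the unlabeled bound — each
marginalized term reduces exactly to its labeled counterpart under one-hot
weights — and adds a classification term
`α Σ_{labeled} w_{y_t} log q(y_t | x)` with `α = 100` and class weights `w`
inversely proportional to the labeled class frequencies (normalized to mean
one; the proportionality is the published choice, the normalization is
ours — it keeps `α` comparable across datasets). The classifier appears in
the unlabeled terms only, which is why the explicit classification term is
needed at all.

For the static model, the labeled bound is the three-term VAE-style bound
per frame, and the unlabeled bound is its class-weighted sum **plus** the
entropy of the classifier posterior. The sign of the entropy term is forced
by the algebra of the marginalized bound (`−E_q log q(y|x) = +H`), and we
verify it against a brute-force Monte-Carlo estimate of the joint
expectation in the acceptance suite.

Numerical choices: all Gaussian factors are diagonal, so every KL is
analytic; encoder log-variances are clamped to [−10, 10]; softmax and
log-sum-exp are max-shifted; one reparameterized sample per (frame, class)
per evaluation (the single-sample estimator — the sample count is not
prescribed by the protocol, and one sample keeps the cost linear in K for
the reconstruction term). The per-class noise array is shared by every
objective entry point so that one-hot substitution reproduces the labeled
bound term by term, not just in total.

## Training protocol

Adam with learning rate 1e-4; batches of 8 sequences of 1000 contiguous
frames (sessions are cut into non-overlapping chunks; shorter sessions are
kept whole, and each chunk is zero-padded at its own boundaries); 500 epochs
by default. The KL and discrete-state terms are annealed linearly from 0 to
1 over the first 100 epochs; reconstruction and classification are never
annealed. 10% of chunks are held out and the best-validation checkpoint is
kept (validation uses annealing weight 1 and a fixed noise seed, so
checkpoint selection compares a consistent objective). Features are
z-scored per column with training-split statistics stored in the
checkpoint — the protocol does not specify standardization, but Gaussian
emissions with a shared covariance behave poorly on heterogeneous feature
scales. A non-finite loss aborts with the name of the offending term.

Generative initialization for the switching models: `A_k = 0.99 I`,
`b_k ~ N(0, 0.01)`, `Q_k = 0.1 I`, zero recurrence, uniform `π`, and the
emission map initialized from the top-`Dz` PCA loadings of the training
features — a standard initialization for switching-model fitting. `Dz`
itself defaults to the number of principal components explaining 95% of the
feature variance.

Gradients flow through the entire objective — both posterior networks and
all generative parameters — via a small reverse-mode automatic
differentiation engine built into the package (dense-matrix nodes, BLAS
matmuls, a fused dilated-convolution node). Every operation's backward pass
is tested against central differences.

## Feature engineering

Inputs are per-frame feature tables: plain CSV, or DeepLabCut pose exports
(three header rows; likelihood columns are dropped rather than thresholded —
occlusion handling belongs upstream in pose post-processing).
`add_velocity()` concatenates first differences, turning positions `x_t`
into position-velocity features `[x_t; x_t − x_{t−1}]`; the first frame's
velocity is zero, which keeps T unchanged and is exact for a still start.
Labels are one integer per frame with `−1` for unlabeled and `−2` for
background frames; background frames are treated as unlabeled by every
objective and excluded from every score, so models are never trained to
predict a background class.

## Synthetic data and what the tests show

The ancestral samplers double as the synthetic-data generators for the whole
test suite. The documented preset (`rslds_preset("two_state")`) is a sticky
two-state model with `Dz = 2`, `Dx = 4`: contractive linear dynamics
(`A = 0.9 I`) toward fixed points at ±(1, 1), latent noise `0.02 I`,
emission noise `0.1 I`, and 0.98 self-transition probability, giving a mean
dwell time of 50 frames — comparable to the bout lengths annotators actually
label. Label masking keeps contiguous 50-frame blocks, mimicking bout-wise
annotation.

The pipeline regression checks train on one simulated session of 20,000
frames with 10% of frames labeled, 200 epochs, and score a held-out session
of 4,000 frames; the label-budget trend uses sessions of 6,000 frames, 60
epochs (annealing over 30), fractions {5%, 20%, 100%} and three seeds. The
bound-dominance checks use instances small enough (K ≤ 3, T ≤ 5) for exact
enumeration over all discrete sequences with a Kalman filter per sequence;
the enumeration oracle itself is validated against dense joint Gaussians and
2-D numerical quadrature. The oracle deliberately excludes recurrent
transitions, where exact marginals are intractable; for recurrent models the
exact one-hot reduction identity plays that role.

Passing these tests shows the implementation optimizes the objective it
claims to optimize and recovers planted structure in well-separated
low-dimensional data. It does not show that the model separates real
behavioral data, where class boundaries are ambiguous, noise is structured
and non-Gaussian, and annotators disagree; nor does the synthetic preset
emulate occlusions, tracking errors, or class imbalance beyond what the
sticky transitions induce.

## Known limitations

* Diagonal covariances throughout the objectives (`Q_k`, `S`); full
  covariances are accepted by the samplers and densities but not by the
  analytic KLs used in training.
* The enumeration oracle is exponential in T and refuses K^T > 1e6.
* Training is CPU-bound R; it is sized for the simulation studies above
  (minutes per fit), not for million-frame datasets.
* Sticky/hierarchical priors over the number of discrete states are out of
  scope; K is fixed by the user.

## A complete run

```{r, eval = FALSE}
pre <- rslds_preset("two_state")
traj <- sample_rslds(pre$params, 10000, seed = 1)
labels <- mask_labels(traj$y, 0.1, seed = 2)
sessions <- list(list(features = feature_sequence(traj$x),
                      labels = label_sequence(labels, pre$class_names)))
fit <- train(sessions, train_config("s3lds", n_epochs = 100, seed = 1))
test <- sample_rslds(pre$params, 2000, seed = 3)
pred <- predict_states(fit, feature_sequence(test$x))
f1_report(pred$states, label_sequence(test$y, pre$class_names))$macro_f1
```
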