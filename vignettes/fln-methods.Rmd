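---
title: "Fast learning networks for binary tumor classification: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast learning networks for binary tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flnet)
```

## The model and its assumptions

A fast learning network (FLN) is a double-parallel feedforward network:
a randomized single-hidden-layer network augmented with a direct linear
path from the inputs to the outputs. For `n` features, `m` hidden nodes
and `l` classes the score vector of a sample `x` is

$$y = W^{oi} x + W^{oh}\, g(W^{in} x + b),$$

with $W^{in} \in [-1,1]^{m\times n}$ and $b \in [0,1]^m$ drawn uniformly
at random once and frozen, output biases fixed at zero, and $g$ the
hidden activation. Training never touches the random layer: writing
$H = [X; G]$ for the scaled training inputs stacked on the hidden
activations (both with samples as columns) and $Y$ for the one-hot
targets, the trained weights are the joint least-squares optimum

$$\widehat W = [W^{oi}\ W^{oh}] = Y H^{+},$$

computed by SVD pseudoinverse. The direct input–output block matters:
any target that is linear in the features is representable exactly by
$W^{oi}$ alone, so the hidden layer only has to model the nonlinear
remainder. That is why the package's linear-probe fixture must fit with
numerically zero residual, and why small hidden layers suffice on
near-linearly-separable tumor data.

Assumptions worth stating: samples are i.i.d. rows with no missing
values after ingestion; classes are coded `1..l` with class 1 the
positive (malignant) class throughout the metric suite; and the model is
purely offline — no incremental updates, no refinement of the random
weights (both deliberately out of scope).

## Tunable parameters

* `hidden_count` (`m`, default 25) — the only structural knob. The
  evaluation protocol sweeps 25–200 in steps of 25; on both tumor
  schemas the smallest width wins, and accuracy degrades as `m` grows
  because the least-squares fit starts chasing noise in the widened
  random basis.
* `activation` — hidden `g(·)`, default the logistic sigmoid
  `1/(1+e^{−z})`. The FLN formulation does not prescribe `g`; logistic
  is the conventional choice for randomized single-hidden-layer
  networks and keeps `G` entries in (0, 1). `tanh` and `relu` are
  available as alternatives. The output activation is the identity,
  which is the only choice consistent with solving `Y = Ŵ H` as a
  linear least-squares problem.
* `scale_features` (default `TRUE`) — min-max scaling to [0, 1] learned
  on the training partition, stored in the model, applied with clipping
  to new data. The raw feature ranges of the 30-feature schema span four
  orders of magnitude (area reaches 4254 while fractal dimension stays
  below 0.21); unscaled, those columns saturate the sigmoid and dominate
  the least-squares objective. Constant features map to 0. The flag
  exists so pre-scaled data can bypass the rule.
* `pinv_cutoff` (default 1e−12, relative) — singular values below
  `cutoff × σ_max` are treated as zero. `ridge` (default 0) switches to
  a regularized normal-equations solve for deliberately ill-conditioned
  problems.
* `seed` — one seeded generator per fit; the weight matrix is drawn
  before the bias vector, row-major, so fits are bit-reproducible across
  processes.

## The evaluation protocol

Each experiment is a hidden-node count; each run is a fresh stratified
70/30 holdout (per class: seeded shuffle, then round-half-up of
0.30 × class size to test — the only rounding rule consistent with all
four published per-class test counts, 72/133 and 64/107). Per run the
test confusion matrix yields accuracy, precision, recall, specificity,
F-measure, G-mean, MCC and the single-operating-point AROC
`(sensitivity + specificity)/2`; the threshold-sweep `roc_curve()` is
available separately for continuous scores. Whether the original
protocol re-split per run or fixed one split is not determinable from
its description; the default here is a fresh split per run (the run
index offsets the base seed), with `reshuffle_per_run = FALSE` for the
fixed alternative.

Runs aggregate per metric on the percent scale as mean, RMSE about the
optimum `o = 100`, and population (divide-by-N) standard deviation. The
percent scale and the divide-by-N convention are forced by the algebraic
identity `rmse² = (o − mean)² + std²`, which the published 25-node
accuracy row satisfies to 0.01 and which every aggregation in this
package satisfies to 1e−9 — it is asserted as an invariant. The best run
is the one maximizing accuracy, ties broken by higher MCC and then lower
run index (the tie-break is this package's choice; the protocol leaves
it unstated). Wall-clock time is recorded per run but excluded from all
assertions — it is hardware, not science.

Zero-denominator metric ratios (e.g. precision with no positive
predictions) are defined as 0 and the affected names recorded in the
report's `flagged` field, so 50-run batches never abort on a degenerate
draw.

One documented ambiguity: the published best-run tables report
precision/recall/specificity values that correspond to a transposed
reading of the underlying confusion matrices (their printed "precision"
98.61 equals TP/(TP+FN) = 71/72 under standard definitions). This
package reports standard-convention names only; accuracy, F-measure,
G-mean, MCC and AROC agree with the printed values under either reading
and are the figures used for cross-checks.

## The synthetic generator

`synth_dataset()` emulates the two schemas' surface statistics: nine
integer cytology features in 1..10 (`wbcd_like`) or thirty real
cell-nucleus features each confined to its observed range (`wdbc_like`).
Each feature is an independent truncated normal with standard deviation
one tenth of the schema range; the class means sit `separation` pooled
standard deviations apart along every feature, benign low and malignant
high, mirroring the real data's direction. Integer features are rounded
and clipped; continuous features are truncated to their ranges. Defaults
are 70 malignant / 130 benign (the real datasets' ≈35% malignant mix)
and `separation = 3` — strongly but not perfectly separable, chosen once
to echo how separable the real Wisconsin data are (published mean
accuracies sit at 96–99%).

What the generator does *not* emulate: inter-feature correlation (real
cytology features are strongly correlated), class-conditional skew, and
label noise. Consequently a passing test suite demonstrates the
machinery — closed-form optimality, protocol determinism, metric
correctness, schema conformity — not clinical performance; synthetic
separable data are *easier* than the real datasets, and sweeps on them
saturate near 100%. Reproducing the published real-data means requires
the original UCI files, which this package deliberately does not ship or
download; `read_wbcd()`/`read_wdbc()` accept them if present.

## Numerical choices

* Samples are columns internally (matching the `m×N` hidden-output
  convention); the public interface is samples-as-rows and converts at
  the boundary.
* The pseudoinverse truncates singular values at a *relative* cutoff, so
  rank-deficient `H` (e.g. a constant feature mapped to 0 by the scaler)
  yields the minimum-norm solution rather than an error.
* Oracle testing: the SVD route is verified against two independently
  coded least-squares solvers — a dense QR solve on the transposed
  system everywhere, and the ridge-limit normal equations on instances
  whose conditioning keeps that oracle meaningful. Forming `H Hᵀ`
  squares the condition number, so normal-equations agreement at 1e−8 is
  only asserted where `cond(H) < 3×10³`; the comparison instances are
  sized (more raw features than hidden nodes, `N` well above `n+m`) to
  keep conditioning in that regime. When `rank(H) = N` the fit must
  interpolate: the training residual bound 1e−6 is asserted on seeded
  full-rank instances.
* Ties in the argmax decision rule go to the smaller class index,
  deterministically.
* Model serialization writes 17 significant digits, which round-trips
  IEEE doubles bit-exactly; the round trip is asserted with `identical()`.

## Problem sizes in the test suite

Tests run on generated data at the published class sizes (683 and 569
samples) for protocol checks, 8–50 samples for oracle instances, and
10 seeds × 200 samples for the separable-recovery property; the full
suite completes in well under a minute. The acceptance script runs the
complete 8 × 50 sweep on both schema stand-ins — 800 fits — in a few
seconds, so the published protocol's scale (50 runs per experiment) is
used as-is rather than scaled down.

## Known limitations

* Binary metric suite only; the network itself is multiclass-capable
  (one-hot targets, argmax decision), but macro/micro averaging is not
  provided.
* No confidence intervals on metrics; the protocol's mean/RMSE/STD are
  descriptive, not inferential.
* The random hidden layer is never optimized — by design; metaheuristic
  weight tuning is listed as future work for the method and is out of
  scope here.
* `wbcd_like` data at low separation can collapse a feature to a single
  observed value in a small training partition; the scaler's
  constant-feature rule (map to 0) plus the relative pseudoinverse
  cutoff make this a no-op rather than a failure.
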