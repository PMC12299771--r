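---
title: "Methods: models, optimizers and design choices in polygru"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, optimizers and design choices in polygru}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polygru` classifies polymers (plastics, peptides, oligosaccharides, or
any set of class strings) from molecular structure. This vignette
describes each model in the pipeline, its assumptions, the tunable
parameters that matter, the numerical conventions, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Featurization

A molecule's SMILES string is parsed by OpenBabel (through `ChemmineOB`)
and hashed into a circular-substructure (Morgan-type / ECFP) fingerprint:
every atom-centred environment up to `radius` bonds sets a position in a
fixed-width hash. The backend hashes to 4096 positions; `polygru` folds
these onto `nBits` positions by modular OR. Defaults are `nBits = 2048`
and `radius = 2` (the ECFP4 diameter convention) — the de facto standard
2048-bit molecular representation. Binary presence bits, not counts, are
used.

Two conventions are worth noting:

* **Strict parsing.** An unparsable SMILES aborts the run with all
  offending row numbers, rather than being dropped silently: silent drops
  would desynchronize rows from labels, which is unacceptable in a
  supervised pipeline. A light syntactic screen (balanced parentheses and
  brackets) backs up the parser, which otherwise truncates some malformed
  inputs without complaint.
* **Stereochemistry.** `useChirality = FALSE` strips the SMILES stereo
  markers (`@`, `/`, `\`) before parsing. The backend's circular hash is
  largely insensitive to tetrahedral chirality anyway, so this flag
  mainly guards against spelling-level differences.

## Preprocessing

Per feature, in this fixed order: (1) missing values are imputed with the
feature median; (2) values are winsorized at the 1st and 99th empirical
percentiles (linear-interpolation quantiles, type 7, computed on the
imputed values); (3) values are Z-scored with the mean and *population*
standard deviation of the capped values. All statistics are learned on
the training split only and carried in a `ScalerState` whose provenance
tag records what it was fit on; the held-out split is transformed with
the training statistics (no leakage, asserted by a pipeline test that
corrupts the test rows and checks the fitted artifacts are unchanged).

Choices made here: impute-first ordering (so percentiles are computed on
complete columns); population rather than sample standard deviation
(matches the standard Z-score definition); constant features map to 0
rather than NaN, keeping downstream linear algebra finite.

## Bald Eagle Search and the feature-selection wrapper

BES is a swarm optimizer with three sequential phases per iteration,
applied population-wide with greedy acceptance after each phase:

* **select** — `P_new = P_best + alpha * r6 * (P_mean - P_i)`, `alpha` in
  `[1.5, 2]` (default 2), `r6 ~ U(0,1)` fresh per eagle;
* **search** — a spiral walk: `theta = a * pi * r7`,
  `r = theta + R * r8`, `xr = r sin(theta)`, `yr = r cos(theta)`, each
  max-|.|-normalized over the population, driving
  `P_new = P_i + y_i (P_i - P_{i+1}) + x_i (P_i - P_mean)` with the
  neighbour index wrapping cyclically (eagle N pairs with eagle 1);
* **swoop** — the hyperbolic analogue (`sinh`/`cosh`, `r = theta`)
  pulling toward the best: `P_new = r9 * P_best + x1_i (P_i - c1 P_mean)
  + y1_i (P_i - c2 P_best)`, `c1, c2` in `(1, 2)` (default 1.5).

Conventions: out-of-bounds candidates are clipped to the violated bound
(not reflected); a candidate replaces an eagle only if it improves its
fitness, so the best-so-far trace is non-increasing by construction;
`1e-12` is added to the max-normalization denominators, and the swoop
angle is capped at 20 before `sinh`/`cosh` to keep weights finite; all
draws come from one seeded generator owned by the run. Each phase's
candidate computation is exposed as a pure function of its random draws
(`besSelectStep()` etc.) so the vectorized code can be checked against
scalar transcriptions in the test suite.

The **wrapper objective** scores a binary mask by
`alpha_fs * gamma + (1 - alpha_fs) * |R|/|C|`, with `gamma` the pooled
3-fold stratified cross-validated error of a 1-nearest-neighbour
classifier on the selected columns. Design decisions:

* BES is continuous, feature selection needs bits: the search runs over
  `[0,1]^D` and a coordinate selects its feature when it exceeds 0.5 —
  the simplest transfer rule; the threshold is configurable.
* Training the BiGRU inside every fitness evaluation would multiply the
  cost by the whole training budget; a 1-NN surrogate is the standard
  cheap proxy, and the evaluator is pluggable (any
  `function(X, y, foldIds)`, including a BiGRU-based one for final
  verification).
* The error weight `alpha_fs` defaults to 0.9: subset size matters, but
  an order of magnitude less than accuracy. `alpha_fs + beta_fs = 1` by
  construction.
* The CV fold assignment is drawn once per selection run, so all masks
  are compared on identical folds, and the empty mask receives a `+Inf`
  sentinel without ever being evaluated.

## The bidirectional GRU classifier

One GRU cell computes, per timestep,
`r_t = sigma(W_r [h_{t-1}, x_t] + b_r)` (reset gate),
`z_t = sigma(W_z [h_{t-1}, x_t] + b_z)` (update gate),
`h~_t = tanh(W_h [r_t ⊙ h_{t-1}, x_t] + b_h)` (candidate state), and
`h_t = (1 - z_t) ⊙ h_{t-1} + z_t ⊙ h~_t`. The reset gate controls how
much past state enters the candidate; the update gate blends past and
candidate states.

A fingerprint is a flat vector, not a sequence, so the model stores an
input-shaping rule: the `D` features are chunked row-major into
`T = ceiling(D / F)` timesteps of width `F` (default `F = 128`, giving
`T = 16` for `D = 2048`), the last chunk zero-padded; prediction reuses
the identical shaping. A forward cell reads chunks `1..T`, a backward
cell `T..1`; their final hidden states are concatenated (mean-pooling is
available as an option), passed through inverted dropout, and linearly
projected to class logits. Training minimizes cross-entropy with
hand-written backpropagation through time and the Adam optimizer
(`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`); weights initialize
uniformly in `±1/sqrt(H)`; classes are ordered lexicographically and
stored in the model; everything is deterministic under the training
seed. The analytic gradients are verified against central finite
differences in the test suite.

Assumptions and limits: a single bidirectional layer (no stacking, no
attention); the chunking imposes an arbitrary sequence order on
fingerprint bits — the recurrence can exploit it but nothing guarantees
the order is meaningful, which is precisely why the architecture must be
validated empirically rather than assumed superior to simpler baselines.

## Zebra Optimization Algorithm and hyperparameter tuning

ZOA maintains a herd in a box; per iteration each zebra takes a herding
step `X_new = X_i + c1 * u * (X_best - X_i) + c2 * (1-u) * (X_avg - X_i)`
(`u ~ U(0,1)` fresh per zebra, `c1 = c2 = 1` by default) followed by a
predator-avoidance perturbation `X_new = X + sigma * g` with `g` standard
normal and `sigma` defaulting to 1% of the per-dimension range; both
moves are clipped to the bounds and accepted greedily ("only improving
zebras endure"), so the best-so-far trace is non-increasing.

The tuner searches the **unit cube** with a decode layer rather than
mixed-integer positions, keeping the update equations purely continuous:
learning rate decodes log-uniformly over `[1e-4, 1e-2]` (position 0.5 is
exactly `1e-3`), the integer parameters (GRU units `[32, 256]`, batch
size `[16, 128]`, epochs `[10, 100]`) decode linearly with round-half-up,
and dropout decodes linearly over `[0.1, 0.5]`. Decoded values always lie
in the closed ranges. The fitness of a zebra is the percent error
`100 * misclassified / total` of a BiGRU trained with the decoded
configuration, evaluated on a validation split disjoint from its
training data; fitness values are cached by decoded configuration so
duplicate positions never retrain.

The tuning protocol inside `runPipeline()`: the 30% test split is never
touched by tuning. An internal 80:20 split is carved from the 70%
training portion; candidate configurations are scored after training on
at most `tuneSubsample` rows (default 400) of the inner-training part —
one full BiGRU fit per evaluation is the pipeline's dominant cost, and a
capped, stratified subsample ranks configurations at a fraction of it —
and the winning configuration is retrained on the full training portion.

## Evaluation battery

`stratifiedSplit()` preserves per-class proportions to within one sample
(floor plus largest-remainder rounding, ties broken by class order).
`computeMetrics()` reports the k-by-k confusion matrix (rows = true
class) and per-class one-vs-rest accuracy `(TP+TN)/n`, precision
`TP/(TP+FP)` (0 when undefined), recall `TP/(TP+FN)`, F1, and AUC as the
midrank (Mann-Whitney) statistic on that class's predicted probability
column, plus unweighted macro averages. Per-class one-vs-rest accuracy is
reported *alongside* the plain multiclass accuracy, clearly labelled,
because the two differ and conflating them inflates headline numbers. A
class absent from the true labels is an error (its recall is undefined),
never a silent NaN. The implementation is checked exactly against a
brute-force double-loop contingency/pair-counting implementation.

## Synthetic data: what it emulates, and what it does not

`generateSynthetic()` draws a balanced k-class dataset (defaults: three
classes named Plastic / Peptide / Oligosaccharide, 6,500 samples per
class, 2,048 binary features — the shape of a realistic fingerprint
corpus). `nInformative` bits are each assigned a signal class
round-robin and fire with probability 0.8 in it and 0.2 elsewhere;
background bits fire at 0.1 everywhere. These rates make
feature-selection recovery neither trivial nor hopeless: the informative
bits dominate 1-NN error, yet single bits overlap enough that subsets
must be found jointly. A continuous mode draws Gaussian descriptors
inside typical polymer property ranges (glass transition −70…150 °C,
melting point 100…350 °C, viscosity 0.01…1000 Pa·s, rheology 0.1…10 Pa·s,
elasticity 1…10 GPa, Young's modulus 0.5…4 GPa, resilient modulus 1…5
GPa), with informative features' signal-class means shifted by
`effectSize` within-class standard deviations (default 2). Missing
values are injected completely at random; outliers (±6 column standard
deviations, to exercise the percentile caps) only in continuous mode.

What passing tests on this generator show: the pipeline's machinery —
standardization, subset recovery, classifier capacity, metric
computation — behaves correctly under a known ground truth. What they do
not show: performance on real polymer corpora, where informative
structure is correlated, class-conditional distributions are not
product-Bernoulli, and label noise exists. Conclusions about real-data
accuracy require real data.

## Problem sizes and budgets used by the checks

Chosen so the full battery runs comfortably on a single CPU:

* optimizer benchmarks: 10-D sphere over `[-10,10]` for BES (N = 30, 200
  iterations) and the 5-D unit cube — the tuner's native domain — for
  ZOA (N = 20, 200 iterations), 10 seeds each;
* feature-selection recovery: 3 × 500 samples, 100 features, 10
  informative, BES with N = 15 and 25 iterations, 5 seeds;
* classifier capacity: 600 samples, 64 features, chunks of 16, 50 epochs;
* end-to-end: 3 × 500 samples, 200 features, 20 informative, BES N = 12
  × 8 iterations, ZOA herd 3 × 2 iterations, 3 seeds.

## Known limitations

* The fingerprint backend does not encode tetrahedral chirality;
  enantiomer-sensitive tasks need a different representation.
* BES and ZOA are heuristics with no optimality guarantees; budgets are
  part of the experimental design, and the greedy-acceptance convention
  (taken throughout) trades exploration for monotone traces.
* The BiGRU is trained in plain R; it is fast at the problem sizes above
  but not engineered for corpora orders of magnitude larger.
* Percent-error tuning fitness ignores training time; the stated ranges
  bound model complexity instead.
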