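# polygru

Multi-class polymer classification from molecular structure, for
cheminformatics and materials-informatics researchers who want a fully
scripted, reproducible pipeline: SMILES in, per-class metrics out.

Polymers such as plastics, peptides and oligosaccharides occupy very
different regions of chemical space, but telling them apart automatically
requires a representation, a feature filter and a classifier that work
together. `polygru` implements that stack end to end:

1. **Featurization** — each SMILES string becomes a hashed circular
   (Morgan-type / ECFP) binary fingerprint of `nBits` positions
   (default 2048, radius 2), via the OpenBabel backend in `ChemmineOB`.
2. **Preprocessing** — per feature, in order: median imputation of missing
   values, winsorization at the 1st/99th percentiles, and Z-scoring
   `z = (x - mu) / sigma` with training-split statistics only (population
   sigma; constant features map to 0).
3. **Feature selection** — a Bald Eagle Search (BES) wrapper. BES is a
   three-phase swarm optimizer (select / search / swoop) run over
   `[0,1]^D`; positions binarize at 0.5 into feature masks scored by

   `fitness = alpha * gamma_R(D) + (1 - alpha) * |R| / |C|`,

   where `gamma_R(D)` is the 3-fold stratified cross-validated error of a
   1-nearest-neighbour surrogate on the selected columns, `|R|/|C|` the
   selected fraction, and `alpha = 0.9` by default.
4. **Classification** — a single-layer bidirectional GRU built directly
   from the gate equations
   `r_t = sigma(W_r [h_{t-1}, x_t] + b_r)`,
   `z_t = sigma(W_z [h_{t-1}, x_t] + b_z)`,
   `h~_t = tanh(W_h [r_t ⊙ h_{t-1}, x_t] + b_h)`,
   `h_t = (1 - z_t) ⊙ h_{t-1} + z_t ⊙ h~_t`,
   with hand-written backpropagation through time and Adam. Flat feature
   vectors are folded into `T = ceiling(D/F)` chunks of width `F`; the two
   directions' final states are concatenated, dropped out, and projected
   to class logits.
5. **Tuning** — a Zebra Optimization Algorithm (ZOA) herd searches the
   unit-cube encoding of learning rate `[1e-4, 1e-2]` (log scale), GRU
   units `[32, 256]`, batch size `[16, 128]`, dropout `[0.1, 0.5]` and
   epochs `[10, 100]`, minimizing the percent validation error
   `100 * misclassified / total` on an internal split.
6. **Evaluation** — stratified 70:30 split; per-class one-vs-rest
   accuracy, precision, recall, F1 and midrank AUC plus their macro
   averages and the confusion matrix.

A synthetic-data generator (`generateSynthetic()`) draws balanced
class-conditional Bernoulli fingerprints (or Gaussian physical
descriptors) with a planted informative subset, so every stage — including
feature-selection *recovery* — is testable without external data.

## Worked example

```r
library(polygru)

res <- runPipeline(pipelineConfig(
  synthetic = syntheticSpec(nPerClass = 500, D = 200, nInformative = 20),
  outDir = "run1",
  besCtrl = besControl(N = 12, maxIter = 8),
  zoaCtrl = zoaControl(N = 3, maxIter = 2),
  bigru   = list(chunk = 16L),
  seed = 1))
res$metrics
```

On this synthetic three-class problem (1,500 molecules, 200 fingerprint
bits of which 20 carry class signal) the run prints, stage by stage (from
`run1/log.txt`):

```
simulate: 1500 x 200 (fingerprint mode, 20 informative)
preprocess: fitted on 1050 training rows
select-features: 62 / 200 kept (error 0.1990, fitness 0.2101)
tune: best val error 5.71% (lr 0.00207, units 111, batch 70, dropout 0.273, epochs 74)
train: 74 epochs, final loss 0.0000, final training accuracy 1.0000
evaluate: multiclass accuracy 0.9644, macro F1 0.9644 on 450 test rows
```

and `res$metrics` shows:

```
MetricsReport on 450 samples, 3 classes
  multiclass accuracy: 0.9644
  macro: accuracy 0.9763  precision 0.9644  recall 0.9644  F1 0.9644  AUC 0.9949
```

Reading: feature selection kept 62 of 200 bits (including the informative
ones — the surrogate error drops to 0.20 from 0.33 at chance); the tuned
BiGRU then classifies 96.4% of the held-out 30% correctly, with per-class
one-vs-rest AUC averaging 0.995. The six packaged example molecules
(`fixtureSmiles()`) can be pushed through a trained archive with
`predictFromArchive()`.

A command-line front end with the same stages
(`simulate`, `featurize`, `select-features`, `train`, `tune`, `evaluate`,
`predict`, `run-all`) ships as `inst/scripts/polygru-cli.R`.

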