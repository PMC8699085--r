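---
title: "Auditing and ablating batch effects in MSI prediction from TMA images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and ablating batch effects in MSI prediction from TMA images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep-learning models that predict microsatellite instability (MSI) from
H&E-stained colorectal tissue can reach impressive internal-validation
performance while secretly keying on *batch effects*: systematic,
non-biological signatures of how and where a sample was processed. Tissue
microarrays (TMAs) are particularly exposed — a cohort mixes contributing
projects with different MSI prevalence and staining eras, dozens of spots from
one patient that share slicing and staining conditions, and TMA glasses whose
digitization leaves a glass-wide fingerprint over both tissue and background.
A model that predicts "project 1" instead of "MSI-H" looks excellent in
validation and fails on any cohort where that association breaks.

`msidistill` implements the two halves of the remedy:

1. **Audit** — quantify the statistical dependence between the learned
   features `F` and each protected variable with the squared distance
   correlation, globally and within subgroups (backward selection), so hidden
   interactions (e.g. a glass effect confined to one project) surface.
2. **Ablate** — retrain with one adversarial head per protected variable and
   a three-step min-max schedule so the feature extractor is explicitly
   driven towards features that classify MSI while being conditionally
   independent of each bias.

## The model

The network has a feature extractor `FE` producing a feature vector `F`, an
MSI head predicting the two-class label, and one bias head `BE_n` per
protected variable `b_n` (levels indicator-encoded, one output per level).
The classification loss is the summed cross-entropy over the batch. Each bias
head's loss is the negative sum over encoded columns of the squared Pearson
correlation between the column and the head's prediction; zero-variance
columns contribute nothing, so the loss lies in `[-K, 0]`. The overall
objective is the min-max game

```
min_{fe,msi} max_{be}  L_msi - lambda * sum_n L_be_n
```

optimised by a three-step schedule per batch iteration: (1) update `FE` and
the MSI head on the cross-entropy; (2) for each bias consecutively, freeze
`FE` and train its head to predict the bias from `F`; (3) freeze the heads
and update `FE` to *reduce* every head's squared correlation, scaled by
`lambda`. Steps 2–3 run only on the rho-conditioned sub-batch (MSS tiles by
default): conditioning on the label is what makes the target "conditional
independence of the bias given the class" rather than the stronger, usually
unattainable marginal independence; sub-batches smaller than `min_bias_batch`
(default 8) are skipped.

The squared distance correlation used for monitoring and audits is the
classical V-statistic: double-centred Euclidean distance matrices, with
`dc = dCov^2 / sqrt(dVar_x * dVar_y)` in `[0, 1]`, and 0 by convention when a
sample is constant. It is zero in the population only under independence,
which is what makes it the right audit statistic; the biased (V) rather than
unbiased estimator keeps values in `[0, 1]` for monitoring. It is computed
per training batch (a batch-level operation) and, post hoc, on a seeded
subsample of at most `max_n` rows because of its quadratic memory cost.

## Backbone choice

The reference design for full-scale runs is a pretrained convolutional
backbone with two 512-wide ReLU hidden layers per head. The ablation
mechanism is backbone-agnostic, and this package targets desk-scale,
CPU-only experiments, so the trunk here is a dense (fully connected) stack
over a fixed image representation: tiles are area-averaged to
`net_px x net_px` (default 16) and augmented with local gradient-magnitude
maps (absolute horizontal/vertical neighbour differences per channel). The
gradient maps act as a fixed edge/texture front end — dense layers on raw
pixels alone are slow to discover granularity contrasts within a few hundred
iterations, while nuclear density, the morphological signal of interest,
is precisely a granularity contrast. Inputs are standardized to
training-cohort column statistics before entering the network. All parameter
groups are trained with Adam; the default desk-scale learning rate is 1e-3
(2e-3 in the benchmark), batch size 128, epoch cap 3 (6 in the benchmark,
whose cohorts are two orders of magnitude smaller than a full-scale corpus).

Two non-obvious defaults matter:

- `lambda` (default 1 in `train_config()`, 40 in the benchmark): the
  reference work never states its value. At a few hundred iterations the
  fooling gradient must compete with a classification gradient that is
  re-learning the shortcut every iteration, so an effective `lambda` is much
  larger than 1. 40 removes the removable confounds — including the
  many-level patient signature, whose head needs the strongest push —
  while leaving the classification objective dominant; far larger values
  start to collapse the features.
- `be_lr_mult` (default 5): the adversary must track a moving feature
  extractor; with a single head update per iteration (as the three-step
  schedule prescribes) a faster adversary keeps the step-3 gradient
  informative. The alternative of multiple inner head steps (`be_steps`) is
  exposed but not the default.

Seeding is stream-separated: initialisation of each parameter group, batch
order, and audit subsampling draw from disjoint streams derived from the
master seed. This is what makes the `lambda = 0` reduction exact: an ablated
trainer with `lambda = 0` produces bit-identical feature-extractor and
MSI-head trajectories to the baseline trainer, because the bias heads neither
consume shared randomness nor touch the shared Adam state.

## The synthetic generator

`synthesize_dataset()` emulates the generative structure of a multi-centre
TMA study. Patients carry an MSI label (default prevalence 7.4%, the
population-based rate of the cohorts emulated; the benchmark uses 15%, the
assumed real-population screening prevalence); each patient belongs to one
project, one glass, and contributes tiles at one or more magnifications.

- **Morphology (the only "real" signal):** MSI-H tumour-epithelium tiles are
  painted with a higher density of larger dark elliptical nuclei and
  mucin-like pale pools, scaled by `signal_strength`; lymphocyte and mucin
  tiles carry an attenuated version of the effect (mirroring their lower
  specificity), other tissues none. After painting, each channel is
  re-centred to the tissue base colour, so the class signal is purely
  textural (spatial structure) while mean-colour axes are reserved for the
  batch-effect overlays. This separation is what makes "bias = removable
  colour, signal = morphology" a well-posed benchmark.
- **Project:** a fixed RGB stain-shift direction per project, scaled by
  `stain_shift_magnitude`; `project_confound` is the probability that a
  patient's project follows its class (the flipped variant reverses the
  association for building out-of-distribution test splits).
- **Glass:** a deterministic per-glass hue rotation scaled by
  `glass_tint_magnitude`; `glass_class_purity = 1` makes every glass
  single-class.
- **Patient:** a per-patient RGB offset plus a patient-specific mixture of
  three low-frequency sinusoid fields with random frequencies, phases and
  channel weights (scale `patient_texture_sd`), giving each patient a
  high-dimensional colour/texture fingerprint, as tiles of one patient share
  laboratory and slicing conditions.
- **Magnifications:** lower levels are box-filtered and re-upsampled versions
  of the same field, so all magnifications share a raster and differ only in
  detail; `"x0"` is the whole-spot-thumbnail level.

Identical seed and configuration give a byte-identical dataset. What the
generator does **not** emulate: real histological texture, scanner formats,
focus/compression artefacts, spatial correlation between neighbouring tiles
of a spot, or label noise. Tests passing on this generator demonstrate that
the machinery behaves as designed under its stated statistical structure —
not that any particular performance level transfers to real slides.

## The benchmark and its calibration

`confound_benchmark()` freezes the study conditions for the paired
baseline-versus-ablated comparison: 200 patients with 30–50 tiles each,
64-px tiles, prevalence 0.15, two projects with confound 0.7, eight mixed
glasses, stain shift 0.12, glass tint 0.15, patient texture 0.12, signal 0.8.
Two calibration facts shaped those numbers:

- *Removability requires representation.* With a near-deterministic confound
  the MSS cohort contains almost no project-1 tiles, the conditioned
  adversary sees a constant bias column, and ablation is blind. Confound 0.7
  leaves about 15% of MSS tiles in project 1 — strongly biased yet removable,
  which is the regime the method is designed for.
- *The V-statistic has an O(1/N) positive bias that grows with level count.*
  At the audit size used here (subsample 2048), the permutation-null mean of
  dc between isotropic 128-dim features and a ~170-level patient indicator
  is about 0.12 (it is smaller, about 0.02, for the low-effective-rank
  features a trained extractor actually produces). The bias magnitudes were
  chosen so that baseline dependences sit well above these nulls, otherwise
  the audit could not distinguish "removed" from "never detectable".

The degenerate configuration (`degenerate_glass = TRUE`) uses two
single-class glasses: every MSS tile lies on one glass, so within the
MSS-conditioned cohort the glass is constant, the glass adversary receives
zero gradient, and the glass dependence of the features — which now rides on
the class signal itself — cannot be removed. This reproduces the negative
finding that decoupling a glass from the label is infeasible when their
association is unequivocal. The degenerate experiment ablates the glass head
in isolation: at this scale a patient head is nested inside two glasses and
acts as a surrogate glass-adversary, which would mask exactly the
infeasibility the experiment is designed to exhibit (a full-scale cohort
with thousands of patients per batch does not have this leak).

## Evaluation machinery

Tile probabilities are aggregated per patient by majority vote of hard
labels at the 0.5 threshold; even splits are called MSI-H (a screening
context prefers sensitivity; `tie = "mean"` switches to thresholding the mean
probability). The patient-level score for AUC is the mean tile probability.
AUC is the rank (Mann-Whitney) statistic with midranks for ties.
Prevalence-adjusted accuracy, PPV and NPV follow the closed forms
`S*P + E*(1-P)`, `S*P/(S*P+(1-E)*(1-P))` and `E*(1-P)/(E*(1-P)+(1-S)*P)` at an
assumed screening prevalence of 15%. Sensitivity, specificity and accuracy
get exact Clopper-Pearson intervals (Beta quantiles); the predictive values
get standard logit (delta-method) intervals with variances
`(1-S)/(S*n_pos) + E/((1-E)*n_neg)` and `(1-E)/(E*n_neg) + S/((1-S)*n_pos)`.
Stratified false-positive/false-negative rates by tissue and magnification
mark strata without negatives (or positives) as undefined rather than zero.

## Preprocessing choices

- Tiling is anchored top-left, row-major, without overlap; partial border
  tiles are discarded rather than padded. A magnification is obtained by
  box-filter (area-average) downsampling of the native raster, which is both
  the correct anti-aliasing filter and exactly reproducible.
- A cheap background pre-filter drops tiles in which more than 80% of pixels
  have HSV saturation below 0.05; background can equivalently be rejected
  later through the tissue classifier's BACK class (`background_max_frac = 1`
  disables the pre-filter), since the glass fingerprint rides on background
  as well as tissue.
- Macenko stain normalization estimates the stain plane by SVD of the
  above-threshold optical-density cloud (transparent pixels removed by mean
  OD), takes the 1st/99th percentile angular directions as the two stain
  vectors, and rescales least-squares concentrations to the reference's 99th
  percentile. Blank tiles are returned unchanged with a `blank` flag. The
  non-negativity clip on concentrations means the extreme percentile tails
  are not exactly reconstructed; idempotence holds in the bulk (mean and 95th
  percentile of the per-pixel deviation), not at the max.
- Augmentation (rotation up to 90 degrees, dihedral flips with probability
  0.5, perspective warp up to 0.2, hue shifts up to 0.15) is deterministic
  under a fixed seed; right-angle rotations resolve to exact index
  permutations, everything else uses bilinear resampling.
- The tissue classifier shares the feature-extractor architecture, so its
  trunk (`tissue_trunk()`) can seed the end-to-end system, mirroring the
  transfer from tissue-type pretraining to MSI prediction.

## Numerical and degenerate-input conventions

- dc returns 0 when either distance variance is zero; inputs with NA are
  rejected; results are clamped to `[0, 1]` against rounding.
- Pearson correlations in the bias loss carry 1e-8 denominators guards;
  zero-variance columns contribute zero loss and zero gradient.
- `encode_bias` uses sorted level order; audits encode only levels present in
  the subset, training targets encode all declared levels (fixed head width).
- Subgroups with fewer than two rows are skipped with a warning; audit
  subsampling beyond `max_n` rows is seeded.
- Patient-grouped folds assert zero patient leakage on every run.

## Known limitations

- The dense trunk cannot represent translation-equivariant features; its
  tile-level accuracy saturates well below what a convolutional backbone
  reaches on real histology. The package measures *relative* effects
  (baseline vs ablated under identical conditions), which is what the desk
  scale supports.
- The patient audit at a few thousand rows is floor-limited (see above):
  small residual patient dc values should be read against the permutation
  null, not as exact zeros.
- Training runs here are a few hundred iterations; phenomena that emerge
  from long memorisation (severe patient overfitting) appear only in
  attenuated form.
- The adversarial game is a heuristic alternating scheme; it has no
  convergence guarantee, and an overly large `lambda` can collapse the
  features entirely. Monitoring the dc trace (`autoplot()` on the fitted
  model) is the intended guard.
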