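---
title: "Trajectory modeling and Siamese-network prognosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory modeling and Siamese-network prognosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models, the
assumptions behind them, the tunable parameters and why their defaults are
what they are, what the synthetic-cohort generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## 1. Trajectory modeling

### The model

Let $x_i \in \mathbb{R}^9$ be subject $i$'s clinical score (MMSE or
ADAS-13) at the nine grid months $\{0,6,12,18,24,36,48,60,72\}$. Subjects
with a complete vector are clustered by agglomerative hierarchical
clustering with Euclidean distance $\lVert x_i - x_j \rVert_2$ and Ward's
linkage (`stats::hclust(method = "ward.D2")`), and the dendrogram is cut at
$k$ clusters. $k$ is a design choice, not estimated: the package defaults to
$k = 2$ (stable / decline) for MMSE and $k = 3$ (stable / slow decline /
fast decline) for ADAS-13, whose wider dynamic range (0–85 vs 0–30)
supports the finer split. The per-class *template* is the elementwise mean
$\mu_c(t)$ of the cluster's scores at each grid month.

Any other subject is labeled by Euclidean proximity over whichever grid
months $T$ they have scores for:
$d_c = \sqrt{\sum_{t \in T}(x_t - \mu_c(t))^2}$, $\hat c = \arg\min_c d_c$,
subject to the eligibility rule of at least 3 scored visits spanning
strictly more than 12 months.

### Assumptions

* Trajectories are adequately summarized by the score values on a common
  visit grid; visits are protocol-scheduled, so off-grid months are
  deviations, not a different design.
* Complete-case clustering is unbiased enough to define prototypes; the
  subjects with all nine visits are assumed to span the same trajectory
  space as everyone else.
* Severity is monotone in the final-month score (lower MMSE / higher
  ADAS-13 is worse). This drives the canonical class ordering.

### Decisions where the design was open

* **Eligibility boundary.** "Longer than one year" is read strictly: a
  scored span of exactly 12 months is excluded. `filterEligible()` exposes
  `minSpanMonths` for users who prefer the closed boundary.
* **Tie-breaking.** A subject equidistant to two templates receives the
  *less severe* class. This is deterministic and conservative for a
  prognostic label; any rule would do, but it must be fixed.
* **Off-grid visits** snap to the nearest grid month within ±3 months
  (half the shortest inter-visit gap); farther visits are ignored for
  assignment. Duplicate snaps keep the closest visit, earlier on ties.
* **Distance is unnormalized** over the available months (not divided by
  $\sqrt{|T|}$): the comparison is within subject across classes, so the
  number of months cancels; normalizing would change nothing about the
  argmin but would obscure the plain "Euclidean proximity" reading.
* **Canonical ordering** (least severe first, by final-month template
  severity) makes `stable`/`decline` labels reproducible across runs
  regardless of `cutree()`'s arbitrary cluster numbering. The training
  subjects themselves are relabeled by proximity like everyone else, for
  uniformity; with separated clusters both conventions agree.

## 2. The Longitudinal Siamese Network

### Architecture

For two cortical-thickness vectors $u, v \in \mathbb{R}^{78}$ (baseline and
follow-up), a single branch $b(\cdot)$ — four hidden rectifier layers of
equal width, then a linear map to the embedding — is applied to both
(weight sharing is structural: one parameter set, one storage). The
*distance embedding* is the signed difference

$$e = b(v) - b(u) \in \mathbb{R}^{d},$$

zero when nothing changed and antisymmetric under swapping the scans; both
properties are asserted in the tests. A one-node layer computes the scalar
gate $g = \sigma(w \cdot \text{APOE4} + c)$ from the allele count alone,
and the head consumes $[g e \,\Vert\, s_0 \,\Vert\, s_1 \,\Vert\,
\text{age}]$ through one hidden rectifier layer to a softmax.

Open points resolved here:

* *Signed difference, not absolute or learned merge*: preserves the
  direction of change (thinning vs thickening) and yields the antisymmetry
  invariant for free.
* *Gate input*: the one-node modulation layer could receive the embedding
  alongside APOE4; the minimal architecture consistent with "multiplicative
  modulation by APOE4 status" is a scalar gate on the allele count alone,
  which is what is implemented. APOE4 enters as the raw ordinal count
  0/1/2.
* *Activations*: rectifiers in the hidden layers, logistic sigmoid in the
  gate, softmax output with cross-entropy; the two-class task uses the same
  2-way softmax as the 3-way task for code uniformity.

### Training

Adam (rate $10^{-3}$, batch 32), early stopping on a stratified 15%
validation split with patience 20 epochs (cap 300), best-validation
parameters restored. Continuous inputs are standardized inside the model
with training-set statistics — per-ROI over both timepoints pooled (the
shared branch needs one scale), scores pooled over both timepoints, and
age — and the statistics are stored in the model object so prediction is
self-contained. All randomness (initialization, split, batch order) derives
from one seed via `deriveSeed()`, so training is bit-reproducible.

Branch width / embedding dimension / head width default to 35 / 15 / 10–20
midpoints, but in the cross-validation harness they are selected per outer
fold on the inner folds from the diagonal grid `lsnDefaultGrid()` —
(25,10,10), (35,15,15), (50,20,20) — by mean inner-fold accuracy, ties to
the smaller model. A full $3^3$ factorial grid triples cost for little
coverage gain at these sample sizes.

## 3. Reference models and evaluation design

The four baselines consume one concatenated vector per subject in the fixed
order $[s_0 (, s_1), \text{age}, \text{APOE4} (, ct_0 (, ct_1))]$, crossed
over feature sets CA / CT / CA+CT and timepoint sets baseline /
baseline+follow-up (vector lengths 3, 4, 78, 156, 81, 160). Features are
standardized with training-fold statistics for the lasso logistic
regression and the SVM only; the random forest takes raw features; the ANN
(single-hidden-layer `nnet`) standardizes internally for trainability —
a documented deviation, since an unscaled 160-dimensional input in mm /
score / year units does not train. The SVM's ROC scores come from decision
values (monotone suffices for AUC; no extra calibration layer).
Hyperparameter grids: lasso penalty $10^{-3}$–$10^2$; SVM radial/linear
with C and $\gamma$ log-grids; forest with 100/500 trees and an optional
node cap; ANN sizes 25/50 with weight decay. Selection is by mean
inner-fold accuracy, ties toward the simpler setting.

Evaluation uses nested stratified cross-validation: 10 outer folds (tests
and examples use 3–5 to stay fast) stratified jointly on cohort tag ×
class, 5 inner folds within each outer training set for all hyperparameter
selection, so no test subject influences standardization, selection or
training. Metrics: accuracy, binary AUC (rank probability, ties ½, via
pROC), pooled confusion matrices, ROC points; the 3-way task additionally
reports macro one-vs-rest AUC, clearly an extension beyond the original
accuracy-only reporting. Per-fold metric samples are compared with the
two-sided Mann-Whitney U test (exact for ≤10 tie-free folds per side,
normal approximation with tie correction otherwise).

Two subject stratifications are reported: the clinical-workflow groups —
baseline edge-cases (BE: baseline score outside [24, 29] for MMSE,
[8, 30] for ADAS-13), follow-up edge-cases (FE: absolute change ≥ 2 MMSE /
6 ADAS-13 points), cognitively consistent (CC: the rest) — and the
visit-span groups (near future: last assignment month ≤ 36; distant
future: ≥ 48; the 36–48 gap is flagged rather than forced into a band).
The workflow cutoffs are documented placeholders: the stratification is
explicitly not a fixed choice and users must review them for their setting.

## 4. The synthetic-cohort generator

`simulateCohort()` draws, per subject: a class from the mixing proportions;
age and APOE4 from class-conditional distributions; scores from the class
mean curve (linear, or logistic with midpoint and steepness) plus Gaussian
noise clamped to the scale range; and a visits × 78 thickness matrix with
per-ROI truncated-normal baselines around 2.5 mm (SD 0.25) declining
linearly at an annual rate — one rate in the 20 signature regions, another
elsewhere — plus 0.05 mm measurement noise, floored at 0.1 mm. Non-baseline
visits drop out independently (default 20%), and retained visits lose their
scan with a second probability (default 10%); the baseline visit never
drops.

The defaults encode the study conditions: the 9-timepoint/72-month grid; a
0.6/0.4 stable/decline split for MMSE (0.52/0.17/0.31 for the three
ADAS-13 classes); APOE4 mixtures skewed by class (stable 0.65/0.29/0.06,
decline 0.37/0.45/0.18 — the published cohort demographics to two decimal
places); decline-class thinning of 0.06 mm/year in signature regions
against 0.015 mm/year for stable subjects, i.e. roughly 2.4%/year vs
0.6%/year of a 2.5 mm cortex, the magnitudes reported for AD and healthy
aging. No quantitative noise or atrophy figures were available from the
source design, so these are defensible testbed values, chosen once — not
biological claims. An AIBL-style preset (18-month grid to 54 months, MMSE
only) supports train-on-A/test-on-B replication exercises via
`replicationTest()`.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: score floor/ceiling effects beyond clamping,
practice effects, non-monotone individual trajectories, correlated
region-wise atrophy topographies, scanner/field-strength batch effects,
informative (dropout-by-severity) missingness, and measurement error that
grows with impairment. Results on the simulator validate the *machinery*
(clustering, template sampling, weight sharing, fold hygiene), not clinical
performance.

## 5. Numerical choices and degenerate inputs

* Score curves are evaluated then clamped; with zero noise the clamp makes
  the zero-noise recovery tests exact rather than approximate.
* Truncated-positive baseline thickness is drawn by rejection; CT values
  are floored at 0.1 mm so late-horizon extrapolation cannot go negative.
* Zero-variance feature columns standardize to 0 with a warning (constant
  columns carry no information; mapping to 0 keeps them inert for the
  lasso and SVM).
* Softmax is computed with row-max subtraction; cross-entropy clips
  probabilities at $10^{-12}$; a NaN/Inf gradient aborts training with a
  diagnostic rather than continuing silently.
* `which.min`/first-max conventions implement every tie rule (less severe
  class, smaller model) deterministically.
* Single-class truth yields AUC `NA`, never 0; empty clusters and
  insufficient timepoints raise errors naming the subject, row or stratum.

## 6. Problem sizes used by the tests

The suite validates clustering recovery on 69-subject complete-case
cohorts (both scales), signal attribution on 600-subject two-visit cohorts
with 5-fold cross-validation, null calibration on a 200-subject cohort with
10 permutation seeds and 3 folds per model kind, and a full 100-subject
smoke pipeline run twice for bit-reproducibility — sizes at which every
targeted property is already decisive while the whole suite runs in a few
minutes on one CPU.

## 7. Known limitations

* The LSN sees cortical thickness only through the *change* embedding. On
  cohorts where class information sits in the thickness *level* rather
  than its change (or largely in the clinical scores), concatenated-feature
  baselines can match or beat it — visible in the README example. This is
  the architecture's design intent (atrophy representation), not a defect,
  but it bounds where the model should be preferred.
* Missing APOE4 is not handled; subjects lacking a qualifying follow-up
  within 12 months are excluded from all two-timepoint analyses (and
  listed with reasons).
* No growth-mixture or latent-class alternative is provided for trajectory
  modeling, and $k$ is never selected automatically.
* The ANN baseline is single-hidden-layer (`nnet`); deeper reference
  networks would need a different backend.
* Feature-level attribution for the LSN (which regions drive a
  prediction) is out of scope.
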