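# TrajLSN

Longitudinal trajectory modeling and Siamese-network prognosis for
Alzheimer's disease.

## The problem

Predicting how an individual's cognitive symptoms will evolve is central to
early intervention in Alzheimer's disease, but the prediction target itself
is awkward to define: fixed-window conversion labels ("MCI-to-AD within 36
months") force hard cutoffs and throw away subjects with missing visits.
TrajLSN implements a two-part longitudinal framework for researchers working
with ADNI-style cohort tables (per-visit MMSE / ADAS-13 scores, regional
cortical thickness, age, APOE4):

1. **Trajectory modeling.** Subjects with complete longitudinal score
   vectors over the visit grid (9 timepoints spanning 72 months by default)
   are clustered by hierarchical agglomeration — Euclidean distance between
   score vectors, Ward's linkage — and the tree is cut at *k* classes (2 for
   MMSE, 3 for ADAS-13 by default). Averaging each cluster's scores at each
   timepoint gives a per-class *trajectory template* μ_c(t). Any subject with
   at least 3 scored visits spanning more than 12 months then receives the
   prognostic label

   c\*(x) = argmin_c √Σ_{t ∈ T(x)} (x_t − μ_c(t))²,

   where T(x) is whatever subset of grid months the subject actually has —
   no fixed-window exclusions.

2. **Trajectory prediction.** A Longitudinal Siamese Network (LSN) predicts
   c\* from just two timepoints (baseline and the latest visit within a
   year). Two 78-dimensional cortical-thickness vectors pass through twin
   *weight-sharing* branches (4 hidden rectifier layers); the signed
   difference of the branch outputs is a *distance embedding* e =
   b(ct₁) − b(ct₀) representing atrophy over the interval. A one-node layer
   computes a scalar gate g = σ(w·APOE4 + c) that multiplicatively modulates
   the embedding, and the prediction head consumes [g·e ∥ score₀ ∥ score₁ ∥
   age] through one hidden layer to a softmax over trajectory classes. All
   stages are trained jointly (Adam, cross-entropy, early stopping).

Four reference classifiers (lasso logistic regression, SVM, random forest,
feed-forward ANN) on concatenated feature vectors, a nested stratified
(cohort × class) cross-validation harness with inner-fold hyperparameter
search, clinical-workflow (BE/FE/CC) and visit-span stratification, and
Mann-Whitney model comparison reproduce the surrounding evaluation design.
Because the cohorts this design was developed on are access-restricted, the
package ships a synthetic-cohort simulator with planted trajectory classes
(class-conditional score curves, APOE4 mixtures, and regional atrophy rates;
random missing visits and scans) so every stage is testable end to end.

## Worked example

```r
library(TrajLSN)

cfg <- simulationConfig(n_subjects = 300, seed = 42)   # ADNI-style defaults
sim <- simulateCohort(cfg)
cohort <- filterEligible(sim$cohort, "mmse")           # >=3 visits, >12 months

scores   <- completeScoreMatrix(cohort, "mmse", cfg$visit_grid)
classes  <- clusterTrajectories(scores, k = 2)         # Ward / Euclidean
template <- buildTemplates(scores, classes, cfg$visit_grid, "mmse")
template
#> TrajectoryTemplate (mmse), 2 classes x 9 months
#>             0     6    12    18    24    36    48    60    72
#> stable  28.89 28.43 28.52 28.57 28.52 28.26 28.35 27.73 27.49
#> decline 26.36 25.95 26.37 25.29 24.80 21.58 17.26 14.47 12.83
#> n per class: 31, 18
```

The template rows are the class prototypes: the stable class drifts by about
1.4 MMSE points over six years while the decline class loses 13.5. Labeling
the whole cohort by template proximity recovers the planted classes:

```r
asg <- labelCohort(cohort, template)$assignments
table(asg$label)
#> decline  stable
#>     118     182
mean(asg$label == sim$labels[asg$subject_id])
#> [1] 1
```

Prediction from two timepoints, cross-validated (5 outer folds here; the
full design uses 10):

```r
bundle <- predictionInputs(cohort, "mmse")   # baseline + follow-up in 1 year
labels <- setNames(asg$label, asg$subject_id)
report <- runExperiment(bundle, labels, "mmse", models = c("LR", "LSN"),
                        specs = list(featureSpec("CA", "baseline", "mmse")),
                        k = 5, innerK = 3, seed = 42)
#> LR|CA|baseline               accuracy = 0.799  AUC = 0.880
#> LSN|CA_CT|baseline_followup  accuracy = 0.707  AUC = 0.797
```

On this small mixed-signal cohort the baseline clinical attributes already
carry most of the class signal, so the clinical-only regression is a strong
reference; the LSN's advantage is specific to signal carried by *change* in
cortical thickness between the two scans, which the methods vignette
(`vignettes/trajectory-prognosis.Rmd`) demonstrates on cohorts where the
classes differ only in atrophy rate — there the LSN reaches AUC ≈ 0.99 while
clinical-only models stay at chance.

A command-line surface over the same functions lives at
`inst/scripts/trajlsn.R` (subcommands `simulate`, `model-trajectories`,
`assign`, `train`, `predict`, `evaluate`, `report`; every run writes a
manifest with seeds and input checksums).

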