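#' Deterministic seed fan-out
#'
#' Derives a component seed below 2^31 from a global seed and a tag so that
#' every stochastic component of a run draws from its own reproducible
#' stream.
#' @param seed integer global seed.
#' @param tag character component tag.
#' @param index optional integer (e.g. fold number).
#' @return integer seed.
#' @export
deriveSeed <- function(seed, tag, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483629)
}

#' Specify one planted trajectory class
#'
#' Parametric description of a trajectory class for the synthetic-cohort
#' simulator: a mean clinical-score curve over the visit grid, score noise,
#' class-conditional cortical-thickness dynamics (baseline level, annual
#' thinning in signature vs. background regions, measurement noise), the
#' APOE4 allele-count mixture, and the age distribution.
#'
#' The score curve is either `linear` — interpolating `score_start` at month
#' 0 to `score_end` at month `horizon` — or `logistic` — a sigmoid running
#' from `score_start` to `score_end` with inflection at `midpoint` months and
#' slope parameter `steepness` (per month). Curves are evaluated and then
#' clamped to the scale range by the simulator.
#'
#' @param label class label string.
#' @param proportion class mixing proportion.
#' @param shape `"linear"` or `"logistic"`.
#' @param score_start,score_end mean score at baseline / end of follow-up.
#' @param midpoint,steepness logistic curve parameters (months, 1/months).
#' @param horizon month at which a linear curve reaches `score_end`
#'   (default 72).
#' @param score_noise_sd Gaussian score noise SD (score points).
#' @param ct_baseline_mean,ct_baseline_sd per-region baseline thickness
#'   distribution (mm), truncated positive.
#' @param atrophy_signature,atrophy_background annual thinning (mm/year) in
#'   signature and background regions.
#' @param ct_noise_sd per-measurement thickness noise SD (mm).
#' @param apoe4_probs probability vector for APOE4 allele counts 0/1/2.
#' @param age_mean,age_sd baseline age distribution (years).
#' @return a `TrajectoryClassSpec` list.
#' @export
trajectoryClassSpec <- function(label, proportion,
                                shape = c("linear", "logistic"),
                                score_start, score_end,
                                midpoint = 36, steepness = 0.1,
                                horizon = 72,
                                score_noise_sd = 1,
                                ct_baseline_mean = 2.5,
                                ct_baseline_sd = 0.25,
                                atrophy_signature = 0.02,
                                atrophy_background = 0.005,
                                ct_noise_sd = 0.05,
                                apoe4_probs = c(0.6, 0.3, 0.1),
                                age_mean = 73, age_sd = 7) {
  shape <- match.arg(shape)
  if (abs(sum(apoe4_probs) - 1) > 1e-9 || any(apoe4_probs < 0))
    stop("apoe4_probs must be a probability vector over {0,1,2}")
  structure(list(
    label = label, proportion = proportion, shape = shape,
    score_start = score_start, score_end = score_end,
    midpoint = midpoint, steepness = steepness, horizon = horizon,
    score_noise_sd = score_noise_sd,
    ct_baseline_mean = ct_baseline_mean, ct_baseline_sd = ct_baseline_sd,
    atrophy_signature = atrophy_signature,
    atrophy_background = atrophy_background,
    ct_noise_sd = ct_noise_sd,
    apoe4_probs = apoe4_probs,
    age_mean = age_mean, age_sd = age_sd
  ), class = "TrajectoryClassSpec")
}

#' Simulation configuration
#'
#' Bundles everything [simulateCohort()] needs. Defaults emulate the pooled
#' ADNI-style study conditions: a 9-timepoint visit grid over 72 months,
#' MMSE as the modeled scale, 78 atlas regions with a 20-region atrophy
#' signature, and moderate random visit/scan missingness. The baseline visit
#' is never dropped.
#'
#' @param n_subjects number of subjects.
#' @param class_spec list of [trajectoryClassSpec()] objects; proportions
#'   must sum to 1 (tolerance 1e-9).
#' @param visit_grid ordered vector of visit months.
#' @param scale modeled clinical scale, `"mmse"` or `"adas13"`.
#' @param roi_count number of atlas regions.
#' @param signature_rois indices of atrophy-signature regions.
#' @param visit_missing_prob probability a non-baseline visit is missing.
#' @param ct_missing_prob probability a retained visit lacks a scan.
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @param scaleRanges named list of scale ranges.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(n_subjects,
                             class_spec = defaultClassSpecs("mmse"),
                             visit_grid = c(0, 6, 12, 18, 24, 36, 48, 60, 72),
                             scale = "mmse",
                             roi_count = 78,
                             signature_rois = 1:20,
                             visit_missing_prob = 0.2,
                             ct_missing_prob = 0.1,
                             seed = 1L,
                             scaleRanges = defaultScaleRanges()) {
  .checkScale(scale)
  props <- vapply(class_spec, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", sum(props), ")")
  if (length(signature_rois) &&
      (min(signature_rois) < 1 || max(signature_rois) > roi_count))
    stop("signature_rois must lie within 1..roi_count")
  if (visit_missing_prob < 0 || visit_missing_prob >= 1 ||
      ct_missing_prob < 0 || ct_missing_prob >= 1)
    stop("missingness probabilities must lie in [0, 1)")
  structure(list(
    n_subjects = n_subjects, class_spec = class_spec,
    visit_grid = sort(visit_grid), scale = scale,
    roi_count = roi_count, signature_rois = signature_rois,
    visit_missing_prob = visit_missing_prob,
    ct_missing_prob = ct_missing_prob,
    seed = as.integer(seed), scaleRanges = scaleRanges
  ), class = "SimulationConfig")
}

#' Default planted class specifications
#'
#' Study-condition presets for the simulator. `"mmse"` gives two classes
#' (stable 0.6 / decline 0.4, emulating the 674/442 split) with APOE4
#' mixtures skewed by class as in the cohort demographics (stable
#' 0.65/0.29/0.06, decline 0.37/0.45/0.18) and a stable-vs-sigmoidal-decline
#' score contrast; `"adas13"` gives three classes (stable / slow decline /
#' fast decline at 0.52/0.17/0.31) on the wider ADAS-13 range. Decliners thin
#' faster in signature regions than stable subjects.
#'
#' @param scale `"mmse"` or `"adas13"`.
#' @return list of [trajectoryClassSpec()] objects.
#' @export
defaultClassSpecs <- function(scale = c("mmse", "adas13")) {
  scale <- match.arg(scale)
  if (scale == "mmse") {
    list(
      trajectoryClassSpec("stable", 0.6, "linear",
        score_start = 29, score_end = 27.5, score_noise_sd = 1,
        atrophy_signature = 0.015, atrophy_background = 0.005,
        apoe4_probs = c(0.65, 0.29, 0.06), age_mean = 72.8),
      trajectoryClassSpec("decline", 0.4, "logistic",
        score_start = 27.5, score_end = 12, midpoint = 40, steepness = 0.08,
        score_noise_sd = 1.5,
        atrophy_signature = 0.06, atrophy_background = 0.01,
        apoe4_probs = c(0.37, 0.45, 0.18), age_mean = 74.8)
    )
  } else {
    list(
      trajectoryClassSpec("stable", 0.52, "linear",
        score_start = 10, score_end = 13, score_noise_sd = 2.5,
        atrophy_signature = 0.015, atrophy_background = 0.005,
        apoe4_probs = c(0.68, 0.28, 0.04), age_mean = 72.3),
      trajectoryClassSpec("slow_decline", 0.17, "logistic",
        score_start = 14, score_end = 32, midpoint = 48, steepness = 0.06,
        score_noise_sd = 3,
        atrophy_signature = 0.035, atrophy_background = 0.008,
        apoe4_probs = c(0.53, 0.33, 0.14), age_mean = 74.9),
      trajectoryClassSpec("fast_decline", 0.31, "logistic",
        score_start = 18, score_end = 55, midpoint = 30, steepness = 0.08,
        score_noise_sd = 3.5,
        atrophy_signature = 0.06, atrophy_background = 0.01,
        apoe4_probs = c(0.31, 0.49, 0.20), age_mean = 74.8)
    )
  }
}

#' AIBL-style replication preset
#'
#' An 18-month-interval visit grid to 54 months, MMSE only, for
#' train-on-one-cohort / test-on-another replication exercises.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param ... passed through to [simulationConfig()].
#' @return a `SimulationConfig`.
#' @export
aiblSimulationConfig <- function(n_subjects, seed = 1L, ...) {
  simulationConfig(n_subjects,
                   class_spec = defaultClassSpecs("mmse"),
                   visit_grid = c(0, 18, 36, 54),
                   scale = "mmse", seed = seed, ...)
}

.curveValue <- function(spec, months) {
  switch(spec$shape,
    linear = spec$score_start +
      (spec$score_end - spec$score_start) * months / spec$horizon,
    logistic = spec$score_start +
      (spec$score_end - spec$score_start) /
        (1 + exp(-spec$steepness * (months - spec$midpoint)))
  )
}

#' Simulate one subject's clinical score trajectory
#'
#' Evaluates the class mean curve at `months`, adds i.i.d. Gaussian noise and
#' clamps to the scale range. Draws from the current RNG state; seed the RNG
#' (or use [simulateCohort()], which seeds once) for reproducibility.
#'
#' @param spec a [trajectoryClassSpec()].
#' @param months months at which to sample.
#' @param scaleRange `c(min, max)` clamp range.
#' @return numeric score vector, one value per month.
#' @export
simulateTrajectory <- function(spec, months, scaleRange = c(0, 30)) {
  mu <- .curveValue(spec, months)
  y <- mu + stats::rnorm(length(months), 0, spec$score_noise_sd)
  pmin(pmax(y, scaleRange[1]), scaleRange[2])
}

#' Simulate one subject's cortical-thickness matrix
#'
#' Baseline thickness per region is drawn from a truncated-positive normal;
#' the value at month m is baseline minus (annual rate x m/12) plus
#' measurement noise, with the signature rate in `signature_rois` and the
#' background rate elsewhere. Values are floored at 0.1 mm.
#'
#' @param spec a [trajectoryClassSpec()].
#' @param months months at which visits occur.
#' @param roi_count number of regions.
#' @param signature_rois indices of signature regions.
#' @return matrix, `length(months)` rows x `roi_count` columns.
#' @export
simulateCT <- function(spec, months, roi_count = 78, signature_rois = 1:20) {
  base <- stats::rnorm(roi_count, spec$ct_baseline_mean, spec$ct_baseline_sd)
  while (any(base <= 0))
    base[base <= 0] <- stats::rnorm(sum(base <= 0), spec$ct_baseline_mean,
                                    spec$ct_baseline_sd)
  rate <- rep(spec$atrophy_background, roi_count)
  rate[signature_rois] <- spec$atrophy_signature
  mu <- outer(months / 12, rate, function(t, r) -t * r) +
    matrix(base, length(months), roi_count, byrow = TRUE)
  noise <- matrix(stats::rnorm(length(months) * roi_count, 0, spec$ct_noise_sd),
                  length(months), roi_count)
  pmax(mu + noise, 0.1)
}

#' Simulate a longitudinal cohort with planted trajectory classes
#'
#' Draws each subject's class from the mixing proportions, then age, sex and
#' APOE4 from the class-conditional distributions, clinical scores from the
#' class mean curve plus noise (clamped to the scale range), and
#' cortical-thickness matrices with class-conditional thinning rates.
#' Non-baseline visits are dropped independently with `visit_missing_prob`;
#' thickness vectors of retained visits are additionally dropped with
#' `ct_missing_prob`. The baseline visit (month 0) is always present. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `cohort` (a [Cohort]) and `labels` (named
#'   character vector mapping subject_id to planted class label).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  specs <- config$class_spec
  props <- vapply(specs, `[[`, numeric(1), "proportion")
  labels_pool <- vapply(specs, `[[`, character(1), "label")
  rng <- config$scaleRanges[[config$scale]]
  n <- config$n_subjects
  grid <- config$visit_grid

  cls <- sample(seq_along(specs), n, replace = TRUE, prob = props)
  ids <- sprintf("S%04d", seq_len(n))

  sub_rows <- vector("list", n)
  vis_rows <- vector("list", n)
  ct_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[cls[i]]]
    age <- round(stats::rnorm(1, sp$age_mean, sp$age_sd), 1)
    apoe4 <- sample(0:2, 1, prob = sp$apoe4_probs)
    sex <- sample(c("M", "F"), 1)
    keep <- c(TRUE, stats::runif(length(grid) - 1) >= config$visit_missing_prob)
    months <- grid[keep]
    scores <- simulateTrajectory(sp, months, rng)
    ct <- simulateCT(sp, months, config$roi_count, config$signature_rois)
    ct_drop <- stats::runif(length(months)) < config$ct_missing_prob
    ct[ct_drop, ] <- NA_real_
    sub_rows[[i]] <- data.frame(
      subject_id = ids[i], age = age, sex = sex, apoe4 = apoe4,
      diagnosis = "MCI", cohort = "SIM", stringsAsFactors = FALSE)
    vis <- data.frame(subject_id = ids[i], month = months,
                      mmse = NA_real_, adas13 = NA_real_,
                      stringsAsFactors = FALSE)
    vis[[config$scale]] <- scores
    vis_rows[[i]] <- vis
    ct_rows[[i]] <- ct
  }
  cohort <- makeCohort(
    do.call(rbind, sub_rows),
    do.call(rbind, vis_rows),
    do.call(rbind, ct_rows),
    roiNames = paste0("roi_", seq_len(config$roi_count)),
    scaleRanges = config$scaleRanges
  )
  labels <- stats::setNames(labels_pool[cls], ids)
  list(cohort = cohort, labels = labels)
}
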