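#' Stratified fold assignment
#'
#' Partitions indices into `k` folds so that every stratum is split as
#' evenly as possible (per-fold stratum counts within 1 of proportional
#' allocation). Deterministic given `seed`.
#'
#' @param strata factor (or coercible) of stratum membership.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors (the folds).
#' @export
stratifiedFolds <- function(strata, k, seed = 1L) {
  strata <- as.factor(strata)
  set.seed(seed)
  fold_of <- integer(length(strata))
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    idx <- sample(idx)
    start <- sample.int(k, 1L)  # rotate which folds receive the remainder
    fold_of[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

#' Nested stratified cross-validation folds
#'
#' Outer folds are stratified jointly on cohort tag x class label; inner
#' folds are nested within each outer training set with the same joint
#' stratification, for hyperparameter selection. Deterministic given `seed`.
#'
#' @param labels class label per subject.
#' @param cohorts cohort tag per subject (a single tag is fine).
#' @param k outer folds (default 10).
#' @param innerK inner folds (default 5).
#' @param seed integer seed.
#' @return list of `k` fold objects, each with `$test`, `$train` (absolute
#'   index vectors) and `$inner` (list of `innerK` absolute-index validation
#'   sets partitioning `$train`).
#' @export
nestedCvSplit <- function(labels, cohorts = NULL, k = 10, innerK = 5,
                          seed = 1L) {
  n <- length(labels)
  if (is.null(cohorts)) cohorts <- rep("all", n)
  strata <- interaction(cohorts, labels, drop = TRUE)
  tab <- table(strata)
  if (min(tab) < k)
    stop("outer fold count k=", k, " exceeds the smallest (cohort x class) ",
         "stratum '", names(tab)[which.min(tab)], "' (n=", min(tab), ")")
  outer <- stratifiedFolds(strata, k, deriveSeed(seed, "outer-folds"))
  lapply(seq_len(k), function(f) {
    test <- outer[[f]]
    train <- setdiff(seq_len(n), test)
    inner <- stratifiedFolds(droplevels(strata[train]), innerK,
                             deriveSeed(seed, "inner-folds", f))
    list(test = test, train = train,
         inner = lapply(inner, function(v) train[v]))
  })
}

#' Classification metrics: accuracy, AUC, confusion matrix, ROC
#'
#' Accuracy is the fraction of correct argmax predictions. Binary AUC is the
#' probability that a random positive outscores a random negative (ties
#' counted 1/2), computed from the positive-class score; the 3-class task
#' reports macro-averaged one-vs-rest AUC (an extension — the reference
#' study reports only accuracy for the 3-way task). Confusion-matrix rows
#' are true classes. With single-class truth the AUC is reported as `NA`,
#' not 0.
#'
#' @param truth true class labels.
#' @param scores subjects x classes score matrix with class-label column
#'   names.
#' @param predicted optional predicted labels; defaults to the score argmax.
#' @return list with `accuracy`, `auc`, `confusion` (matrix), `roc`
#'   (data.frame of binary ROC points: fpr, tpr, threshold; `NULL` for
#'   3-class), `n`.
#' @export
computeMetrics <- function(truth, scores, predicted = NULL) {
  scores <- as.matrix(scores)
  classLabels <- colnames(scores)
  stopifnot(!is.null(classLabels))
  truth <- factor(as.character(truth), levels = classLabels)
  if (is.null(predicted))
    predicted <- classLabels[max.col(scores, ties.method = "first")]
  predicted <- factor(as.character(predicted), levels = classLabels)
  acc <- mean(predicted == truth)
  cm <- table(truth = truth, predicted = predicted)
  auc <- NA_real_
  rocdf <- NULL
  present <- levels(droplevels(truth))
  if (length(classLabels) == 2L) {
    if (length(present) == 2L) {
      r <- pROC::roc(response = truth, predictor = scores[, 2L],
                     levels = classLabels, direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(r))
      rocdf <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                          threshold = r$thresholds)
      rocdf <- rocdf[order(rocdf$fpr, rocdf$tpr), ]
      rownames(rocdf) <- NULL
    }
  } else {
    ovr <- vapply(classLabels, function(cl) {
      pos <- truth == cl
      if (!any(pos) || all(pos)) return(NA_real_)
      r <- pROC::roc(response = factor(ifelse(pos, "pos", "neg"),
                                       levels = c("neg", "pos")),
                     predictor = scores[, cl], direction = "<", quiet = TRUE)
      as.numeric(pROC::auc(r))
    }, numeric(1))
    auc <- mean(ovr, na.rm = !all(is.na(ovr)))
    if (all(is.na(ovr))) auc <- NA_real_
  }
  list(accuracy = acc, auc = auc, confusion = cm, roc = rocdf,
       n = length(truth))
}

#' Clinical-workflow stratification thresholds
#'
#' Extreme-baseline cutoffs and the absolute follow-up change defining a
#' "marked" short-term change, per scale. The shipped defaults (MMSE:
#' baseline outside [24, 29], change >= 2 points; ADAS-13: baseline outside
#' [8, 30], change >= 6 points) are documented placeholders for
#' demonstrating the workflow — the stratification is intentionally
#' configurable and users should review the cutoffs for their setting.
#'
#' @param scale `"mmse"` or `"adas13"`.
#' @param low_baseline,high_baseline baseline scores outside
#'   `[low_baseline, high_baseline]` define baseline edge-cases.
#' @param change absolute score change at follow-up defining follow-up
#'   edge-cases (> 0).
#' @return a `WorkflowThresholds` list.
#' @export
workflowThresholds <- function(scale = c("mmse", "adas13"),
                               low_baseline = NULL, high_baseline = NULL,
                               change = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "mmse") list(low = 24, high = 29, change = 2)
         else list(low = 8, high = 30, change = 6)
  th <- list(scale = scale,
             low_baseline = if (is.null(low_baseline)) def$low else low_baseline,
             high_baseline = if (is.null(high_baseline)) def$high else high_baseline,
             change = if (is.null(change)) def$change else change)
  rng <- defaultScaleRanges()[[scale]]
  if (th$low_baseline < rng[1] || th$high_baseline > rng[2] ||
      th$low_baseline > th$high_baseline)
    stop("baseline thresholds outside the ", scale, " scale range")
  if (th$change <= 0) stop("change cutoff must be > 0")
  structure(th, class = "WorkflowThresholds")
}

#' Stratify subjects by a clinical decision workflow
#'
#' Baseline edge-cases (BE) have extreme baseline scores (outside
#' `[low_baseline, high_baseline]`); among the rest, follow-up edge-cases
#' (FE) show a marked absolute change (>= `change`) at follow-up; the
#' remaining cognitively consistent (CC) subjects have mid-range baselines
#' and marginal short-term change — the group for which multimodal
#' longitudinal prediction matters most. Every subject maps to exactly one
#' group.
#'
#' @param score_t0,score_t1 baseline and follow-up scores (vectors).
#' @param thresholds a [workflowThresholds()].
#' @return factor with levels BE, FE, CC.
#' @export
stratifyClinicalWorkflow <- function(score_t0, score_t1, thresholds) {
  stopifnot(inherits(thresholds, "WorkflowThresholds"),
            length(score_t0) == length(score_t1),
            !anyNA(score_t0), !anyNA(score_t1))
  be <- score_t0 < thresholds$low_baseline | score_t0 > thresholds$high_baseline
  fe <- !be & abs(score_t1 - score_t0) >= thresholds$change
  grp <- ifelse(be, "BE", ifelse(fe, "FE", "CC"))
  factor(grp, levels = c("BE", "FE", "CC"))
}

#' Stratify subjects by last available ground-truth visit
#'
#' Subjects whose latest trajectory-assignment timepoint falls at or before
#' `nearMaxMonth` form the near-future group; those at or after
#' `farMinMonth` the distant-future group. Subjects strictly between the
#' bands fall in neither and are flagged as `"gap"`.
#'
#' @param assignments the `assignments` data.frame from [labelCohort()]
#'   (uses its `last_month` column), or a numeric vector of last months.
#' @param nearMaxMonth upper bound of the near-future band (default 36).
#' @param farMinMonth lower bound of the distant-future band (default 48).
#' @return factor (levels near_future, distant_future, gap) named by
#'   subject id when available.
#' @export
stratifyBySpan <- function(assignments, nearMaxMonth = 36, farMinMonth = 48) {
  if (is.data.frame(assignments)) {
    last <- assignments$last_month
    nm <- assignments$subject_id
  } else {
    last <- assignments
    nm <- names(assignments)
  }
  grp <- ifelse(last <= nearMaxMonth, "near_future",
                ifelse(last >= farMinMonth, "distant_future", "gap"))
  stats::setNames(factor(grp, levels = c("near_future", "distant_future",
                                         "gap")), nm)
}

#' Compare two models' per-fold metric samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact null
#' distribution for small tie-free samples (n <= 10 per side), normal
#' approximation with tie correction otherwise.
#'
#' @param a,b numeric per-fold metric samples (>= 3 folds each).
#' @return list with `p.value`, `statistic` (U for sample `a`) and `method`.
#' @export
compareModels <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 folds per model")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Select the second (follow-up) timepoint for a subject
#'
#' Returns the latest visit within `windowMonths` of baseline that has both
#' a non-missing score on the task scale and a complete cortical-thickness
#' vector; subjects with data missing at the 12-month visit but complete at
#' 6 months thus contribute their 6-month visit. `NULL` when no visit in
#' the window qualifies (the subject is then excluded from two-timepoint
#' analyses).
#'
#' @param subject a subject record from [getSubject()].
#' @param scale `"mmse"` or `"adas13"`.
#' @param windowMonths window after baseline (default 12).
#' @return list with `month`, `score`, `ct` (vector), and `index` into the
#'   subject's visit table, or `NULL`.
#' @export
selectFollowup <- function(subject, scale, windowMonths = 12) {
  .checkScale(scale)
  vis <- subject$visits
  has_ct <- if (ncol(subject$ct)) stats::complete.cases(subject$ct)
            else rep(FALSE, nrow(vis))
  ok <- vis$month > 0 & vis$month <= windowMonths &
    !is.na(vis[[scale]]) & has_ct
  if (!any(ok)) return(NULL)
  i <- max(which(ok))
  list(month = vis$month[i], score = vis[[scale]][i],
       ct = subject$ct[i, ], index = i)
}

#' Build the two-timepoint prediction-input bundle for a cohort
#'
#' Keeps subjects with a complete baseline (month-0 score on `scale` plus CT
#' vector) and a qualifying follow-up per [selectFollowup()]; everyone else
#' is listed in `excluded` with a reason. The bundle feeds both the LSN and
#' the concatenated-feature reference models.
#'
#' @param cohort a [Cohort].
#' @param scale `"mmse"` or `"adas13"`.
#' @param windowMonths follow-up selection window (default 12).
#' @return list with `subject_id`, matrices `ct0`, `ct1`, vectors `score0`,
#'   `score1`, `age`, `apoe4`, `cohort` (source tags), `followup_month`, and
#'   an `excluded` data.frame.
#' @export
predictionInputs <- function(cohort, scale, windowMonths = 12) {
  .checkScale(scale)
  ids <- subjectIds(cohort)
  keep <- list(); excl <- list()
  for (id in ids) {
    s <- getSubject(cohort, id)
    b <- which(s$visits$month == 0)
    reason <- NULL
    if (!length(b) || is.na(s$visits[[scale]][b])) {
      reason <- "no baseline score"
    } else if (!ncol(s$ct) || !stats::complete.cases(s$ct[b, , drop = FALSE])) {
      reason <- "no baseline CT"
    } else {
      fu <- selectFollowup(s, scale, windowMonths)
      if (is.null(fu)) reason <- "no qualifying follow-up within window"
    }
    if (!is.null(reason)) {
      excl[[id]] <- data.frame(subject_id = id, reason = reason,
                               stringsAsFactors = FALSE)
    } else {
      keep[[id]] <- list(id = id, ct0 = s$ct[b, ], ct1 = fu$ct,
                         score0 = s$visits[[scale]][b], score1 = fu$score,
                         age = s$info$age, apoe4 = s$info$apoe4,
                         cohort = s$info$cohort, fu_month = fu$month)
    }
  }
  if (!length(keep))
    stop("no subject has complete two-timepoint data")
  list(
    subject_id = vapply(keep, `[[`, character(1), "id"),
    ct0 = do.call(rbind, lapply(keep, `[[`, "ct0")),
    ct1 = do.call(rbind, lapply(keep, `[[`, "ct1")),
    score0 = vapply(keep, `[[`, numeric(1), "score0"),
    score1 = vapply(keep, `[[`, numeric(1), "score1"),
    age = vapply(keep, `[[`, numeric(1), "age"),
    apoe4 = vapply(keep, function(x) as.numeric(x$apoe4), numeric(1)),
    cohort = vapply(keep, `[[`, character(1), "cohort"),
    followup_month = vapply(keep, `[[`, numeric(1), "fu_month"),
    excluded = if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
               else data.frame(subject_id = character(), reason = character())
  )
}

.subsetInputs <- function(inputs, idx) {
  list(subject_id = inputs$subject_id[idx],
       ct0 = inputs$ct0[idx, , drop = FALSE],
       ct1 = inputs$ct1[idx, , drop = FALSE],
       score0 = inputs$score0[idx], score1 = inputs$score1[idx],
       age = inputs$age[idx], apoe4 = inputs$apoe4[idx],
       cohort = inputs$cohort[idx])
}

.cellName <- function(model, spec) {
  paste(model, spec$feature_set, spec$timepoints, sep = "|")
}

#' Default LSN width grid
#'
#' A diagonal cover of the architecture's design ranges (branch 25-50,
#' embedding 10-20, head 10-20) searched on inner folds; smaller
#' configurations are listed first so accuracy ties resolve toward the
#' simpler model.
#' @return data.frame with columns `branch_width`, `embedding_dim`,
#'   `head_width`.
#' @export
lsnDefaultGrid <- function() {
  data.frame(branch_width = c(25L, 35L, 50L),
             embedding_dim = c(10L, 15L, 20L),
             head_width = c(10L, 15L, 20L))
}

.lsnWithWidths <- function(cfg, row) {
  cfg$branch_width <- row$branch_width
  cfg$embedding_dim <- row$embedding_dim
  cfg$head_width <- row$head_width
  cfg
}

# train one LSN on tr, selecting widths by mean inner-fold accuracy when the
# grid has more than one row
.trainLSNGrid <- function(inputs, labels, tr, inner, cfg, grid, seed) {
  classLabels <- levels(labels)
  best_row <- 1L
  if (!is.null(grid) && nrow(grid) > 1L) {
    acc <- matrix(NA_real_, nrow(grid), length(inner))
    for (v in seq_along(inner)) {
      val <- inner[[v]]
      sub_tr <- setdiff(tr, val)
      for (g in seq_len(nrow(grid))) {
        cfg_g <- .lsnWithWidths(cfg, grid[g, ])
        cfg_g$seed <- deriveSeed(seed, "lsn-grid", v * 100L + g)
        class(cfg_g) <- "LSNConfig"
        fit <- trainLSN(.subsetInputs(inputs, sub_tr), labels[sub_tr], cfg_g,
                        classLabels = classLabels)
        sc <- predictLSN(fit, .subsetInputs(inputs, val))
        pred <- colnames(sc)[max.col(sc, ties.method = "first")]
        acc[g, v] <- mean(pred == as.character(labels[val]))
      }
    }
    best_row <- which.max(rowMeans(acc))  # first max: smaller model on ties
  }
  cfg_b <- if (is.null(grid)) cfg else .lsnWithWidths(cfg, grid[best_row, ])
  cfg_b$seed <- seed
  class(cfg_b) <- "LSNConfig"
  trainLSN(.subsetInputs(inputs, tr), labels[tr], cfg_b,
           classLabels = classLabels)
}

# fit one model on the training indices of one fold and score the test set
.fitScoreFold <- function(model, spec, inputs, labels, fold, innerK, seed,
                          lsnConfigBase, grids, keepModel = FALSE,
                          lsnGrid = NULL) {
  tr <- fold$train; te <- fold$test
  classLabels <- levels(labels)
  if (model == "LSN") {
    cfg <- lsnConfigBase
    cfg$n_classes <- length(classLabels)
    cfg$roi_count <- ncol(inputs$ct0)
    fit <- .trainLSNGrid(inputs, labels, tr, fold$inner, cfg, lsnGrid, seed)
    sc <- predictLSN(fit, .subsetInputs(inputs, te))
  } else {
    X <- buildFeatureMatrix(inputs, spec)
    fit <- fitReference(model, X[tr, , drop = FALSE], labels[tr],
                        grid = grids[[model]], innerK = innerK, seed = seed)
    sc <- predictReference(fit, X[te, , drop = FALSE])
    # inner-fold class dropout can shrink columns; re-expand
    if (!identical(colnames(sc), classLabels)) {
      full <- matrix(0, nrow(sc), length(classLabels),
                     dimnames = list(NULL, classLabels))
      full[, colnames(sc)] <- sc
      sc <- full
    }
  }
  list(scores = sc, model = if (keepModel) fit)
}

#' Run the factorial prediction experiment
#'
#' The full evaluation harness: for each model x feature-set x timepoint-set
#' cell, models are trained on the outer training folds of a nested
#' stratified (cohort x class) cross-validation and scored on the held-out
#' test folds, so every reported prediction is out-of-fold. The LSN applies
#' only to the two-timepoint CA+CT cell. Metrics are reported per fold and
#' pooled, overall and stratified by the BE/FE/CC clinical-workflow groups.
#'
#' @param inputs prediction-input bundle from [predictionInputs()].
#' @param labels named class labels covering `inputs$subject_id`.
#' @param scale `"mmse"` or `"adas13"`.
#' @param models character subset of LR, SVM, RF, ANN, LSN.
#' @param specs list of [featureSpec()]; defaults to the 2x3 design.
#' @param k outer folds (default 10).
#' @param innerK inner folds for hyperparameter selection (default 5).
#' @param seed global seed; per-fold seeds derive from it.
#' @param lsn an [lsnConfig()] template for the LSN cells (training scalars;
#'   widths come from `lsnGrid` when it has several rows).
#' @param lsnGrid data.frame of LSN width combinations searched on the inner
#'   folds ([lsnDefaultGrid()] by default); a single row pins the widths.
#' @param grids optional named list of hyperparameter grids per model kind.
#' @param thresholds a [workflowThresholds()] for group stratification.
#' @param keepModels keep the per-fold fitted models (for replication-style
#'   testing on another cohort).
#' @return an `EvaluationReport` list: `cells` (per-cell per-fold and pooled
#'   metrics, group metrics), `predictions` (long data.frame of out-of-fold
#'   scores), `folds`, `groups`, `seed`.
#' @export
runExperiment <- function(inputs, labels, scale,
                          models = c("LR", "SVM", "RF", "ANN", "LSN"),
                          specs = NULL, k = 10, innerK = 5, seed = 1L,
                          lsn = lsnConfig(), lsnGrid = lsnDefaultGrid(),
                          grids = list(),
                          thresholds = workflowThresholds(scale),
                          keepModels = FALSE) {
  .checkScale(scale)
  labels <- labels[inputs$subject_id]
  if (anyNA(labels)) stop("labels missing for some input subjects")
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  if (is.null(specs)) {
    specs <- list()
    for (fs in c("CA", "CT", "CA_CT"))
      for (tp in c("baseline", "baseline_followup"))
        specs[[length(specs) + 1L]] <- featureSpec(fs, tp, scale)
  }
  folds <- nestedCvSplit(labels, inputs$cohort, k = k, innerK = innerK,
                         seed = seed)
  groups <- stratifyClinicalWorkflow(inputs$score0, inputs$score1, thresholds)
  classLabels <- levels(labels)

  cells <- list(); pred_rows <- list(); fold_models <- list()
  for (model in models) {
    model_specs <- if (model == "LSN")
      list(featureSpec("CA_CT", "baseline_followup", scale)) else specs
    for (spec in model_specs) {
      cell <- .cellName(model, spec)
      scores <- matrix(NA_real_, n, length(classLabels),
                       dimnames = list(inputs$subject_id, classLabels))
      fold_of <- integer(n)
      per_fold <- list()
      cms <- list()
      for (f in seq_along(folds)) {
        res <- .fitScoreFold(model, spec, inputs, labels, folds[[f]],
                             innerK, deriveSeed(seed, cell, f), lsn, grids,
                             keepModel = keepModels, lsnGrid = lsnGrid)
        te <- folds[[f]]$test
        scores[te, ] <- res$scores
        fold_of[te] <- f
        met <- computeMetrics(labels[te], res$scores)
        per_fold[[f]] <- data.frame(fold = f, accuracy = met$accuracy,
                                    auc = met$auc, n = met$n)
        if (keepModels) fold_models[[cell]][[f]] <- res$model
      }
      pooled <- computeMetrics(labels, scores)
      grp_metrics <- lapply(levels(groups), function(g) {
        gi <- which(groups == g)
        if (length(gi) < 2) return(list(n = length(gi), accuracy = NA_real_,
                                        auc = NA_real_))
        m <- computeMetrics(labels[gi], scores[gi, , drop = FALSE])
        list(n = m$n, accuracy = m$accuracy, auc = m$auc)
      })
      names(grp_metrics) <- levels(groups)
      cells[[cell]] <- list(model = model, spec = spec,
                            per_fold = do.call(rbind, per_fold),
                            pooled = pooled, groups = grp_metrics)
      pred_rows[[cell]] <- data.frame(
        subject_id = inputs$subject_id, model = model,
        feature_set = spec$feature_set, timepoints = spec$timepoints,
        fold = fold_of, truth = as.character(labels),
        predicted = classLabels[max.col(scores, ties.method = "first")],
        group = as.character(groups),
        scores, check.names = FALSE, row.names = NULL)
    }
  }
  structure(list(cells = cells,
                 predictions = do.call(rbind, c(pred_rows,
                                                make.row.names = FALSE)),
                 folds = folds, groups = groups, seed = seed,
                 classLabels = classLabels, scale = scale,
                 models = if (keepModels) fold_models),
            class = "EvaluationReport")
}

#' Replication-style test of fold models on an independent cohort
#'
#' Applies every per-fold model of one experiment cell (trained on cohort A,
#' `keepModels = TRUE`) to an independent bundle and averages the metrics
#' over the fold-model instances.
#'
#' @param report an `EvaluationReport` produced with `keepModels = TRUE`.
#' @param cell cell name (`"<model>|<feature_set>|<timepoints>"`).
#' @param inputs prediction-input bundle for the replication cohort.
#' @param labels named class labels for the replication cohort.
#' @return data.frame of per-fold-model accuracy and AUC plus their means.
#' @export
replicationTest <- function(report, cell, inputs, labels) {
  stopifnot(!is.null(report$models), cell %in% names(report$models))
  labels <- droplevels(factor(labels[inputs$subject_id],
                              levels = report$classLabels))
  spec <- report$cells[[cell]]$spec
  model_kind <- report$cells[[cell]]$model
  rows <- lapply(seq_along(report$models[[cell]]), function(f) {
    fit <- report$models[[cell]][[f]]
    sc <- if (model_kind == "LSN") predictLSN(fit, inputs)
          else predictReference(fit, buildFeatureMatrix(inputs, spec))
    if (!identical(colnames(sc), report$classLabels)) {
      full <- matrix(0, nrow(sc), length(report$classLabels),
                     dimnames = list(NULL, report$classLabels))
      full[, colnames(sc)] <- sc
      sc <- full
    }
    met <- computeMetrics(labels, sc)
    data.frame(fold_model = f, accuracy = met$accuracy, auc = met$auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- c(accuracy = mean(out$accuracy),
                          auc = mean(out$auc, na.rm = TRUE))
  out
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON (per-cell metrics, fold membership, seed) plus
#' a flat CSV of per-cell pooled metrics next to it.
#'
#' @param report an `EvaluationReport`.
#' @param path output JSON path; the CSV gets extension `.csv`.
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, path) {
  cells <- lapply(report$cells, function(cl) {
    list(model = cl$model,
         feature_set = cl$spec$feature_set,
         timepoints = cl$spec$timepoints,
         per_fold = cl$per_fold,
         pooled = list(accuracy = cl$pooled$accuracy, auc = cl$pooled$auc,
                       confusion = as.data.frame.matrix(
                         unclass(cl$pooled$confusion))),
         groups = cl$groups)
  })
  obj <- list(seed = report$seed, scale = report$scale,
              class_labels = report$classLabels,
              folds = lapply(report$folds, function(f) f$test),
              cells = cells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  flat <- do.call(rbind, lapply(names(report$cells), function(nm) {
    cl <- report$cells[[nm]]
    data.frame(cell = nm, model = cl$model,
               feature_set = cl$spec$feature_set,
               timepoints = cl$spec$timepoints,
               accuracy = cl$pooled$accuracy, auc = cl$pooled$auc,
               mean_fold_accuracy = mean(cl$per_fold$accuracy),
               mean_fold_auc = mean(cl$per_fold$auc))
  }))
  utils::write.csv(flat, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
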