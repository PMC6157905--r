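#' Feature-set specification for the reference models
#'
#' The evaluation design crosses two timepoint sets (baseline only, baseline
#' + follow-up) with three feature sets: clinical attributes (CA: clinical
#' score(s), age, APOE4), cortical thickness (CT: 78 or 156 ROI values), and
#' their combination (CA_CT). Feature vectors are concatenated in the fixed
#' order score_t0 (, score_t1), age, apoe4 (, ct_t0 (, ct_t1)).
#'
#' @param feature_set `"CA"`, `"CT"` or `"CA_CT"`.
#' @param timepoints `"baseline"` or `"baseline_followup"`.
#' @param scale `"mmse"` or `"adas13"`.
#' @return a `FeatureSpec` list.
#' @export
featureSpec <- function(feature_set = c("CA", "CT", "CA_CT"),
                        timepoints = c("baseline", "baseline_followup"),
                        scale = c("mmse", "adas13")) {
  structure(list(feature_set = match.arg(feature_set),
                 timepoints = match.arg(timepoints),
                 scale = match.arg(scale)),
            class = "FeatureSpec")
}

#' Expected feature-vector length for a specification
#' @param spec a [featureSpec()].
#' @param roi_count ROIs per timepoint.
#' @return integer length (3, 4, 78, 156, 81 or 160 at the default atlas).
#' @export
featureLength <- function(spec, roi_count = 78) {
  two <- spec$timepoints == "baseline_followup"
  ca <- if (spec$feature_set %in% c("CA", "CA_CT")) (if (two) 4L else 3L) else 0L
  ct <- if (spec$feature_set %in% c("CT", "CA_CT"))
    (if (two) 2L else 1L) * roi_count else 0L
  ca + ct
}

#' Build the concatenated feature matrix for a specification
#'
#' @param inputs prediction-input bundle (see [predictionInputs()]).
#' @param spec a [featureSpec()].
#' @return numeric matrix, one row per subject, columns in the canonical
#'   concatenation order.
#' @export
buildFeatureMatrix <- function(inputs, spec) {
  two <- spec$timepoints == "baseline_followup"
  if (two && (is.null(inputs$ct1) || is.null(inputs$score1)))
    stop("specification requires follow-up data but the input bundle has none")
  cols <- list()
  if (spec$feature_set %in% c("CA", "CA_CT")) {
    cols$score_t0 <- inputs$score0
    if (two) cols$score_t1 <- inputs$score1
    cols$age <- inputs$age
    cols$apoe4 <- inputs$apoe4
  }
  X <- do.call(cbind, cols)
  if (spec$feature_set %in% c("CT", "CA_CT")) {
    X <- cbind(X, inputs$ct0)
    if (two) X <- cbind(X, inputs$ct1)
  }
  if (anyNA(X)) stop("missing values in feature matrix (incomplete visits ",
                     "for the requested specification)")
  X
}

#' Make one subject's flat feature vector
#' @param subjectInputs single-subject bundle (scalars plus length-78 `ct0`
#'   and optionally `ct1`).
#' @inheritParams buildFeatureMatrix
#' @return numeric vector.
#' @export
makeFeatureVector <- function(subjectInputs, spec) {
  si <- subjectInputs
  if (!is.null(si$ct0) && is.null(dim(si$ct0))) si$ct0 <- matrix(si$ct0, 1)
  if (!is.null(si$ct1) && is.null(dim(si$ct1))) si$ct1 <- matrix(si$ct1, 1)
  drop(buildFeatureMatrix(si, spec))
}

#' Train-statistics standardization
#'
#' Column-wise z-scoring of train and test matrices using means and standard
#' deviations computed from the training matrix only. Zero-variance training
#' columns are mapped to 0 in both matrices, with a warning.
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   `NULL`).
#' @return list with `train`, `test`, and `stats` (mean/sd per column).
#' @export
standardizeFeatures <- function(train, test = NULL) {
  stopifnot(nrow(train) > 0)
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  zero <- !is.finite(sd_) | sd_ == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) standardized to 0")
    sd_[zero] <- 1
  }
  z <- function(X) {
    Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
    Z[, zero] <- 0
    Z
  }
  list(train = z(train), test = if (!is.null(test)) z(test),
       stats = list(mean = mu, sd = sd_, zero_variance = zero))
}

.defaultGrid <- function(kind) {
  switch(kind,
    LR = list(lambda = 10^seq(-3, 2, length.out = 8)),
    SVM = expand.grid(kernel = c("radial", "linear"),
                      cost = c(0.1, 1, 10), gamma = c(0.01, 0.1),
                      stringsAsFactors = FALSE),
    RF = expand.grid(ntree = c(100L, 500L), maxnodes = c(NA, 32L)),
    ANN = expand.grid(size = c(25L, 50L), decay = c(1e-3, 1e-1)),
    stop("unknown kind: ", kind)
  )
}

.fitOne <- function(kind, X, y, hp, seed) {
  set.seed(seed)
  k <- nlevels(y)
  switch(kind,
    LR = glmnet::glmnet(X, y, alpha = 1, lambda = hp$lambda,
                        family = if (k == 2) "binomial" else "multinomial"),
    SVM = e1071::svm(X, y, kernel = hp$kernel, cost = hp$cost,
                     gamma = if (hp$kernel == "radial") hp$gamma else 0.1,
                     scale = FALSE),
    RF = if (is.na(hp$maxnodes))
           randomForest::randomForest(X, y, ntree = hp$ntree)
         else
           randomForest::randomForest(X, y, ntree = hp$ntree,
                                      maxnodes = hp$maxnodes),
    ANN = {
      std <- standardizeFeatures(X)
      fit <- if (k == 2)
        nnet::nnet(std$train, as.numeric(y) - 1, size = hp$size,
                   decay = hp$decay, entropy = TRUE, maxit = 200,
                   trace = FALSE, MaxNWts = 50000)
      else
        nnet::nnet(std$train, nnet::class.ind(y), size = hp$size,
                   decay = hp$decay, softmax = TRUE, maxit = 200,
                   trace = FALSE, MaxNWts = 50000)
      list(fit = fit, stats = std$stats)
    }
  )
}

.scoreOne <- function(kind, fit, X, classLabels) {
  k <- length(classLabels)
  out <- switch(kind,
    LR = {
      pr <- stats::predict(fit, X, type = "response")
      if (k == 2) cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
    },
    SVM = {
      pred <- stats::predict(fit, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      sc <- matrix(0, nrow(X), k, dimnames = list(NULL, classLabels))
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        sc[, pair[1]] <- sc[, pair[1]] + dv[, cn]
        sc[, pair[2]] <- sc[, pair[2]] - dv[, cn]
      }
      # softmax keeps per-class ordering (monotone), bounds scores in (0,1)
      .softmax(sc)
    },
    RF = stats::predict(fit, X, type = "prob"),
    ANN = {
      Xs <- sweep(sweep(X, 2, fit$stats$mean), 2,
                  pmax(fit$stats$sd, 1e-12), "/")
      Xs[, fit$stats$zero_variance] <- 0
      pr <- stats::predict(fit$fit, Xs)
      if (k == 2) cbind(1 - pr[, 1], pr[, 1]) else pr
    }
  )
  out <- as.matrix(out)
  colnames(out) <- classLabels
  out
}

#' Fit a reference classifier with inner-fold hyperparameter selection
#'
#' The four baselines — lasso-regularized logistic regression (LR), support
#' vector machine (SVM), random forest (RF) and a feed-forward artificial
#' neural network (ANN) — consume the same concatenated feature vectors.
#' Hyperparameters are selected by mean accuracy over stratified inner folds
#' (ties broken toward the smaller/simpler setting, which is listed first in
#' each grid), then the model is refit on all training data. Features are
#' standardized with training statistics for LR and SVM (per fold and for
#' the final refit); RF consumes raw features; the ANN standardizes
#' internally for trainability. Deterministic given `seed`.
#'
#' @param kind `"LR"`, `"SVM"`, `"RF"` or `"ANN"`.
#' @param X numeric feature matrix.
#' @param y class labels (factor or character).
#' @param grid data.frame/list of hyperparameter combinations; `NULL` for
#'   the built-in default grid. A single-row grid skips the inner search.
#' @param innerK number of stratified inner folds (default 5).
#' @param seed integer seed.
#' @return a `ReferenceModel` list with elements `kind`, `fit`, `hyper`,
#'   `stats` (standardization statistics or `NULL`), `classLabels`.
#' @export
fitReference <- function(kind, X, y, grid = NULL, innerK = 5, seed = 1L) {
  kind <- match.arg(kind, c("LR", "SVM", "RF", "ANN"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training requires at least 2 classes")
  if (is.null(grid)) grid <- .defaultGrid(kind)
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  standardize <- kind %in% c("LR", "SVM")
  classLabels <- levels(y)

  if (nrow(grid) > 1L) {
    folds <- stratifiedFolds(y, k = innerK,
                             seed = deriveSeed(seed, "inner", 1L))
    acc <- matrix(NA_real_, nrow(grid), innerK)
    for (f in seq_len(innerK)) {
      te <- folds[[f]]
      tr <- setdiff(seq_along(y), te)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (standardize) {
        std <- suppressWarnings(standardizeFeatures(Xtr, Xte))
        Xtr <- std$train; Xte <- std$test
      }
      for (gidx in seq_len(nrow(grid))) {
        fit <- tryCatch(
          .fitOne(kind, Xtr, droplevels(y[tr]), grid[gidx, , drop = FALSE],
                  deriveSeed(seed, "fit", f * 1000L + gidx)),
          error = function(e) NULL)
        if (is.null(fit)) next
        sc <- .scoreOne(kind, fit, Xte, levels(droplevels(y[tr])))
        pred <- colnames(sc)[max.col(sc, ties.method = "first")]
        acc[gidx, f] <- mean(pred == as.character(y[te]))
      }
    }
    mean_acc <- rowMeans(acc, na.rm = TRUE)
    best <- which.max(mean_acc)  # first max: smaller model wins ties
  } else best <- 1L

  stats_ <- NULL
  Xfit <- X
  if (standardize) {
    std <- suppressWarnings(standardizeFeatures(X))
    Xfit <- std$train
    stats_ <- std$stats
  }
  fit <- .fitOne(kind, Xfit, y, grid[best, , drop = FALSE],
                 deriveSeed(seed, "final-fit", best))
  structure(list(kind = kind, fit = fit, hyper = grid[best, , drop = FALSE],
                 stats = stats_, classLabels = classLabels),
            class = "ReferenceModel")
}

#' Class scores/probabilities from a fitted reference model
#'
#' Applies the model's stored training standardization (LR/SVM) and returns
#' a subjects x classes score matrix; SVM scores derive from decision values
#' (monotone in the decision function, suitable for ROC/AUC).
#'
#' @param model a `ReferenceModel` from [fitReference()].
#' @param X feature matrix on the original scale.
#' @return numeric score matrix with class-label column names.
#' @export
predictReference <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$stats)) {
    X <- sweep(sweep(X, 2, model$stats$mean), 2,
               pmax(model$stats$sd, 1e-12), "/")
    X[, model$stats$zero_variance] <- 0
  }
  .scoreOne(model$kind, model$fit, X, model$classLabels)
}
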