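#' Longitudinal Siamese Network configuration
#'
#' Architecture and training settings for the LSN. The branch depth is fixed
#' at 4 hidden layers; branch width, distance-embedding dimension and head
#' width default to the midpoints of the design grids (25-50, 10-20, 10-20).
#' Training uses Adam with softmax cross-entropy and early stopping on an
#' inner validation split.
#'
#' @param roi_count cortical ROI count per timepoint (78).
#' @param branch_width nodes per branch hidden layer (grid 25-50).
#' @param embedding_dim distance-embedding length (grid 10-20).
#' @param head_width nodes in the prediction-head hidden layer (grid 10-20).
#' @param n_classes 2 (MMSE task) or 3 (ADAS-13 task).
#' @param learning_rate Adam step size.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param seed integer seed controlling initialization, the validation split
#'   and batch order.
#' @return an `LSNConfig` list.
#' @export
lsnConfig <- function(roi_count = 78, branch_width = 35, embedding_dim = 15,
                      head_width = 15, n_classes = 2,
                      learning_rate = 1e-3, max_epochs = 300,
                      batch_size = 32, early_stop_patience = 20,
                      val_fraction = 0.15, seed = 1L) {
  if (!n_classes %in% 2:3) stop("n_classes must be 2 or 3")
  if (branch_width < 1 || embedding_dim < 1 || head_width < 1)
    stop("invalid dimensions")
  structure(list(
    roi_count = roi_count, branch_width = branch_width,
    embedding_dim = embedding_dim, head_width = head_width,
    n_classes = n_classes, n_branch_layers = 4L,
    learning_rate = learning_rate, max_epochs = max_epochs,
    batch_size = batch_size, early_stop_patience = early_stop_patience,
    val_fraction = val_fraction, seed = as.integer(seed)
  ), class = "LSNConfig")
}

#' Closed-form LSN parameter count
#'
#' Weights plus biases of the shared branch (4 hidden rectifier layers and a
#' linear map to the embedding), the 1-node APOE4 gate, and the prediction
#' head (one hidden layer then the softmax layer). The shared branch is
#' counted once: weight sharing is structural.
#'
#' @param config an [lsnConfig()].
#' @return integer parameter count.
#' @export
countLSNParams <- function(config) {
  p <- config$roi_count; w <- config$branch_width
  e <- config$embedding_dim; h <- config$head_width; k <- config$n_classes
  branch <- (p * w + w) + 3 * (w * w + w) + (w * e + e)
  gate <- 2
  head <- (e + 3) * h + h + h * k + k
  as.integer(branch + gate + head)
}

.initMat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Initialize an untrained LSN
#'
#' Parameters are drawn deterministically from `config$seed` (He-scaled
#' normal weights, zero biases; gate initialized to the identity-leaning
#' g = sigmoid(1) regime via zero weight, unit bias). Standardization
#' statistics start at identity (mean 0, sd 1) and are fitted by
#' [trainLSN()].
#'
#' @param config an [lsnConfig()].
#' @param classLabels optional class labels (defaults to `class_1..k`).
#' @return an [LSNModel] (untrained).
#' @export
buildLSN <- function(config, classLabels = NULL) {
  stopifnot(inherits(config, "LSNConfig"))
  set.seed(deriveSeed(config$seed, "lsn-init"))
  p <- config$roi_count; w <- config$branch_width
  e <- config$embedding_dim; h <- config$head_width; k <- config$n_classes
  dims <- c(p, w, w, w, w, e)
  Wb <- list(); bb <- list()
  for (l in 1:5) {
    Wb[[l]] <- .initMat(dims[l], dims[l + 1])
    bb[[l]] <- numeric(dims[l + 1])
  }
  params <- list(
    Wb = Wb, bb = bb,
    gate_w = 0, gate_b = 1,
    Wh1 = .initMat(e + 3, h), bh1 = numeric(h),
    Wh2 = .initMat(h, k), bh2 = numeric(k),
    stats = list(ct_mean = numeric(p), ct_sd = rep(1, p),
                 score_mean = 0, score_sd = 1,
                 age_mean = 0, age_sd = 1)
  )
  if (is.null(classLabels)) classLabels <- paste0("class_", seq_len(k))
  stopifnot(length(classLabels) == k)
  new("LSNModel", config = unclass(config), params = params,
      classLabels = classLabels,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()))
}

.stdCT <- function(params, ct) {
  sweep(sweep(ct, 2, params$stats$ct_mean), 2, params$stats$ct_sd, "/")
}

# forward through the shared branch; returns activations for backprop
.branchForward <- function(params, X) {
  A <- list(X)
  for (l in 1:4) A[[l + 1]] <- pmax(A[[l]] %*% params$Wb[[l]] +
                                      rep(params$bb[[l]], each = nrow(X)), 0)
  out <- A[[5]] %*% params$Wb[[5]] + rep(params$bb[[5]], each = nrow(X))
  list(out = out, A = A)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass; inputs must already be standardized
.lsnForward <- function(params, ct0s, ct1s, s0s, s1s, ages, apoe4) {
  f0 <- .branchForward(params, ct0s)
  f1 <- .branchForward(params, ct1s)
  emb <- f1$out - f0$out
  g <- 1 / (1 + exp(-(params$gate_w * apoe4 + params$gate_b)))
  mod <- emb * g
  X <- cbind(mod, s0s, s1s, ages)
  H <- pmax(X %*% params$Wh1 + rep(params$bh1, each = nrow(X)), 0)
  logits <- H %*% params$Wh2 + rep(params$bh2, each = nrow(X))
  list(probs = .softmax(logits), f0 = f0, f1 = f1, emb = emb, g = g,
       mod = mod, X = X, H = H)
}

#' Distance embedding of neuroanatomical change
#'
#' Applies the shared branch to the two cortical-thickness vectors
#' (standardized with the model's stored statistics) and returns the signed
#' difference b(ct_t1) - b(ct_t0): a change-representative embedding that is
#' exactly zero for identical inputs and antisymmetric under swapping the
#' timepoints.
#'
#' @param model an [LSNModel].
#' @param ct_t0,ct_t1 numeric matrices (subjects x ROIs) or single vectors.
#' @return numeric matrix, subjects x embedding_dim.
#' @export
distanceEmbedding <- function(model, ct_t0, ct_t1) {
  if (is.null(dim(ct_t0))) ct_t0 <- matrix(ct_t0, nrow = 1)
  if (is.null(dim(ct_t1))) ct_t1 <- matrix(ct_t1, nrow = 1)
  p <- model@config$roi_count
  if (ncol(ct_t0) != p || ncol(ct_t1) != p)
    stop("CT vectors must have length ", p)
  b1 <- .branchForward(model@params, .stdCT(model@params, ct_t1))$out
  b0 <- .branchForward(model@params, .stdCT(model@params, ct_t0))$out
  b1 - b0
}

#' Multiplicative APOE4 modulation
#'
#' Scales the distance embedding elementwise by the scalar gate
#' g = sigmoid(w * apoe4 + c) computed by the 1-node modulation layer from
#' the APOE4 allele count alone.
#'
#' @param model an [LSNModel].
#' @param embedding matrix from [distanceEmbedding()] (or a single vector).
#' @param apoe4 allele counts in {0,1,2}, one per row.
#' @return modulated embedding, same shape as `embedding`.
#' @export
modulateEmbedding <- function(model, embedding, apoe4) {
  if (is.null(dim(embedding))) embedding <- matrix(embedding, nrow = 1)
  if (!all(apoe4 %in% 0:2)) stop("apoe4 must be in {0,1,2}")
  g <- 1 / (1 + exp(-(model@params$gate_w * apoe4 + model@params$gate_b)))
  embedding * g
}

.checkLSNInputs <- function(inputs, p) {
  if (is.null(inputs$ct0) || is.null(inputs$ct1) ||
      anyNA(inputs$ct0) || anyNA(inputs$ct1))
    stop("LSN requires two timepoints: complete CT vectors at baseline ",
         "and follow-up")
  stopifnot(ncol(inputs$ct0) == p, ncol(inputs$ct1) == p,
            nrow(inputs$ct0) == nrow(inputs$ct1))
  if (!all(inputs$apoe4 %in% 0:2)) stop("apoe4 must be in {0,1,2}")
  invisible(inputs)
}

.standardizeInputs <- function(params, inputs) {
  st <- params$stats
  list(
    ct0 = .stdCT(params, inputs$ct0),
    ct1 = .stdCT(params, inputs$ct1),
    s0 = (inputs$score0 - st$score_mean) / st$score_sd,
    s1 = (inputs$score1 - st$score_mean) / st$score_sd,
    age = (inputs$age - st$age_mean) / st$age_sd,
    apoe4 = inputs$apoe4
  )
}

#' Predict trajectory-class probabilities with a trained LSN
#'
#' @param model a trained [LSNModel].
#' @param inputs prediction-input bundle: list with matrices `ct0`, `ct1`
#'   (subjects x ROIs) and vectors `score0`, `score1`, `age`, `apoe4` — see
#'   [predictionInputs()].
#' @return numeric matrix of class probabilities (rows sum to 1), columns
#'   named by class label.
#' @export
predictLSN <- function(model, inputs) {
  .checkLSNInputs(inputs, model@config$roi_count)
  s <- .standardizeInputs(model@params, inputs)
  fw <- .lsnForward(model@params, s$ct0, s$ct1, s$s0, s$s1, s$age, s$apoe4)
  probs <- fw$probs
  colnames(probs) <- model@classLabels
  probs
}

# ---- training ---------------------------------------------------------------

.flatten <- function(params) {
  unlist(params[c("Wb", "bb", "gate_w", "gate_b", "Wh1", "bh1", "Wh2", "bh2")],
         use.names = FALSE)
}

.unflatten <- function(vec, skeleton) {
  out <- skeleton
  pos <- 1L
  for (nm in c("Wb", "bb")) {
    for (l in seq_along(skeleton[[nm]])) {
      n <- length(skeleton[[nm]][[l]])
      out[[nm]][[l]][] <- vec[pos:(pos + n - 1L)]
      pos <- pos + n
    }
  }
  for (nm in c("gate_w", "gate_b", "Wh1", "bh1", "Wh2", "bh2")) {
    n <- length(skeleton[[nm]])
    out[[nm]][] <- vec[pos:(pos + n - 1L)]
    pos <- pos + n
  }
  out
}

# gradient of mean cross-entropy wrt all trainable parameters, same
# structure as params; Y is the n x k one-hot matrix
.lsnBackward <- function(params, fw, ct0s, ct1s, apoe4, Y) {
  n <- nrow(Y)
  dlogits <- (fw$probs - Y) / n
  gWh2 <- t(fw$H) %*% dlogits
  gbh2 <- colSums(dlogits)
  dH <- (dlogits %*% t(params$Wh2)) * (fw$H > 0)
  gWh1 <- t(fw$X) %*% dH
  gbh1 <- colSums(dH)
  dX <- dH %*% t(params$Wh1)
  e_dim <- ncol(fw$emb)
  dmod <- dX[, seq_len(e_dim), drop = FALSE]
  demb <- dmod * fw$g
  dg <- rowSums(dmod * fw$emb)
  dz <- dg * fw$g * (1 - fw$g)
  g_gate_w <- sum(dz * apoe4)
  g_gate_b <- sum(dz)

  gWb <- lapply(params$Wb, function(W) W * 0)
  gbb <- lapply(params$bb, function(b) b * 0)
  backBranch <- function(f, dout) {
    gWb[[5]] <<- gWb[[5]] + t(f$A[[5]]) %*% dout
    gbb[[5]] <<- gbb[[5]] + colSums(dout)
    dA <- dout %*% t(params$Wb[[5]])
    for (l in 4:1) {
      dA <- dA * (f$A[[l + 1]] > 0)
      gWb[[l]] <<- gWb[[l]] + t(f$A[[l]]) %*% dA
      gbb[[l]] <<- gbb[[l]] + colSums(dA)
      if (l > 1) dA <- dA %*% t(params$Wb[[l]])
    }
  }
  backBranch(fw$f1, demb)   # emb = b(ct1) - b(ct0)
  backBranch(fw$f0, -demb)
  list(Wb = gWb, bb = gbb, gate_w = g_gate_w, gate_b = g_gate_b,
       Wh1 = gWh1, bh1 = gbh1, Wh2 = gWh2, bh2 = gbh2)
}

.crossEntropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

.oneHot <- function(y, k) {
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

#' Train a Longitudinal Siamese Network
#'
#' Jointly learns the shared branch, the APOE4 gate and the prediction head
#' by minimizing softmax cross-entropy with Adam. Standardization statistics
#' for CT (per ROI, pooled over both timepoints), clinical scores (pooled
#' over both timepoints) and age are fitted on the training portion only and
#' stored in the model. A stratified `val_fraction` of the data is held out
#' for early stopping (patience in epochs); the parameters of the best
#' validation epoch are returned. Fully deterministic given `config$seed`.
#'
#' @param inputs prediction-input bundle (see [predictLSN()]).
#' @param labels class labels (factor or character), one per subject.
#' @param config an [lsnConfig()]; `n_classes` must match the labels.
#' @param classLabels optional explicit class ordering; defaults to the
#'   factor levels of `labels`.
#' @return a trained [LSNModel] with per-epoch history.
#' @export
trainLSN <- function(inputs, labels, config = lsnConfig(),
                     classLabels = NULL) {
  .checkLSNInputs(inputs, config$roi_count)
  labels <- as.factor(labels)
  if (is.null(classLabels)) classLabels <- levels(labels)
  labels <- factor(labels, levels = classLabels)
  k <- length(classLabels)
  if (k < 2) stop("training requires at least 2 classes present")
  if (k != config$n_classes)
    stop("config$n_classes (", config$n_classes, ") does not match the ",
         k, " observed classes")
  y <- as.integer(labels)
  n <- length(y)

  model <- buildLSN(config, classLabels)
  params <- model@params

  # stratified validation split for early stopping
  set.seed(deriveSeed(config$seed, "lsn-split"))
  val_idx <- unlist(lapply(split(seq_len(n), labels), function(idx) {
    nv <- max(1L, round(length(idx) * config$val_fraction))
    sample(idx, nv)
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)

  # standardization statistics from the training portion only
  ct_tr <- rbind(inputs$ct0[tr_idx, , drop = FALSE],
                 inputs$ct1[tr_idx, , drop = FALSE])
  sc_tr <- c(inputs$score0[tr_idx], inputs$score1[tr_idx])
  sdz <- function(x) { s <- stats::sd(x); if (!is.finite(s) || s == 0) 1 else s }
  params$stats <- list(
    ct_mean = colMeans(ct_tr),
    ct_sd = apply(ct_tr, 2, sdz),
    score_mean = mean(sc_tr), score_sd = sdz(sc_tr),
    age_mean = mean(inputs$age[tr_idx]), age_sd = sdz(inputs$age[tr_idx])
  )
  s <- .standardizeInputs(params, inputs)
  Y <- .oneHot(y, k)

  theta <- .flatten(params)
  m_t <- v_t <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  best_val <- Inf; best_theta <- theta; wait <- 0L
  hist_rows <- vector("list", config$max_epochs)

  set.seed(deriveSeed(config$seed, "lsn-batches"))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      fw <- .lsnForward(params, s$ct0[b, , drop = FALSE],
                        s$ct1[b, , drop = FALSE],
                        s$s0[b], s$s1[b], s$age[b], s$apoe4[b])
      gr <- .lsnBackward(params, fw, s$ct0[b, , drop = FALSE],
                         s$ct1[b, , drop = FALSE], s$apoe4[b],
                         Y[b, , drop = FALSE])
      g <- .flatten(gr)
      if (anyNA(g) || any(!is.finite(g)))
        stop("NaN/Inf gradient at epoch ", epoch,
             "; consider a smaller learning rate")
      step <- step + 1L
      m_t <- beta1 * m_t + (1 - beta1) * g
      v_t <- beta2 * v_t + (1 - beta2) * g^2
      mh <- m_t / (1 - beta1^step)
      vh <- v_t / (1 - beta2^step)
      theta <- theta - lr * mh / (sqrt(vh) + eps)
      params <- .unflatten(theta, params)
    }
    tr_loss <- .crossEntropy(
      .lsnForward(params, s$ct0[tr_idx, , drop = FALSE],
                  s$ct1[tr_idx, , drop = FALSE], s$s0[tr_idx], s$s1[tr_idx],
                  s$age[tr_idx], s$apoe4[tr_idx])$probs,
      Y[tr_idx, , drop = FALSE])
    val_loss <- .crossEntropy(
      .lsnForward(params, s$ct0[val_idx, , drop = FALSE],
                  s$ct1[val_idx, , drop = FALSE], s$s0[val_idx], s$s1[val_idx],
                  s$age[val_idx], s$apoe4[val_idx])$probs,
      Y[val_idx, , drop = FALSE])
    hist_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                     val_loss = val_loss)
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best_theta <- theta; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  params <- .unflatten(best_theta, params)
  new("LSNModel", config = unclass(config), params = params,
      classLabels = classLabels,
      history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                 logical(1))]))
}

#' Serialize a trained LSN to a portable JSON file
#'
#' Config, class labels, standardization statistics and all weight arrays
#' are written as a single JSON document (full double precision).
#' @param model an [LSNModel].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLSNModel <- function(model, path) {
  obj <- list(config = model@config, class_labels = model@classLabels,
              params = list(
                Wb = lapply(model@params$Wb, unname),
                bb = model@params$bb,
                gate_w = model@params$gate_w, gate_b = model@params$gate_b,
                Wh1 = unname(model@params$Wh1), bh1 = model@params$bh1,
                Wh2 = unname(model@params$Wh2), bh2 = model@params$bh2,
                stats = model@params$stats))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LSN model written by [writeLSNModel()]
#' @param path input path.
#' @return an [LSNModel].
#' @export
readLSNModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  params <- list(
    Wb = lapply(p$Wb, as.matrix), bb = lapply(p$bb, as.numeric),
    gate_w = p$gate_w, gate_b = p$gate_b,
    Wh1 = as.matrix(p$Wh1), bh1 = as.numeric(p$bh1),
    Wh2 = as.matrix(p$Wh2), bh2 = as.numeric(p$bh2),
    stats = lapply(p$stats, as.numeric))
  names(params$stats) <- names(p$stats)
  new("LSNModel", config = as.list(obj$config), params = params,
      classLabels = as.character(obj$class_labels),
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()))
}
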