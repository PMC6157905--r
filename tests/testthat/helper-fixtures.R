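# Fixture builders and independent oracles used across the suite.

# small long-format cohort table (3-ROI atlas) for I/O tests
tinyCohortDF <- function() {
  df <- data.frame(
    subject_id = c("A", "A", "A", "B", "B", "B"),
    month = c(0, 6, 18, 0, 12, 24),
    age = c(71.2, 71.2, 71.2, 68.0, 68.0, 68.0),
    sex = c("F", "F", "F", "M", "M", "M"),
    apoe4 = c(1, 1, 1, 0, 0, 0),
    diagnosis = c("LMCI", "LMCI", "LMCI", "CN", "CN", "CN"),
    cohort = c("ADNI1", "ADNI1", "ADNI1", "ADNI2", "ADNI2", "ADNI2"),
    mmse = c(29, 28, 27, 30, NA, 29),
    adas13 = c(10, 12, NA, 5, 6, 7),
    stringsAsFactors = FALSE
  )
  ct <- matrix(round(runif(18, 2, 3), 3), 6, 3)
  ct[5, ] <- NA  # visit without a scan
  colnames(ct) <- paste0("ct_", 1:3)
  cbind(df, ct)
}

tinyCohort <- function() {
  df <- tinyCohortDF()
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  readCohortTable(path, atlas_size = 3)
}

# fast simulator preset: fewer ROIs, no missingness unless asked
quickSimConfig <- function(n, seed = 1L, roi_count = 10,
                          visit_missing_prob = 0, ct_missing_prob = 0,
                          class_spec = NULL, scale = "mmse", ...) {
  if (is.null(class_spec)) class_spec <- defaultClassSpecs(scale)
  simulationConfig(n, class_spec = class_spec, scale = scale,
                   roi_count = roi_count,
                   signature_rois = seq_len(min(4, roi_count)),
                   visit_missing_prob = visit_missing_prob,
                   ct_missing_prob = ct_missing_prob, seed = seed, ...)
}

# two-class specs with zero score noise (exact-recovery settings)
noiselessSpecs <- function() {
  list(
    trajectoryClassSpec("stable", 0.5, "linear", score_start = 29,
                        score_end = 28, score_noise_sd = 0),
    trajectoryClassSpec("decline", 0.5, "logistic", score_start = 28,
                        score_end = 12, midpoint = 36, steepness = 0.1,
                        score_noise_sd = 0)
  )
}

# minimal LSN (2 ROIs, 1 node per layer, 2-dim embedding) with hand-set
# weights so forward passes can be verified by pencil-and-paper arithmetic
handSetLSN <- function() {
  m <- buildLSN(lsnConfig(roi_count = 2, branch_width = 1, embedding_dim = 2,
                          head_width = 2, n_classes = 2, seed = 1))
  p <- m@params
  # branch: h1..h4 chained 1-node relu layers, then linear map to 2 dims
  p$Wb[[1]] <- matrix(c(1, -1), 2, 1);  p$bb[[1]] <- 0.5
  p$Wb[[2]] <- matrix(2, 1, 1);         p$bb[[2]] <- 0
  p$Wb[[3]] <- matrix(1, 1, 1);         p$bb[[3]] <- -0.25
  p$Wb[[4]] <- matrix(0.5, 1, 1);       p$bb[[4]] <- 0
  p$Wb[[5]] <- matrix(c(1, -2), 1, 2);  p$bb[[5]] <- c(0.1, 0.2)
  p$gate_w <- 0.3; p$gate_b <- -0.1
  p$Wh1 <- matrix(c(1, 0, 0.5, -1, 0, 1, 0, 0, 2, 0), 5, 2)
  p$bh1 <- c(0.05, -0.05)
  p$Wh2 <- matrix(c(1, -1, 0.5, 0.5), 2, 2)
  p$bh2 <- c(0, 0.1)
  # identity standardization so hand arithmetic applies directly
  p$stats <- list(ct_mean = c(0, 0), ct_sd = c(1, 1), score_mean = 0,
                  score_sd = 1, age_mean = 0, age_sd = 1)
  m@params <- p
  m
}

# ---- independent oracles ----------------------------------------------------

# greedy Ward agglomeration via the Lance-Williams recurrence on squared
# Euclidean distances; returns the partition at k clusters
wardOracle <- function(X, k) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  while (length(active) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      a <- active[i]; b <- active[j]
      if (D2[a, b] < bestd) { bestd <- D2[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (c_ in setdiff(active, c(a, b))) {
      D2[a, c_] <- D2[c_, a] <-
        ((sizes[a] + sizes[c_]) * D2[a, c_] +
         (sizes[b] + sizes[c_]) * D2[b, c_] -
         sizes[c_] * D2[a, b]) / (sizes[a] + sizes[b] + sizes[c_])
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  out <- integer(n)
  for (i in seq_along(active)) out[clusters[[active[i]]]] <- i
  out
}

samePartition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# all-pairs concordance AUC (ties count 1/2)
aucOracle <- function(truthPos, score) {
  pos <- score[truthPos]
  neg <- score[!truthPos]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (tie-free samples)
mwExactOracle <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  r <- rank(x)
  uStat <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- uStat(seq_len(n))
  combs <- combn(length(x), n)
  us <- apply(combs, 2, uStat)
  mu <- n * length(b) / 2
  min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# brute-force eligibility per subject
eligibleOracle <- function(cohort, scale, minVisits = 3, minSpan = 12) {
  vapply(subjectIds(cohort), function(id) {
    v <- getSubject(cohort, id)$visits
    m <- v$month[!is.na(v[[scale]])]
    length(m) >= minVisits && diff(range(m)) > minSpan
  }, logical(1))
}
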