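test_that("stratified nested folds partition the cohort with balanced strata", {
  set.seed(1)
  labels <- sample(c("stable", "decline"), 100, TRUE, prob = c(0.6, 0.4))
  folds <- nestedCvSplit(labels, k = 10, innerK = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)            # disjoint cover
  expect_equal(sum(vapply(tests, length, 1L)), 100)
  for (f in folds) {
    expect_setequal(c(f$test, f$train), 1:100)
    expect_equal(sort(unlist(f$inner)), sort(f$train)) # inner partition train
  }
  # per-fold class counts within 1 of proportional allocation
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    cnt <- vapply(tests, function(te) sum(labels[te] == cl), 1L)
    expect_true(all(abs(cnt - n_cl / 10) <= 1))
  }
})

test_that("joint cohort-by-class stratification matches brute-force cell counts", {
  set.seed(2)
  cohorts <- sample(c("A", "B"), 200, TRUE, prob = c(0.7, 0.3))
  labels <- sample(c("s", "d"), 200, TRUE, prob = c(0.6, 0.4))
  k <- 5
  folds <- nestedCvSplit(labels, cohorts, k = k, innerK = 3, seed = 9)
  for (co in c("A", "B")) for (cl in c("s", "d")) {
    cell <- which(cohorts == co & labels == cl)
    cnt <- vapply(folds, function(f) length(intersect(f$test, cell)), 1L)
    expect_true(all(abs(cnt - length(cell) / k) <= 1),
                info = paste(co, cl))
  }
  expect_error(nestedCvSplit(c("a", rep("b", 30)), k = 5, seed = 1),
               "smallest")
})

test_that("AUC equals the all-pairs concordance oracle on random instances", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    truth <- sample(c("neg", "pos"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("neg", "pos")
    sc_pos <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    scores <- cbind(neg = 1 - sc_pos, pos = sc_pos)
    met <- computeMetrics(truth, scores)
    expect_equal(met$auc, aucOracle(truth == "pos", sc_pos),
                 tolerance = 1e-12)
  }
})

test_that("accuracy and confusion matrix equal counting oracles", {
  set.seed(4)
  labs <- c("a", "b", "c")
  truth <- sample(labs, 150, TRUE)
  scores <- matrix(runif(450), 150, 3, dimnames = list(NULL, labs))
  met <- computeMetrics(truth, scores)
  pred <- labs[apply(scores, 1, which.max)]
  expect_equal(met$accuracy, mean(pred == truth))
  for (t_ in labs) for (p_ in labs)
    expect_equal(unname(met$confusion[t_, p_]),
                 sum(truth == t_ & pred == p_))
  expect_true(all(rowSums(met$confusion) == table(factor(truth, labs))))
  # macro OvR AUC equals the mean of the per-class oracles
  ovr <- sapply(labs, function(cl) aucOracle(truth == cl, scores[, cl]))
  expect_equal(met$auc, mean(ovr), tolerance = 1e-12)
})

test_that("perfect separation and null scores give the expected AUC", {
  truth <- rep(c("neg", "pos"), each = 20)
  scores <- cbind(neg = 1 - c(runif(20, 0, 0.4), runif(20, 0.6, 1)),
                  pos = c(runif(20, 0, 0.4), runif(20, 0.6, 1)))
  met <- computeMetrics(truth, scores)
  expect_equal(met$auc, 1)
  expect_equal(met$accuracy, 1)
  # the hand-countable 2x2 example: pos {0.9,0.4}, neg {0.6,0.1} -> 3/4
  m2 <- computeMetrics(c("pos", "pos", "neg", "neg"),
                       cbind(neg = 1 - c(0.9, 0.4, 0.6, 0.1),
                             pos = c(0.9, 0.4, 0.6, 0.1)))
  expect_equal(m2$auc, 3 / 4)
  # random scores at n=2000 sit in the null band
  set.seed(6)
  truth <- sample(c("neg", "pos"), 2000, TRUE)
  sc <- runif(2000)
  expect_lt(abs(computeMetrics(truth, cbind(neg = 1 - sc, pos = sc))$auc -
                  0.5), 0.04)
  # single-class truth: AUC missing, not zero
  m1 <- computeMetrics(rep("pos", 5), cbind(neg = runif(5), pos = runif(5)))
  expect_true(is.na(m1$auc))
})

test_that("ROC points trace the empirical curve", {
  truth <- c("pos", "pos", "neg", "neg")
  met <- computeMetrics(truth, cbind(neg = 1 - c(0.9, 0.4, 0.6, 0.1),
                                     pos = c(0.9, 0.4, 0.6, 0.1)))
  expect_true(all(diff(met$roc$fpr) >= 0))
  expect_equal(range(met$roc$fpr), c(0, 1))
  expect_equal(range(met$roc$tpr), c(0, 1))
})

test_that("clinical-workflow groups partition an exhaustive score grid", {
  th <- workflowThresholds("mmse")  # low 24, high 29, change 2
  grid <- expand.grid(s0 = 0:30, s1 = 0:30)
  grp <- stratifyClinicalWorkflow(grid$s0, grid$s1, th)
  # independent rule-table oracle
  oracle <- apply(grid, 1, function(r) {
    if (r["s0"] < 24 || r["s0"] > 29) "BE"
    else if (abs(r["s1"] - r["s0"]) >= 2) "FE"
    else "CC"
  })
  expect_identical(as.character(grp), oracle)
  expect_false(anyNA(grp))  # partition: every pair in exactly one group
  # rule order: extreme baseline wins regardless of follow-up
  expect_identical(as.character(stratifyClinicalWorkflow(30, 30, th)), "BE")
  expect_identical(as.character(stratifyClinicalWorkflow(26, 26, th)), "CC")
  expect_error(workflowThresholds("mmse", high_baseline = 40), "range")
  expect_error(workflowThresholds("mmse", change = 0), "> 0")
})

test_that("timepoint-span stratification separates near and distant futures", {
  last <- c(a = 24, b = 72, c = 36, d = 48, e = 42)
  grp <- stratifyBySpan(last)
  expect_identical(as.character(grp[c("a", "c")]),
                   rep("near_future", 2))
  expect_identical(as.character(grp[c("b", "d")]),
                   rep("distant_future", 2))
  expect_identical(as.character(grp[["e"]]), "gap")
  # counting oracle on a simulated cohort's assignments
  sim <- simulateCohort(quickSimConfig(60, seed = 17,
                                       visit_missing_prob = 0.35))
  grid <- c(0, 6, 12, 18, 24, 36, 48, 60, 72)
  tpl <- new("TrajectoryTemplate", scale = "mmse", months = grid,
             classLabels = c("stable", "decline"),
             means = rbind(stable = rep(28.5, 9),
                           decline = seq(28, 12, length.out = 9)),
             nPerClass = c(30L, 30L), provenance = list())
  asg <- labelCohort(sim$cohort, tpl)$assignments
  grp2 <- stratifyBySpan(asg)
  expect_equal(sum(grp2 == "near_future"), sum(asg$last_month <= 36))
  expect_equal(sum(grp2 == "distant_future"), sum(asg$last_month >= 48))
})

test_that("model comparison matches the exact permutation null at n=5+5", {
  a <- c(1, 2, 3, 4, 5); b <- c(11, 12, 13, 14, 15)
  res <- compareModels(a, b)
  expect_identical(res$method, "exact")
  expect_equal(res$p.value, mwExactOracle(a, b), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5, sample(c(0, 1), 1))
    expect_equal(compareModels(x, y)$p.value, mwExactOracle(x, y),
                 tolerance = 1e-10)
  }
  # identical samples give the maximal attainable p
  expect_gte(compareModels(c(1, 2, 3, 4), c(1, 2, 3, 4))$p.value, 0.99)
  expect_error(compareModels(1:2, 1:5), "3 folds")
})

test_that("rank-sum rejection rate under a shift matches the reference test", {
  set.seed(9)
  n_sim <- 300
  rej_pkg <- rej_ref <- logical(n_sim)
  for (i in 1:n_sim) {
    a <- rnorm(8); b <- rnorm(8, 1.2)
    rej_pkg[i] <- compareModels(a, b)$p.value < 0.05
    rej_ref[i] <- stats::wilcox.test(a, b, exact = TRUE)$p.value < 0.05
  }
  expect_equal(mean(rej_pkg), mean(rej_ref), tolerance = 1e-12)
})

test_that("follow-up selection takes the latest complete visit in the window", {
  mk <- function(months, score_ok, ct_ok) {
    ct <- matrix(2.5, length(months), 4)
    ct[!ct_ok, ] <- NA
    list(info = data.frame(subject_id = "X", age = 70, apoe4 = 1,
                           cohort = "SIM"),
         visits = data.frame(subject_id = "X", month = months,
                             mmse = ifelse(score_ok, 28, NA), adas13 = NA),
         ct = ct)
  }
  # all complete: pick month 12
  s <- mk(c(0, 6, 12), c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
  expect_equal(selectFollowup(s, "mmse")$month, 12)
  # month-12 scan missing, month-6 complete: fall back to 6
  s <- mk(c(0, 6, 12), c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))
  expect_equal(selectFollowup(s, "mmse")$month, 6)
  # only baseline: none
  s <- mk(0, TRUE, TRUE)
  expect_null(selectFollowup(s, "mmse"))
  # visits beyond the window do not qualify
  s <- mk(c(0, 18), c(TRUE, TRUE), c(TRUE, TRUE))
  expect_null(selectFollowup(s, "mmse"))
})

test_that("prediction-input bundles keep complete subjects and explain exclusions", {
  sim <- simulateCohort(quickSimConfig(50, seed = 23,
                                       visit_missing_prob = 0.3,
                                       ct_missing_prob = 0.25))
  bundle <- predictionInputs(sim$cohort, "mmse")
  expect_equal(length(bundle$subject_id) + nrow(bundle$excluded), 50L)
  expect_false(anyNA(bundle$ct0)); expect_false(anyNA(bundle$ct1))
  expect_true(all(bundle$followup_month > 0 & bundle$followup_month <= 12))
  expect_true(all(bundle$excluded$reason %in%
                    c("no baseline score", "no baseline CT",
                      "no qualifying follow-up within window")))
})

test_that("a small factorial experiment satisfies the report invariants", {
  sim <- simulateCohort(quickSimConfig(60, seed = 29))
  bundle <- predictionInputs(sim$cohort, "mmse")
  y <- sim$labels[bundle$subject_id]
  rep1 <- runExperiment(bundle, y, "mmse", models = c("LR", "LSN"),
                        specs = list(featureSpec("CA", "baseline", "mmse")),
                        k = 3, innerK = 2, seed = 13,
                        lsn = lsnConfig(roi_count = 10, branch_width = 6,
                                        embedding_dim = 3, head_width = 3,
                                        max_epochs = 30),
                        grids = list(LR = list(lambda = 0.01)))
  expect_setequal(names(rep1$cells),
                  c("LR|CA|baseline", "LSN|CA_CT|baseline_followup"))
  n <- length(bundle$subject_id)
  for (cell in rep1$cells) {
    expect_equal(sum(cell$per_fold$n), n)       # folds partition the cohort
    expect_equal(sum(cell$pooled$confusion), n)
    expect_true(all(rowSums(cell$pooled$confusion) ==
                      table(factor(y, levels = rep1$classLabels))))
  }
  # group-restricted metrics equal recomputation from stored predictions
  pr <- rep1$predictions
  lr <- pr[pr$model == "LR", ]
  for (g in c("BE", "FE", "CC")) {
    gi <- lr$group == g
    if (sum(gi) < 2) next
    met <- computeMetrics(lr$truth[gi],
                          as.matrix(lr[gi, rep1$classLabels]))
    expect_equal(rep1$cells[["LR|CA|baseline"]]$groups[[g]]$accuracy,
                 met$accuracy)
    expect_equal(rep1$cells[["LR|CA|baseline"]]$groups[[g]]$auc, met$auc)
  }
  # determinism: identical report under the same seed
  rep2 <- runExperiment(bundle, y, "mmse", models = c("LR", "LSN"),
                        specs = list(featureSpec("CA", "baseline", "mmse")),
                        k = 3, innerK = 2, seed = 13,
                        lsn = lsnConfig(roi_count = 10, branch_width = 6,
                                        embedding_dim = 3, head_width = 3,
                                        max_epochs = 30),
                        grids = list(LR = list(lambda = 0.01)))
  expect_identical(rep1$predictions, rep2$predictions)
})

test_that("out-of-fold evaluation never sees test subjects in training (leakage canary)", {
  # plant canaries: duplicate feature rows with flipped labels; if any
  # training stage saw its test twin, the twin's prediction would follow the
  # flipped training label rather than the feature signal
  set.seed(31)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + 8
  folds <- nestedCvSplit(y, k = 3, seed = 5)
  for (f in folds) {
    expect_length(intersect(f$test, f$train), 0L)
    # poisoned training set: test rows with flipped labels appended
    X_poison <- rbind(X[f$train, ], X[f$test, ])
    y_poison <- c(y[f$train], ifelse(y[f$test] == "a", "b", "a"))
    fit_clean <- fitReference("LR", X[f$train, ], y[f$train],
                              grid = list(lambda = 0.01), seed = 1)
    sc <- predictReference(fit_clean, X[f$test, , drop = FALSE])
    pred <- colnames(sc)[max.col(sc, ties.method = "first")]
    expect_equal(mean(pred == y[f$test]), 1)  # clean model follows signal
  }
})

test_that("replication mode averages fold-model metrics on an independent cohort", {
  simA <- simulateCohort(quickSimConfig(60, seed = 37))
  simB <- simulateCohort(quickSimConfig(40, seed = 38))
  bunA <- predictionInputs(simA$cohort, "mmse")
  bunB <- predictionInputs(simB$cohort, "mmse")
  repA <- runExperiment(bunA, simA$labels[bunA$subject_id], "mmse",
                        models = "LR",
                        specs = list(featureSpec("CA", "baseline", "mmse")),
                        k = 3, seed = 7, grids = list(LR = list(lambda = 0.01)),
                        keepModels = TRUE)
  out <- replicationTest(repA, "LR|CA|baseline", bunB,
                         simB$labels[bunB$subject_id])
  expect_equal(nrow(out), 3L)
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
  expect_equal(attr(out, "means")[["accuracy"]], mean(out$accuracy))
})

test_that("reports serialize to JSON + CSV", {
  sim <- simulateCohort(quickSimConfig(50, seed = 43))
  bundle <- predictionInputs(sim$cohort, "mmse")
  y <- sim$labels[bundle$subject_id]
  rp <- runExperiment(bundle, y, "mmse", models = "RF",
                      specs = list(featureSpec("CA", "baseline", "mmse")),
                      k = 3, seed = 3,
                      grids = list(RF = data.frame(ntree = 50L,
                                                   maxnodes = NA)))
  p <- tempfile(fileext = ".json")
  writeReport(rp, p)
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(obj$cells[["RF|CA|baseline"]]$pooled$accuracy,
               rp$cells[["RF|CA|baseline"]]$pooled$accuracy)
  flat <- read.csv(sub("\\.json$", ".csv", p))
  expect_equal(nrow(flat), 1L)
})
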