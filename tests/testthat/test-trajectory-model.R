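test_that("well-separated flat and declining vectors split perfectly at k=2", {
  flat <- matrix(29, 3, 9) + matrix(rnorm(27, 0, 0.1), 3)
  dec <- t(sapply(1:3, function(i) seq(29, 10, length.out = 9) + rnorm(9, 0, 0.1)))
  set.seed(1)
  X <- rbind(flat, dec)
  cl <- clusterTrajectories(X, 2)
  expect_true(samePartition(cl, rep(1:2, each = 3)))
})

test_that("clustering agrees with the greedy Ward merge oracle on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 4), 8, 4)
    for (k in 2:3) {
      expect_true(samePartition(clusterTrajectories(X, k), wardOracle(X, k)),
                  info = paste("seed", seed, "k", k))
    }
  }
})

test_that("clustering rejects incomplete input and degenerate k", {
  X <- matrix(rnorm(20), 5, 4)
  X[2, 3] <- NA
  expect_error(clusterTrajectories(X, 2), "complete")
  expect_error(clusterTrajectories(matrix(rnorm(20), 5, 4), 5), "smaller")
  expect_error(clusterTrajectories(matrix(rnorm(20), 5, 4), 1), ">= 2")
})

test_that("templates are per-cell means in canonical severity order", {
  # hand mean of one cluster
  X <- rbind(c(30, 28, 26), c(28, 26, 24), c(20, 15, 10), c(22, 13, 8))
  tpl <- buildTemplates(X, c(1, 1, 2, 2), months = c(0, 12, 24), scale = "mmse")
  expect_identical(tpl@classLabels, c("stable", "decline"))
  expect_equal(unname(tpl@means["stable", ]), c(29, 27, 25))
  expect_equal(unname(tpl@means["decline", ]), c(21, 14, 9))
  expect_equal(tpl@nPerClass, c(2L, 2L))

  # single cluster of identical rows reproduces the row
  one <- matrix(rep(c(25, 24, 23), 3), 3, byrow = TRUE)
  tpl1 <- buildTemplates(rbind(one, c(10, 9, 8)), c(1, 1, 1, 2),
                         months = c(0, 12, 24), scale = "mmse")
  expect_equal(unname(tpl1@means["stable", ]), c(25, 24, 23))

  # elementwise oracle on a random labeled matrix
  set.seed(3)
  R <- matrix(runif(20 * 9, 0, 30), 20, 9)
  lab <- sample(1:3, 20, replace = TRUE)
  tpl3 <- buildTemplates(R, lab, months = seq(0, 72, 9), scale = "mmse")
  for (l in unique(lab)) {
    manual <- colMeans(R[lab == l, , drop = FALSE])
    hit <- apply(tpl3@means, 1, function(r) isTRUE(all.equal(unname(r), manual)))
    expect_true(any(hit))
  }

  # ADAS-13 severity direction flips the canonical order
  tplA <- buildTemplates(rbind(c(10, 12, 14), c(20, 35, 50)), c(1, 2),
                         months = c(0, 12, 24), scale = "adas13",
                         classLabels = c("stable", "decline"))
  expect_equal(unname(tplA@means["stable", ]), c(10, 12, 14))

  expect_error(buildTemplates(X, c(1, 1, 1, 1), c(0, 12, 24), "mmse",
                              classLabels = c("a", "b")), "length")
})

test_that("assignment reproduces the hand-worked Euclidean distances", {
  tpl <- new("TrajectoryTemplate", scale = "mmse", months = c(0, 12, 24),
             classLabels = c("stable", "decline"),
             means = rbind(stable = c(29, 29, 29), decline = c(27, 22, 15)),
             nPerClass = c(5L, 5L), provenance = list())
  subj <- list(info = data.frame(subject_id = "W"),
               visits = data.frame(month = c(0, 12, 24),
                                   mmse = c(28, 25, 20), adas13 = NA))
  a <- assignTrajectory(subj, tpl)
  # brute force: stable (1,4,9) -> sqrt(98); decline (1,3,5) -> sqrt(35)
  expect_equal(unname(a$distances["stable"]), sqrt(1 + 16 + 81),
               tolerance = 1e-12)
  expect_equal(unname(a$distances["decline"]), sqrt(1 + 9 + 25),
               tolerance = 1e-12)
  expect_identical(a$label, "decline")

  # exact template match -> distance zero
  subj0 <- list(info = data.frame(subject_id = "V"),
                visits = data.frame(month = c(0, 12, 24),
                                    mmse = c(29, 29, 29), adas13 = NA))
  a0 <- assignTrajectory(subj0, tpl)
  expect_identical(a0$label, "stable")
  expect_equal(unname(a0$distances["stable"]), 0)

  # equidistant subject goes to the less severe class
  tplT <- new("TrajectoryTemplate", scale = "mmse", months = c(0, 12, 24),
              classLabels = c("stable", "decline"),
              means = rbind(stable = c(28, 28, 28), decline = c(24, 24, 24)),
              nPerClass = c(5L, 5L), provenance = list())
  mid <- list(info = data.frame(subject_id = "T"),
              visits = data.frame(month = c(0, 12, 24),
                                  mmse = c(26, 26, 26), adas13 = NA))
  expect_identical(assignTrajectory(mid, tplT)$label, "stable")
})

test_that("assignment enforces eligibility and snaps off-grid months", {
  tpl <- new("TrajectoryTemplate", scale = "mmse", months = c(0, 6, 12, 24, 36),
             classLabels = c("stable", "decline"),
             means = rbind(stable = rep(29, 5), decline = c(27, 25, 22, 15, 10)),
             nPerClass = c(5L, 5L), provenance = list())
  few <- list(info = data.frame(subject_id = "F"),
              visits = data.frame(month = c(0, 24), mmse = c(29, 29),
                                  adas13 = NA))
  expect_error(assignTrajectory(few, tpl), "insufficient")
  narrow <- list(info = data.frame(subject_id = "N"),
                 visits = data.frame(month = c(0, 6, 12),
                                     mmse = c(29, 29, 29), adas13 = NA))
  expect_error(assignTrajectory(narrow, tpl), "timespan")
  # months 2 and 25 snap to grid 0 and 24; month 30 (|30-36|=6 > 3) ignored
  off <- list(info = data.frame(subject_id = "O"),
              visits = data.frame(month = c(2, 13, 25, 30),
                                  mmse = c(29, 29, 29, 29), adas13 = NA))
  a <- assignTrajectory(off, tpl)
  expect_equal(a$months_used, c(0, 12, 24))
  expect_identical(a$label, "stable")
})

test_that("assignment is invariant to month order and class order", {
  tpl <- new("TrajectoryTemplate", scale = "mmse", months = c(0, 12, 24),
             classLabels = c("stable", "decline"),
             means = rbind(stable = c(29, 28, 28), decline = c(27, 20, 14)),
             nPerClass = c(4L, 6L), provenance = list())
  subj <- list(info = data.frame(subject_id = "P"),
               visits = data.frame(month = c(24, 0, 12),
                                   mmse = c(18, 27, 22), adas13 = NA))
  subj_sorted <- subj
  subj_sorted$visits <- subj$visits[order(subj$visits$month), ]
  a1 <- assignTrajectory(subj, tpl)
  a2 <- assignTrajectory(subj_sorted, tpl)
  expect_identical(a1$label, a2$label)
  expect_equal(a1$distances, a2$distances)
})

test_that("zero-noise cohorts are relabeled perfectly, even with thinned visits", {
  cfg <- quickSimConfig(60, seed = 21, class_spec = noiselessSpecs())
  sim <- simulateCohort(cfg)
  sm <- completeScoreMatrix(sim$cohort, "mmse", cfg$visit_grid)
  tpl <- buildTemplates(sm, clusterTrajectories(sm, 2), cfg$visit_grid, "mmse")
  res <- labelCohort(sim$cohort, tpl)
  expect_equal(nrow(res$ineligible), 0L)
  expect_true(all(res$assignments$label ==
                    sim$labels[res$assignments$subject_id]))

  # thin every subject to 3-5 random visits (keeping span > 12) and re-assign
  set.seed(99)
  vis <- visitTable(sim$cohort)
  keep_rows <- unlist(lapply(split(seq_len(nrow(vis)), vis$subject_id),
    function(rows) {
      n <- sample(3:5, 1)
      sort(c(rows[1], sample(rows[-1], n - 1)))
    }))
  thin <- makeCohort(subjectTable(sim$cohort), vis[keep_rows, ],
                     ctMatrix(sim$cohort)[keep_rows, ],
                     roiNames(sim$cohort), scaleRanges(sim$cohort))
  thin <- filterEligible(thin, "mmse")
  res2 <- labelCohort(thin, tpl)
  expect_true(all(res2$assignments$label ==
                    sim$labels[res2$assignments$subject_id]))
})

test_that("label_cohort matches a nearest-centroid oracle under noise and lists ineligibles", {
  cfg <- quickSimConfig(100, seed = 31, visit_missing_prob = 0.25)
  sim <- simulateCohort(cfg)
  sm <- completeScoreMatrix(sim$cohort, "mmse", cfg$visit_grid)
  tpl <- buildTemplates(sm, clusterTrajectories(sm, 2), cfg$visit_grid, "mmse")
  res <- labelCohort(sim$cohort, tpl)
  # oracle: per subject, nearest template row over its available grid months
  for (i in sample(nrow(res$assignments), 20)) {
    id <- res$assignments$subject_id[i]
    v <- getSubject(sim$cohort, id)$visits
    v <- v[!is.na(v$mmse) & v$month %in% tpl@months, ]
    d <- apply(tpl@means[, match(v$month, tpl@months), drop = FALSE], 1,
               function(mu) sqrt(sum((v$mmse - mu)^2)))
    expect_identical(res$assignments$label[i], names(which.min(d)))
  }
  # a 2-visit subject lands in the ineligible list
  short <- makeCohort(
    data.frame(subject_id = "SS", age = 70, sex = "F", apoe4 = 0,
               diagnosis = "CN", cohort = "SIM"),
    data.frame(subject_id = "SS", month = c(0, 24), mmse = c(29, 28),
               adas13 = NA))
  res_s <- labelCohort(short, tpl)
  expect_equal(nrow(res_s$assignments), 0L)
  expect_match(res_s$ineligible$reason, "insufficient")
})

test_that("planted classes are recovered with high adjusted Rand index at wide separation", {
  skip_if_not_installed("mclust")
  specs <- lapply(noiselessSpecs(), function(s) { s$score_noise_sd <- 1; s })
  cfg <- quickSimConfig(80, seed = 41, class_spec = specs)
  sim <- simulateCohort(cfg)
  sm <- completeScoreMatrix(sim$cohort, "mmse", cfg$visit_grid)
  cl <- clusterTrajectories(sm, 2)
  ari <- mclust::adjustedRandIndex(cl, sim$labels[rownames(sm)])
  expect_gte(ari, 0.9)
})

test_that("templates survive a JSON round trip", {
  sm <- matrix(runif(45, 10, 30), 5, 9)
  tpl <- buildTemplates(sm, c(1, 1, 2, 2, 2), seq(0, 72, 9), "mmse",
                        provenance = list(k = 2, seed = 7))
  p <- tempfile(fileext = ".json")
  writeTemplate(tpl, p)
  back <- readTemplate(p)
  expect_equal(back@means, tpl@means, tolerance = 1e-12)
  expect_identical(back@classLabels, tpl@classLabels)
  expect_equal(back@months, tpl@months)
  expect_equal(back@nPerClass, tpl@nPerClass)
})
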