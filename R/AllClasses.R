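#' @import methods
NULL

#' Longitudinal cohort container
#'
#' A `Cohort` holds a longitudinal clinical cohort in long format: one row of
#' `visits` per subject-visit (month from baseline, MMSE, ADAS-13), a parallel
#' matrix of mean cortical thickness per atlas region (one row per visit, all
#' `NA` when no usable scan exists for that visit), and one row of `subjects`
#' per subject carrying time-invariant attributes (age at baseline, sex, APOE4
#' allele count, baseline diagnosis, source cohort tag).
#'
#' Invariants enforced by the validity method: unique subject identifiers;
#' non-empty, strictly increasing visit months per subject starting at month
#' 0; APOE4 in {0,1,2}; scores within the declared scale ranges; cortical
#' thickness rows either fully present (all regions, strictly positive) or
#' fully missing.
#'
#' @slot subjects data.frame with columns `subject_id`, `age`, `sex`,
#'   `apoe4`, `diagnosis`, `cohort`; one row per subject.
#' @slot visits data.frame with columns `subject_id`, `month`, `mmse`,
#'   `adas13`; rows grouped by subject and sorted by month.
#' @slot ct numeric matrix, `nrow(visits)` rows by `length(roiNames)`
#'   columns; row i is the thickness vector of visit i or all `NA`.
#' @slot roiNames character vector of atlas region identifiers; its order
#'   defines the column order of `ct`.
#' @slot scaleRanges named list mapping scale name to `c(min, max)`.
#'
#' @seealso [readCohortTable()], [writeCohortTable()], [filterEligible()],
#'   [simulateCohort()]
#' @export
setClass("Cohort",
  representation(
    subjects    = "data.frame",
    visits      = "data.frame",
    ct          = "matrix",
    roiNames    = "character",
    scaleRanges = "list"
  )
)

.validCohort <- function(object) {
  msgs <- character()
  sub <- object@subjects
  vis <- object@visits
  need_sub <- c("subject_id", "age", "sex", "apoe4", "diagnosis", "cohort")
  need_vis <- c("subject_id", "month", "mmse", "adas13")
  if (!all(need_sub %in% names(sub))) {
    return(paste("subjects table lacks columns:",
                 paste(setdiff(need_sub, names(sub)), collapse = ", ")))
  }
  if (!all(need_vis %in% names(vis))) {
    return(paste("visits table lacks columns:",
                 paste(setdiff(need_vis, names(vis)), collapse = ", ")))
  }
  if (anyDuplicated(sub$subject_id))
    msgs <- c(msgs, "duplicated subject_id in subjects table")
  if (nrow(vis) != nrow(object@ct))
    msgs <- c(msgs, "ct matrix must have one row per visit")
  if (ncol(object@ct) != length(object@roiNames))
    msgs <- c(msgs, "ct matrix width must equal length(roiNames)")
  if (!all(vis$subject_id %in% sub$subject_id))
    msgs <- c(msgs, "visits reference unknown subject_id")
  bad_apoe <- !(sub$apoe4 %in% 0:2)
  if (any(bad_apoe))
    msgs <- c(msgs, paste0("apoe4 outside {0,1,2} for subject(s): ",
                           paste(sub$subject_id[bad_apoe], collapse = ", ")))
  if (nrow(vis) > 0L) {
    by_sub <- split(seq_len(nrow(vis)), vis$subject_id)
    for (id in names(by_sub)) {
      m <- vis$month[by_sub[[id]]]
      if (length(m) == 0L)
        msgs <- c(msgs, paste0("subject ", id, " has no visits"))
      if (any(m < 0) || is.unsorted(m, strictly = TRUE))
        msgs <- c(msgs, paste0("visit months for subject ", id,
                               " must be >= 0 and strictly increasing"))
      if (m[1L] != 0)
        msgs <- c(msgs, paste0("subject ", id, " lacks a baseline (month 0) visit"))
    }
    missing_sub <- setdiff(sub$subject_id, vis$subject_id)
    if (length(missing_sub))
      msgs <- c(msgs, paste0("subject(s) without visits: ",
                             paste(missing_sub, collapse = ", ")))
    for (sc in intersect(names(object@scaleRanges), names(vis))) {
      rng <- object@scaleRanges[[sc]]
      v <- vis[[sc]]
      bad <- !is.na(v) & (v < rng[1L] | v > rng[2L])
      if (any(bad))
        msgs <- c(msgs, paste0(sc, " out of range [", rng[1L], ",", rng[2L],
                               "] in visit row(s): ",
                               paste(which(bad), collapse = ", ")))
    }
    na_ct <- is.na(object@ct)
    partial <- rowSums(na_ct) %% ncol(object@ct) != 0L & rowSums(na_ct) > 0L
    if (ncol(object@ct) > 0L) {
      n_na <- rowSums(na_ct)
      partial <- n_na > 0L & n_na < ncol(object@ct)
      if (any(partial))
        msgs <- c(msgs, paste0("partially missing ct vector in visit row(s): ",
                               paste(which(partial), collapse = ", ")))
      nonpos <- !is.na(object@ct) & object@ct <= 0
      if (any(nonpos))
        msgs <- c(msgs, "ct values must be strictly positive")
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("Cohort", .validCohort)

#' Trajectory template
#'
#' Per-class mean clinical score at each month of a fixed visit grid, built by
#' averaging the scores of the subjects in each trajectory cluster. Classes
#' are stored in canonical order: least severe (most stable) first, graded by
#' severity of the mean score at the final grid month.
#'
#' @slot scale scale name, `"mmse"` or `"adas13"`.
#' @slot months numeric visit grid (months from baseline).
#' @slot classLabels character class labels in canonical order.
#' @slot means numeric matrix, classes x months, of mean scores.
#' @slot nPerClass integer count of training subjects per class.
#' @slot provenance list of clustering parameters (k, linkage, seed, n).
#'
#' @seealso [buildTemplates()], [assignTrajectory()], [labelCohort()]
#' @export
setClass("TrajectoryTemplate",
  representation(
    scale       = "character",
    months      = "numeric",
    classLabels = "character",
    means       = "matrix",
    nPerClass   = "integer",
    provenance  = "list"
  )
)

setValidity("TrajectoryTemplate", function(object) {
  msgs <- character()
  if (length(object@scale) != 1L)
    msgs <- c(msgs, "scale must be a single string")
  if (nrow(object@means) != length(object@classLabels))
    msgs <- c(msgs, "means must have one row per class")
  if (ncol(object@means) != length(object@months))
    msgs <- c(msgs, "means must have one column per month")
  if (length(object@nPerClass) != length(object@classLabels))
    msgs <- c(msgs, "nPerClass must align with classLabels")
  if (anyDuplicated(object@classLabels))
    msgs <- c(msgs, "class labels must be unique")
  if (is.unsorted(object@months, strictly = TRUE))
    msgs <- c(msgs, "months must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Longitudinal Siamese Network model
#'
#' A trained (or freshly initialized) Longitudinal Siamese Network. The
#' parameter list holds a single shared branch (used for both timepoints), the
#' one-node multiplicative APOE4 gate, the prediction head, and the
#' standardization statistics fitted on training data, so the object is
#' self-contained at prediction time.
#'
#' @slot config list of architecture and training settings, see [lsnConfig()].
#' @slot params list of weight matrices/vectors (`branch`, `gate`, `head`)
#'   plus `stats` (feature means/sds).
#' @slot classLabels character class labels in output order.
#' @slot history data.frame of per-epoch training/validation loss (empty for
#'   an untrained model).
#'
#' @seealso [buildLSN()], [trainLSN()], [predictLSN()]
#' @export
setClass("LSNModel",
  representation(
    config      = "list",
    params      = "list",
    classLabels = "character",
    history     = "data.frame"
  )
)

setMethod("show", "Cohort", function(object) {
  cat("Cohort with", nrow(object@subjects), "subjects,",
      nrow(object@visits), "visits,",
      length(object@roiNames), "ROIs\n")
  n_ct <- sum(stats::complete.cases(object@ct))
  cat("  visits with CT:", n_ct, "\n")
  for (sc in names(object@scaleRanges)) {
    cat("  ", sc, ": ", sum(!is.na(object@visits[[sc]])), " scored visits\n",
        sep = "")
  }
  cat("  source cohorts:",
      paste(unique(object@subjects$cohort), collapse = ", "), "\n")
})

setMethod("show", "TrajectoryTemplate", function(object) {
  cat("TrajectoryTemplate (", object@scale, "), ",
      length(object@classLabels), " classes x ",
      length(object@months), " months\n", sep = "")
  m <- round(object@means, 2)
  dimnames(m) <- list(object@classLabels, object@months)
  print(m)
  cat("n per class:", paste(object@nPerClass, collapse = ", "), "\n")
})

setMethod("show", "LSNModel", function(object) {
  cfg <- object@config
  cat("LSNModel: ", cfg$roi_count, " ROIs -> 4 x ", cfg$branch_width,
      " shared branch -> ", cfg$embedding_dim,
      " distance embedding -> APOE4 gate -> head ", cfg$head_width,
      " -> ", cfg$n_classes, " classes\n", sep = "")
  cat("  classes:", paste(object@classLabels, collapse = ", "), "\n")
  if (nrow(object@history)) {
    cat("  trained ", nrow(object@history), " epochs; best val loss ",
        signif(min(object@history$val_loss), 4), "\n", sep = "")
  } else cat("  untrained (initialized parameters)\n")
})
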