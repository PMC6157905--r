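#' Cluster longitudinal score vectors into trajectory classes
#'
#' Agglomerative hierarchical clustering of complete-case longitudinal score
#' vectors using Euclidean distance as the similarity metric and Ward's
#' linkage criterion, with the tree cut at `k` clusters. The number of
#' clusters is a design choice: 2 for MMSE and 3 for ADAS-13 are the
#' framework defaults, matching the dynamic range of each scale.
#'
#' @param scoreMatrix numeric matrix, subjects x months, no missing entries.
#' @param k number of clusters (>= 2, < number of subjects).
#' @return integer vector of cluster indices (1..k), one per subject. Cluster
#'   numbering is the `stats::cutree()` convention (order of first
#'   appearance); use [buildTemplates()] for canonical severity ordering.
#' @export
clusterTrajectories <- function(scoreMatrix, k) {
  scoreMatrix <- as.matrix(scoreMatrix)
  if (anyNA(scoreMatrix))
    stop("score matrix contains missing entries; clustering requires ",
         "complete cases - subset to subjects with all timepoints first")
  if (k < 2) stop("k must be >= 2")
  if (k >= nrow(scoreMatrix)) stop("k must be smaller than the number of subjects")
  hc <- stats::hclust(stats::dist(scoreMatrix, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = k)
}

.defaultClassLabels <- function(k) {
  if (k == 2) c("stable", "decline")
  else if (k == 3) c("stable", "slow_decline", "fast_decline")
  else paste0("class_", seq_len(k))
}

#' Build per-class trajectory templates
#'
#' Averages the clinical scores of the subjects in each cluster at each
#' individual timepoint to obtain one mean-trajectory template per class.
#' Classes are reordered canonically by severity of the final-month mean
#' (least severe first: highest final MMSE, or lowest final ADAS-13), so
#' that class labels are reproducible across runs.
#'
#' @param scoreMatrix numeric matrix, subjects x months (complete cases).
#' @param clusterLabels integer or character cluster membership per row.
#' @param months numeric visit grid, one entry per column.
#' @param scale `"mmse"` or `"adas13"` (controls severity direction).
#' @param classLabels optional labels for the reordered classes; defaults to
#'   stable/decline (k=2), stable/slow_decline/fast_decline (k=3).
#' @param provenance optional list recorded in the template.
#' @return a [TrajectoryTemplate].
#' @export
buildTemplates <- function(scoreMatrix, clusterLabels, months, scale,
                           classLabels = NULL, provenance = list()) {
  .checkScale(scale)
  scoreMatrix <- as.matrix(scoreMatrix)
  stopifnot(length(clusterLabels) == nrow(scoreMatrix),
            length(months) == ncol(scoreMatrix))
  lev <- unique(clusterLabels)
  if (any(table(factor(clusterLabels, levels = lev)) == 0))
    stop("empty cluster")
  means <- t(vapply(lev, function(l) {
    colMeans(scoreMatrix[clusterLabels == l, , drop = FALSE])
  }, numeric(ncol(scoreMatrix))))
  nper <- as.integer(table(factor(clusterLabels, levels = lev)))
  # canonical order: least severe final-month mean first
  sev <- .severitySign(scale) * means[, ncol(means)]
  ord <- order(sev)
  means <- means[ord, , drop = FALSE]
  nper <- nper[ord]
  k <- length(lev)
  if (is.null(classLabels)) classLabels <- .defaultClassLabels(k)
  stopifnot(length(classLabels) == k)
  dimnames(means) <- list(classLabels, NULL)
  new("TrajectoryTemplate", scale = scale, months = as.numeric(months),
      classLabels = classLabels, means = means, nPerClass = nper,
      provenance = provenance)
}

#' Assign a trajectory class to one subject
#'
#' Computes the Euclidean distance between the subject's available scores on
#' the template scale and each class template restricted to the same months,
#' and assigns the class of minimum distance. Visit months off the template
#' grid are snapped to the nearest grid month within `snapMonths`; visits
#' farther from any grid month are ignored. Ties are broken toward the less
#' severe class (first in canonical template order). Requires at least
#' `minVisits` usable scored visits spanning more than `minSpanMonths`.
#'
#' @param subject a subject record from [getSubject()], or any list with a
#'   `visits` data.frame (columns `month` and the template scale) and an
#'   `info` data.frame with `subject_id`.
#' @param template a [TrajectoryTemplate].
#' @param snapMonths half-width of the grid-snapping window (months).
#' @param minVisits minimum usable scored visits (default 3).
#' @param minSpanMonths minimum span of usable visits, exclusive (default 12).
#' @return list with `subject_id`, `label`, `distances` (named per class),
#'   `months_used` (template grid months used) and `span_months`.
#' @export
assignTrajectory <- function(subject, template, snapMonths = 3,
                             minVisits = 3, minSpanMonths = 12) {
  vis <- subject$visits
  sc <- template@scale
  ok <- !is.na(vis[[sc]])
  m <- vis$month[ok]
  y <- vis[[sc]][ok]
  # snap each visit to nearest template grid month within the window
  grid <- template@months
  gi <- vapply(m, function(mm) {
    d <- abs(grid - mm)
    j <- which.min(d)
    if (d[j] <= snapMonths) j else NA_integer_
  }, integer(1))
  keep <- !is.na(gi)
  m <- m[keep]; y <- y[keep]; gi <- gi[keep]
  # one visit per grid month: keep the closest (earlier visit wins ties)
  if (anyDuplicated(gi)) {
    sel <- !logical(length(gi))
    for (g in unique(gi[duplicated(gi)])) {
      idx <- which(gi == g)
      best <- idx[order(abs(m[idx] - grid[g]), m[idx])][1L]
      sel[setdiff(idx, best)] <- FALSE
    }
    m <- m[sel]; y <- y[sel]; gi <- gi[sel]
  }
  if (length(m) < minVisits)
    stop("insufficient eligible timepoints: ", length(m), " usable scored ",
         "visit(s), need >= ", minVisits)
  span <- max(m) - min(m)
  if (span <= minSpanMonths)
    stop("scored timespan ", span, " months does not exceed ", minSpanMonths)
  d <- apply(template@means[, gi, drop = FALSE], 1L,
             function(mu) sqrt(sum((y - mu)^2)))
  lab <- template@classLabels[which.min(d)]  # which.min = first min: less severe wins ties
  list(subject_id = subject$info$subject_id[1L],
       label = lab,
       distances = stats::setNames(d, template@classLabels),
       months_used = grid[gi],
       span_months = span)
}

#' Assign trajectory classes to every eligible subject of a cohort
#'
#' Applies [assignTrajectory()] per subject; subjects failing the
#' eligibility rule (fewer than `minVisits` usable scored visits, or span not
#' exceeding `minSpanMonths`) are reported in a separate ineligible table
#' with the reason, never raised as errors.
#'
#' @param cohort a [Cohort].
#' @param template a [TrajectoryTemplate].
#' @inheritParams assignTrajectory
#' @return list with `assignments` (data.frame: subject_id, label, one
#'   `dist_<class>` column per class, n_months, span_months, last_month) and
#'   `ineligible` (data.frame: subject_id, reason).
#' @export
labelCohort <- function(cohort, template, snapMonths = 3,
                        minVisits = 3, minSpanMonths = 12) {
  ids <- subjectIds(cohort)
  rows <- list(); bad <- list()
  for (id in ids) {
    res <- tryCatch(
      assignTrajectory(getSubject(cohort, id), template, snapMonths,
                       minVisits, minSpanMonths),
      error = function(e) e)
    if (inherits(res, "error")) {
      bad[[id]] <- data.frame(subject_id = id,
                              reason = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      r <- data.frame(subject_id = id, label = res$label,
                      stringsAsFactors = FALSE)
      for (cl in template@classLabels)
        r[[paste0("dist_", cl)]] <- res$distances[[cl]]
      r$n_months <- length(res$months_used)
      r$span_months <- res$span_months
      r$last_month <- max(res$months_used)
      rows[[id]] <- r
    }
  }
  empty_assign <- data.frame(subject_id = character(), label = character(),
                             stringsAsFactors = FALSE)
  list(
    assignments = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                  else empty_assign,
    ineligible = if (length(bad)) do.call(rbind, c(bad, make.row.names = FALSE))
                 else data.frame(subject_id = character(), reason = character(),
                                 stringsAsFactors = FALSE)
  )
}

#' Extract the complete-case score matrix of a cohort
#'
#' Returns the subjects x grid-months score matrix restricted to subjects
#' with a non-missing score at every grid month — the complete-case input
#' the trajectory clustering step requires.
#'
#' @param cohort a [Cohort].
#' @param scale `"mmse"` or `"adas13"`.
#' @param months visit grid; defaults to the union of observed months.
#' @return numeric matrix with subject ids as row names.
#' @export
completeScoreMatrix <- function(cohort, scale, months = NULL) {
  .checkScale(scale)
  vis <- cohort@visits
  if (is.null(months)) months <- sort(unique(vis$month))
  ids <- subjectIds(cohort)
  mat <- matrix(NA_real_, length(ids), length(months),
                dimnames = list(ids, months))
  sel <- !is.na(vis[[scale]]) & vis$month %in% months
  mat[cbind(match(vis$subject_id[sel], ids),
            match(vis$month[sel], months))] <- vis[[scale]][sel]
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' Serialize a trajectory template to JSON
#' @param template a [TrajectoryTemplate].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTemplate <- function(template, path) {
  obj <- list(scale = template@scale, months = template@months,
              class_labels = template@classLabels,
              means = unname(template@means),
              n_per_class = template@nPerClass,
              provenance = template@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory template from JSON
#' @param path path written by [writeTemplate()].
#' @return a [TrajectoryTemplate].
#' @export
readTemplate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(obj$means)
  dimnames(means) <- list(obj$class_labels, NULL)
  new("TrajectoryTemplate", scale = obj$scale, months = as.numeric(obj$months),
      classLabels = as.character(obj$class_labels), means = means,
      nPerClass = as.integer(obj$n_per_class),
      provenance = as.list(obj$provenance))
}
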