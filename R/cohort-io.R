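#' Default clinical scale ranges
#'
#' MMSE spans 0-30 (lower is worse); ADAS-13 spans 0-85 (higher is worse).
#' @return named list of `c(min, max)` per scale.
#' @export
defaultScaleRanges <- function() {
  list(mmse = c(0, 30), adas13 = c(0, 85))
}

#' Direction of severity for a clinical scale
#'
#' Returns -1 for scales where lower scores are worse (MMSE) and +1 where
#' higher scores are worse (ADAS-13).
#' @param scale scale name.
#' @keywords internal
.severitySign <- function(scale) {
  switch(scale,
    mmse = -1,
    adas13 = 1,
    stop("unknown scale: ", scale)
  )
}

.checkScale <- function(scale) {
  if (!scale %in% c("mmse", "adas13"))
    stop("unknown scale name: ", scale, " (expected 'mmse' or 'adas13')")
  scale
}

#' Construct a Cohort
#'
#' Low-level constructor assembling a [Cohort] from its component tables; the
#' class validity method enforces all invariants. Visit rows are sorted by
#' subject and month.
#'
#' @param subjects data.frame of per-subject attributes.
#' @param visits data.frame of per-visit scores.
#' @param ct numeric matrix of cortical thickness, one row per visit row.
#' @param roiNames character ROI identifiers (defines `ct` column order).
#' @param scaleRanges named list of scale ranges.
#' @return a [Cohort].
#' @export
makeCohort <- function(subjects, visits, ct = NULL,
                       roiNames = paste0("roi_", seq_len(ncol(ct))),
                       scaleRanges = defaultScaleRanges()) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$age <- as.numeric(subjects$age)
  subjects$apoe4 <- as.integer(subjects$apoe4)
  visits$subject_id <- as.character(visits$subject_id)
  for (col in c("month", "mmse", "adas13"))
    if (col %in% names(visits)) visits[[col]] <- as.numeric(visits[[col]])
  if (is.null(ct)) {
    ct <- matrix(numeric(0), nrow = nrow(visits), ncol = 0)
    roiNames <- character(0)
  }
  ord <- order(match(visits$subject_id, subjects$subject_id), visits$month)
  visits <- visits[ord, , drop = FALSE]
  ct <- ct[ord, , drop = FALSE]
  rownames(visits) <- NULL
  rownames(ct) <- NULL
  colnames(ct) <- roiNames
  new("Cohort", subjects = subjects, visits = visits, ct = ct,
      roiNames = as.character(roiNames), scaleRanges = scaleRanges)
}

#' @rdname cohortAccessors
#' @export
nSubjects <- function(cohort) nrow(cohort@subjects)

#' Cohort accessors
#'
#' Small accessor family for [Cohort] slots: `nSubjects()` counts subjects,
#' `subjectIds()` returns their identifiers, `subjectTable()` and
#' `visitTable()` the per-subject and per-visit data frames, `ctMatrix()` the
#' visit-aligned thickness matrix, `roiNames()` the atlas region names and
#' `scaleRanges()` the declared score ranges.
#'
#' @param cohort a [Cohort].
#' @name cohortAccessors
#' @export
subjectIds <- function(cohort) cohort@subjects$subject_id

#' @rdname cohortAccessors
#' @export
subjectTable <- function(cohort) cohort@subjects

#' @rdname cohortAccessors
#' @export
visitTable <- function(cohort) cohort@visits

#' @rdname cohortAccessors
#' @export
ctMatrix <- function(cohort) cohort@ct

#' @rdname cohortAccessors
#' @export
roiNames <- function(cohort) cohort@roiNames

#' @rdname cohortAccessors
#' @export
scaleRanges <- function(cohort) cohort@scaleRanges

#' Extract one subject's record
#'
#' @param cohort a [Cohort].
#' @param id subject identifier.
#' @return list with elements `info` (1-row data.frame), `visits` (data.frame
#'   of this subject's visits) and `ct` (matrix of thickness rows aligned with
#'   `visits`).
#' @export
getSubject <- function(cohort, id) {
  i <- match(id, cohort@subjects$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", id)
  rows <- which(cohort@visits$subject_id == id)
  list(info = cohort@subjects[i, , drop = FALSE],
       visits = cohort@visits[rows, , drop = FALSE],
       ct = cohort@ct[rows, , drop = FALSE])
}

#' Subset a cohort by subject identifiers
#'
#' @param cohort a [Cohort].
#' @param ids subject identifiers to keep; order defines the result order.
#' @return a new [Cohort] restricted to `ids`.
#' @export
subsetCohort <- function(cohort, ids) {
  stopifnot(all(ids %in% cohort@subjects$subject_id))
  sub <- cohort@subjects[match(ids, cohort@subjects$subject_id), , drop = FALSE]
  keep <- cohort@visits$subject_id %in% ids
  vis <- cohort@visits[keep, , drop = FALSE]
  ct <- cohort@ct[keep, , drop = FALSE]
  makeCohort(sub, vis, ct, cohort@roiNames, cohort@scaleRanges)
}

.ctColumns <- function(atlas_size) paste0("ct_", seq_len(atlas_size))

#' Read a long-format cohort table
#'
#' Reads a UTF-8 comma-separated table with one row per subject-visit and
#' columns `subject_id, month, age, sex, apoe4, diagnosis, cohort, mmse,
#' adas13, ct_1..ct_<atlas_size>`. Empty cells denote missing values. Scores
#' and thickness vectors may be missing per visit; a thickness vector must be
#' either fully present or fully absent in a row. Validation failures name
#' the offending row (1-based, excluding the header) and column.
#'
#' @param path file path.
#' @param atlas_size number of atlas regions (default 78).
#' @param roiNames optional ROI names; defaults to `ct_1..ct_<atlas_size>`
#'   column names.
#' @param scaleRanges named list of scale ranges used for validation.
#' @return a [Cohort].
#' @seealso [writeCohortTable()] for the inverse operation.
#' @export
readCohortTable <- function(path, atlas_size = 78, roiNames = NULL,
                            scaleRanges = defaultScaleRanges()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  ct_cols <- .ctColumns(atlas_size)
  need <- c("subject_id", "month", "age", "sex", "apoe4", "diagnosis",
            "cohort", "mmse", "adas13")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  missing_ct <- setdiff(ct_cols, names(df))
  if (length(missing_ct))
    stop("cohort table has wrong CT width: missing column(s) ",
         paste(utils::head(missing_ct, 3), collapse = ", "),
         if (length(missing_ct) > 3) " ..." else "")

  dup <- duplicated(df[, c("subject_id", "month")])
  if (any(dup))
    stop("duplicated (subject_id, month) in row(s): ",
         paste(which(dup), collapse = ", "))
  bad_apoe <- !is.na(df$apoe4) & !(df$apoe4 %in% 0:2)
  if (any(bad_apoe))
    stop("invalid apoe4 value in row(s): ",
         paste(which(bad_apoe), collapse = ", "), " (column apoe4)")
  for (sc in names(scaleRanges)) {
    rng <- scaleRanges[[sc]]
    bad <- !is.na(df[[sc]]) & (df[[sc]] < rng[1] | df[[sc]] > rng[2])
    if (any(bad))
      stop(sc, " out of range [", rng[1], ",", rng[2], "] in row(s): ",
           paste(which(bad), collapse = ", "), " (column ", sc, ")")
  }

  # per-subject constants must not vary across a subject's rows
  for (col in c("age", "sex", "apoe4", "diagnosis", "cohort")) {
    n_distinct <- tapply(df[[col]], df$subject_id,
                         function(x) length(unique(x)))
    if (any(n_distinct > 1L))
      stop("column ", col, " varies within subject(s): ",
           paste(names(n_distinct)[n_distinct > 1L], collapse = ", "))
  }

  first_rows <- !duplicated(df$subject_id)
  subjects <- df[first_rows, c("subject_id", "age", "sex", "apoe4",
                               "diagnosis", "cohort")]
  rownames(subjects) <- NULL
  visits <- df[, c("subject_id", "month", "mmse", "adas13")]
  ct <- as.matrix(df[, ct_cols, drop = FALSE])
  mode(ct) <- "numeric"
  if (is.null(roiNames)) roiNames <- ct_cols
  makeCohort(subjects, visits, ct, roiNames, scaleRanges)
}

#' Write a cohort to the long-format dialect read by [readCohortTable()]
#'
#' Missing values are written as empty cells. The output is cell-for-cell
#' re-readable into an equal [Cohort].
#'
#' @param cohort a [Cohort].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeCohortTable <- function(cohort, path) {
  vis <- cohort@visits
  sub <- cohort@subjects
  i <- match(vis$subject_id, sub$subject_id)
  df <- data.frame(
    subject_id = vis$subject_id,
    month = vis$month,
    age = sub$age[i],
    sex = sub$sex[i],
    apoe4 = sub$apoe4[i],
    diagnosis = sub$diagnosis[i],
    cohort = sub$cohort[i],
    mmse = vis$mmse,
    adas13 = vis$adas13,
    stringsAsFactors = FALSE
  )
  if (length(cohort@roiNames)) {
    ct <- as.data.frame(cohort@ct)
    names(ct) <- .ctColumns(length(cohort@roiNames))
    df <- cbind(df, ct)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter subjects by the longitudinal eligibility rule
#'
#' Keeps subjects with at least `minVisits` visits carrying a non-missing
#' score on `scale` whose scored timespan exceeds `minSpanMonths` (strictly:
#' a span of exactly 12 months does not qualify under the default "longer
#' than one year" rule). The input cohort is unchanged; visits are not
#' dropped, only whole subjects.
#'
#' @param cohort a [Cohort].
#' @param scale `"mmse"` or `"adas13"`.
#' @param minVisits minimum number of scored visits (default 3).
#' @param minSpanMonths minimum scored timespan in months, exclusive
#'   (default 12).
#' @return a new [Cohort] containing only eligible subjects.
#' @export
filterEligible <- function(cohort, scale, minVisits = 3, minSpanMonths = 12) {
  .checkScale(scale)
  vis <- cohort@visits
  scored <- vis[!is.na(vis[[scale]]), c("subject_id", "month")]
  keep <- vapply(cohort@subjects$subject_id, function(id) {
    m <- scored$month[scored$subject_id == id]
    length(m) >= minVisits && (max(m) - min(m)) > minSpanMonths
  }, logical(1))
  subsetCohort(cohort, cohort@subjects$subject_id[keep])
}
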