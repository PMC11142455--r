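#' @import methods
NULL

#' Canonical network labels
#'
#' The nine functional networks used throughout the package, in the fixed
#' canonical order that defines the block structure of FC matrices: executive
#' control (ECN), default mode (DMN), dorsal attention (DAN), limbic (LN),
#' salience/ventral attention (SN), somatomotor (SMN), temporal-parietal (TP),
#' visual (VIS), and subcortical (SUB).
#'
#' @export
NETWORKS <- c("ECN", "DMN", "DAN", "LN", "SN", "SMN", "TP", "VIS", "SUB")

#' ParcellationScheme: ROI identities and network membership
#'
#' Holds ROI names with their assignment to one of the nine canonical
#' networks, in canonical network-sorted order (ROIs grouped by network, so
#' that diagonal blocks of an FC matrix are intranetwork edges). Construct
#' with [ParcellationScheme()].
#'
#' @slot roiName character vector of unique ROI names, canonical order.
#' @slot network character vector, parallel to `roiName`; each entry one of
#'   [NETWORKS].
#' @export
setClass("ParcellationScheme",
         representation(roiName = "character", network = "character"))

setValidity("ParcellationScheme", function(object) {
  msg <- character()
  if (length(object@roiName) != length(object@network))
    msg <- c(msg, "roiName and network lengths differ")
  if (anyDuplicated(object@roiName))
    msg <- c(msg, "duplicated ROI names")
  if (!all(object@network %in% NETWORKS))
    msg <- c(msg, sprintf("unknown network labels: %s",
                          paste(setdiff(object@network, NETWORKS), collapse = ", ")))
  ord <- order(match(object@network, NETWORKS))
  if (!identical(ord, seq_along(ord)))
    msg <- c(msg, "ROIs are not in canonical network-sorted order")
  if (length(msg)) msg else TRUE
})

#' RoiTimeSeries: one run's parcellated BOLD data
#'
#' A T x R matrix of ROI time courses for a single run of one subject, with
#' the sampling interval (TR) and a condition label. Columns are in the
#' canonical order of the associated [ParcellationScheme].
#'
#' @slot data numeric matrix, volumes in rows, ROIs in columns (named).
#' @slot subject character subject id.
#' @slot condition character, one of `"rest"`, `"task_run1"`, `"task_run2"`
#'   (or a derived label such as `"dot3"` after block extraction).
#' @slot tr numeric sampling interval in seconds (positive).
#' @export
setClass("RoiTimeSeries",
         representation(data = "matrix", subject = "character",
                        condition = "character", tr = "numeric"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@data) < 2) msg <- c(msg, "need at least 2 volumes")
  if (!is.numeric(object@data) || anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "non-finite entries in time series")
  if (length(object@tr) != 1 || object@tr <= 0) msg <- c(msg, "tr must be a positive scalar")
  if (is.null(colnames(object@data))) msg <- c(msg, "columns must carry ROI names")
  if (length(msg)) msg else TRUE
})

#' FCMatrix: Fisher-z functional connectivity for one condition
#'
#' Symmetric R x R matrix of Fisher r-to-z transformed Pearson correlations
#' between ROI time courses. The diagonal is undefined and stored as 0; it is
#' excluded from every edge set by construction, never by value inspection.
#'
#' @slot values numeric symmetric matrix (diagonal 0).
#' @slot condition character condition label (`"rest"`, `"dot1"`,
#'   `"dot3_run2"`, ...).
#' @slot nTimepoints integer number of volumes used.
#' @slot scheme the [ParcellationScheme] the rows/columns follow.
#' @export
setClass("FCMatrix",
         representation(values = "matrix", condition = "character",
                        nTimepoints = "integer", scheme = "ParcellationScheme"))

setValidity("FCMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@scheme@roiName))
    msg <- c(msg, "dimension does not match scheme")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "non-finite FC values")
  else {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "values not symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be stored as 0")
  }
  if (length(msg)) msg else TRUE
})

#' SubjectRecord: all per-subject inputs for the pipeline
#'
#' One included subject's raw materials: one rest run, two task runs, their
#' event tables, motion parameter traces, nuisance series, demographics, and
#' (for synthetic subjects) the generative ground truth.
#'
#' @slot subject character id.
#' @slot ageGroup `"young"` or `"old"`.
#' @slot sex `"M"` or `"F"`.
#' @slot scanner `"pre"` or `"post"` (scanner-upgrade status).
#' @slot age numeric age in years.
#' @slot rest [RoiTimeSeries] for the resting run (untrimmed).
#' @slot taskRuns list of two [RoiTimeSeries] (untrimmed).
#' @slot events list of two event data.frames (see [readEvents()]).
#' @slot motion list of three T x 6 motion-parameter matrices
#'   (rest, task_run1, task_run2; 3 translations mm, 3 rotations rad).
#' @slot nuisance list of three T x 2 matrices of CSF and WM mean signals.
#' @slot truth list of generative ground truth (empty for real data).
#' @export
setClass("SubjectRecord",
         representation(subject = "character", ageGroup = "character",
                        sex = "character", scanner = "character",
                        age = "numeric", rest = "RoiTimeSeries",
                        taskRuns = "list", events = "list",
                        motion = "list", nuisance = "list", truth = "list"))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (!object@ageGroup %in% c("young", "old")) msg <- c(msg, "ageGroup must be young/old")
  if (length(object@taskRuns) != 2) msg <- c(msg, "exactly two task runs required")
  if (length(object@events) != 2) msg <- c(msg, "exactly two event tables required")
  if (length(msg)) msg else TRUE
})

#' Cohort: a set of subjects plus their participants table
#'
#' @slot subjects list of [SubjectRecord].
#' @slot participants data.frame with columns subject, age_group, sex,
#'   scanner, age.
#' @export
setClass("Cohort",
         representation(subjects = "list", participants = "data.frame"))

setMethod("show", "ParcellationScheme", function(object) {
  cat(sprintf("ParcellationScheme: %d ROIs, %d networks\n",
              length(object@roiName), length(unique(object@network))))
  print(table(factor(object@network, levels = NETWORKS)))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s' (%s): %d volumes x %d ROIs, TR %.3g s\n",
              object@subject, object@condition,
              nrow(object@data), ncol(object@data), object@tr))
})

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix (%s): %d x %d, from %d volumes\n",
              object@condition, nrow(object@values), ncol(object@values),
              object@nTimepoints))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s': %s, %s, scanner %s, age %.1f\n",
              object@subject, object@ageGroup, object@sex, object@scanner,
              object@age))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@participants$age_group)
  cat(sprintf("Cohort: %d subjects (%s)\n", length(object@subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
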