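#' @include AllClasses.R parcellation.R
NULL

EVENT_TYPES <- c("blank", "fixation", "encoding", "maintenance", "probe",
                 "response", "inter_trial_blank", "baseline")

#' Read a parcellated ROI time-series table
#'
#' Tab-separated file: one header row of ROI names, one row per volume.
#' Columns may arrive in any order; they are reordered to the canonical
#' network-sorted order of `scheme`.
#'
#' @param path file path.
#' @param scheme the [ParcellationScheme-class] the columns must match.
#' @param subject subject id to stamp on the result.
#' @param condition condition label (`"rest"`, `"task_run1"`, `"task_run2"`).
#' @param tr sampling interval in seconds (from the sidecar/config; default 2).
#' @return a [RoiTimeSeries-class] with columns in canonical order.
#' @export
readTimeSeries <- function(path, scheme, subject = "unknown",
                           condition = "rest", tr = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- roiNames(scheme)
  missing_rois <- setdiff(want, names(df))
  if (length(missing_rois))
    stop("time-series file is missing ROI column(s): ",
         paste(missing_rois, collapse = ", "))
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("time-series file has unexpected column(s): ",
         paste(extra, collapse = ", "))
  m <- as.matrix(df[, want, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))))[1]
    stop(sprintf("non-numeric value in column '%s', row %d", names(df)[bad], badrow))
  }
  new("RoiTimeSeries", data = m, subject = subject, condition = condition,
      tr = tr)
}

#' Write a ROI time-series table
#' @param ts a [RoiTimeSeries-class].
#' @param path output path (TSV).
#' @return invisibly, `path`.
#' @export
writeTimeSeries <- function(ts, path) {
  # %.17g keeps the binary double exactly recoverable on read
  df <- as.data.frame(apply(ts@data, 2, sprintf, fmt = "%.17g"))
  names(df) <- colnames(ts@data)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a task event table
#'
#' Enforces the structural invariants of a single task run: non-decreasing
#' onsets, known event types, one encoding/maintenance/probe per trial, and
#' exactly three 10-trial blocks, one per load in \{1, 3, 5\}.
#'
#' @param events data.frame with columns onset, duration, event_type, load,
#'   trial_id, correct, response_time.
#' @return the events data.frame, invisibly, if valid; otherwise an error.
#' @export
validateEvents <- function(events) {
  need <- c("onset", "duration", "event_type", "load", "trial_id",
            "correct", "response_time")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.unsorted(events$onset)) stop("event onsets must be non-decreasing")
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad)) stop("unknown event_type(s): ", paste(bad, collapse = ", "))
  tr_rows <- events[!is.na(events$trial_id), , drop = FALSE]
  for (ev in c("encoding", "maintenance", "probe")) {
    cnt <- table(tr_rows$trial_id[tr_rows$event_type == ev])
    ids <- unique(tr_rows$trial_id)
    if (!all(ids %in% names(cnt)) || any(cnt != 1))
      stop("each trial must contain exactly one ", ev, " event")
  }
  enc <- tr_rows[tr_rows$event_type == "encoding", ]
  per_load <- table(enc$load)
  if (!setequal(names(per_load), c("1", "3", "5")))
    stop("run must contain loads 1, 3 and 5; found: ",
         paste(names(per_load), collapse = ", "))
  if (any(per_load != 10))
    stop("each load block must contain exactly 10 trials; counts: ",
         paste(sprintf("load %s: %d", names(per_load), per_load), collapse = ", "))
  invisible(events)
}

#' Read a task event table (BIDS-style TSV dialect)
#'
#' Tab-separated with columns onset, duration, event_type (aka trial_type),
#' load, trial_id, correct, response_time. `n/a`, empty cells and `NA` map to
#' missing. The result passes [validateEvents()].
#'
#' @param path file path.
#' @return a validated events data.frame.
#' @export
readEvents <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("n/a", "NA", ""))
  if ("trial_type" %in% names(df) && !"event_type" %in% names(df))
    names(df)[names(df) == "trial_type"] <- "event_type"
  df$onset <- as.numeric(df$onset)
  df$duration <- as.numeric(df$duration)
  df$load <- as.integer(df$load)
  df$trial_id <- as.integer(df$trial_id)
  df$correct <- as.logical(df$correct)
  df$response_time <- as.numeric(df$response_time)
  validateEvents(df)
  df
}

#' Write a task event table
#' @param events events data.frame.
#' @param path output path (TSV); missing values written as `n/a`.
#' @return invisibly, `path`.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read / write per-volume motion parameters
#'
#' Six columns per volume: three translations (mm), three rotations (rad).
#'
#' @param path file path (TSV, no header).
#' @return numeric T x 6 matrix.
#' @export
readMotion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion file must have exactly 6 columns, got ", ncol(m))
  dimnames(m) <- NULL
  m
}

#' @rdname readMotion
#' @param motion numeric T x 6 matrix.
#' @export
writeMotion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a participants table
#' @param path TSV with columns subject, age_group, sex, scanner (and
#'   optionally age).
#' @return data.frame.
#' @export
readParticipants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "age_group", "sex", "scanner")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("participants table missing: ", paste(miss, collapse = ", "))
  df
}

#' Cohort-level inclusion filtering
#'
#' Keeps subjects performing above chance at the easy load (accuracy > 0.5,
#' strict) whose every run passes motion QC (maximum absolute displacement
#' <= 4 mm and maximum framewise displacement <= 2 mm, both inclusive).
#' Filtering is order-independent: all rules are evaluated for every subject
#' and every violated rule is logged.
#'
#' @param behavior behavior summary table from [scoreBehavior()] covering all
#'   subjects (columns subject, load, accuracy).
#' @param motionSummary data.frame with one row per subject x run: columns
#'   subject, run, max_fd, max_abs_displacement (see [computeFD()]).
#' @param accuracyFloor exclusion threshold on easy-load accuracy (strict >).
#' @param maxFd inclusive bound on maximum framewise displacement (mm).
#' @param maxAbs inclusive bound on maximum absolute displacement (mm).
#' @return list with `included` (character subject ids) and `exclusions`
#'   (data.frame subject, rule).
#' @export
applyInclusionFilters <- function(behavior, motionSummary,
                                  accuracyFloor = 0.5, maxFd = 2, maxAbs = 4) {
  subjectsAll <- unique(c(behavior$subject, motionSummary$subject))
  excl <- list()
  for (s in subjectsAll) {
    beh <- behavior[behavior$subject == s & behavior$load == 1L, , drop = FALSE]
    if (nrow(beh) == 0)
      stop("subject ", s, " has no scored easy-load behavior; score before filtering")
    mot <- motionSummary[motionSummary$subject == s, , drop = FALSE]
    if (nrow(mot) == 0)
      stop("subject ", s, " has no motion summary; summarize motion before filtering")
    if (!(beh$accuracy[1] > accuracyFloor))
      excl[[length(excl) + 1L]] <- data.frame(
        subject = s, rule = "easy_load_accuracy<=0.5", stringsAsFactors = FALSE)
    if (any(mot$max_fd > maxFd))
      excl[[length(excl) + 1L]] <- data.frame(
        subject = s, rule = "max_framewise_displacement>2mm", stringsAsFactors = FALSE)
    if (any(mot$max_abs_displacement > maxAbs))
      excl[[length(excl) + 1L]] <- data.frame(
        subject = s, rule = "max_absolute_displacement>4mm", stringsAsFactors = FALSE)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject = character(), rule = character(), stringsAsFactors = FALSE)
  list(included = setdiff(subjectsAll, exclusions$subject),
       exclusions = exclusions)
}
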