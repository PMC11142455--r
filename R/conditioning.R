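#' @include AllClasses.R utils.R
NULL

#' Signal-conditioning configuration
#'
#' @param hrfPeak,hrfUndershoot response and undershoot peak times (s).
#' @param hrfDispersion,hrfUDispersion gamma dispersions (s).
#' @param hrfRatio undershoot-to-peak amplitude ratio.
#' @param hrfLength kernel length (s).
#' @param bandLow,bandHigh band-pass edges (Hz) for rest data.
#' @param polyOrder detrend polynomial order for rest data.
#' @param volumesToTrim leading volumes discarded from every run.
#' @param fdRadius rotation-to-translation radius (mm) for framewise
#'   displacement.
#' @return a list of class `SignalConfig`.
#' @export
signalConfig <- function(hrfPeak = 6, hrfUndershoot = 16, hrfDispersion = 1,
                         hrfUDispersion = 1, hrfRatio = 1 / 6, hrfLength = 32,
                         bandLow = 0.009, bandHigh = 0.1,
                         polyOrder = 2L, volumesToTrim = 5L, fdRadius = 50) {
  stopifnot(bandLow > 0, bandLow < bandHigh)
  cfg <- list(hrfPeak = hrfPeak, hrfUndershoot = hrfUndershoot,
              hrfDispersion = hrfDispersion, hrfUDispersion = hrfUDispersion,
              hrfRatio = hrfRatio, hrfLength = hrfLength,
              bandLow = bandLow, bandHigh = bandHigh,
              polyOrder = as.integer(polyOrder),
              volumesToTrim = as.integer(volumesToTrim), fdRadius = fdRadius)
  class(cfg) <- "SignalConfig"
  cfg
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities (response peaking at `hrfPeak` s,
#' undershoot at `hrfUndershoot` s, relative amplitude `hrfRatio`), sampled
#' at the TR and normalized to a peak of 1.
#'
#' @param tr sampling interval (s), positive.
#' @param config a [signalConfig()].
#' @return numeric kernel; positive main lobe, negative undershoot.
#' @export
canonicalHrf <- function(tr, config = signalConfig()) {
  stopifnot(tr > 0)
  if (config$hrfLength < config$hrfPeak)
    stop("kernel length (", config$hrfLength, " s) shorter than response peak")
  t <- seq(0, config$hrfLength, by = tr)
  shape1 <- config$hrfPeak / config$hrfDispersion + 1
  shape2 <- config$hrfUndershoot / config$hrfUDispersion + 1
  h <- stats::dgamma(t, shape = shape1, scale = config$hrfDispersion) -
    config$hrfRatio * stats::dgamma(t, shape = shape2,
                                    scale = config$hrfUDispersion)
  h / max(h)
}

# Fractional-overlap boxcar of a set of [onset, onset + duration) intervals
# on a T-volume grid; zero-duration events become unit impulses in their
# containing volume.
boxcarOnGrid <- function(onset, duration, T, tr) {
  x <- numeric(T)
  imp <- duration <= 0
  if (any(imp)) {
    v <- pmin(T, floor(onset[imp] / tr) + 1L)
    x <- x + tabulate(v, T)
  }
  if (any(!imp)) {
    a <- onset[!imp]; b <- (onset + duration)[!imp]
    grid <- seq(0, T) * tr
    # cumulative activated time up to each grid point, summed over events
    A <- colSums(pmax(sweep(outer(b, grid, pmin), 1, a), 0))
    x <- x + diff(A) / tr
  }
  x
}

# First onset .. last offset of all non-baseline events of a load block.
loadInterval <- function(events, load) {
  rows <- events[!is.na(events$load) & events$load == load, , drop = FALSE]
  if (nrow(rows) == 0) stop("load ", load, " absent from run events")
  c(min(rows$onset), max(rows$onset + rows$duration))
}

#' Build task-activation regressors
#'
#' One HRF-convolved boxcar per event class: `encoding` (a single boxcar
#' spanning all dots of a trial), `maintenance`, `probe`, `response` (an
#' impulse at the button press), `iti` (fixation and blanks between trials),
#' and `correct` / `wrong` (boxcars spanning the whole trial, split by
#' outcome). The temporal derivative of each retained main regressor (first
#' difference of the convolved regressor) is appended when
#' `derivatives = TRUE`. Classes whose regressor is identically zero (for
#' example `wrong` in an error-free run) are dropped and reported in the
#' `dropped` element.
#'
#' @param events validated event table ([validateEvents()]).
#' @param T number of volumes in the run (after trimming).
#' @param tr sampling interval (s).
#' @param config a [signalConfig()].
#' @param classes event classes to model.
#' @param derivatives append temporal derivatives?
#' @return list of class `DesignMatrix`: `X` (T x K, labeled columns),
#'   `tr`, `dropped` (character).
#' @export
buildTaskRegressors <- function(events, T, tr, config = signalConfig(),
                                classes = c("encoding", "maintenance", "probe",
                                            "response", "iti", "correct",
                                            "wrong"),
                                derivatives = TRUE) {
  if (any(events$onset + events$duration > T * tr + 1e-9))
    stop("event extends beyond run end (", T * tr, " s)")
  hrf <- canonicalHrf(tr, config)
  onset <- events$onset; duration <- events$duration
  etype <- events$event_type; trial <- events$trial_id
  # per-trial span (blank through probe end) and outcome, for correct/wrong
  core <- etype %in% c("blank", "fixation", "encoding", "maintenance", "probe")
  spanStart <- tapply(onset[core], trial[core], min)
  spanEnd <- tapply((onset + duration)[core], trial[core], max)
  pr <- etype == "probe"
  outcome <- stats::setNames(events$correct[pr], trial[pr])[names(spanStart)]
  boxes <- list()
  for (cl in classes) {
    if (cl %in% c("encoding", "maintenance", "probe", "response")) {
      keep <- etype == cl
      boxes[[cl]] <- boxcarOnGrid(onset[keep], duration[keep], T, tr)
    } else if (cl == "iti") {
      keep <- etype %in% c("blank", "fixation", "inter_trial_blank")
      boxes[[cl]] <- boxcarOnGrid(onset[keep], duration[keep], T, tr)
    } else if (cl %in% c("correct", "wrong")) {
      sel <- !is.na(outcome) & (outcome == (cl == "correct"))
      boxes[[cl]] <- if (any(sel))
        boxcarOnGrid(spanStart[sel], spanEnd[sel] - spanStart[sel], T, tr)
        else numeric(T)
    } else stop("unknown regressor class: ", cl)
  }
  conv <- lapply(boxes, function(bc)
    stats::convolve(bc, rev(hrf), type = "open")[seq_len(T)])
  dropped <- names(conv)[vapply(conv, function(v) all(v == 0), logical(1))]
  conv <- conv[setdiff(names(conv), dropped)]
  X <- do.call(cbind, conv)
  colnames(X) <- names(conv)
  if (derivatives) {
    D <- apply(X, 2, function(v) c(0, diff(v)))
    colnames(D) <- paste0(colnames(X), "_deriv")
    X <- cbind(X, D)
  }
  structure(list(X = X, tr = tr, dropped = dropped), class = "DesignMatrix")
}

#' Ordinary-least-squares residualization
#'
#' Regresses every ROI time course on the given regressors (an intercept is
#' always added; constant or all-zero columns are dropped first) and returns
#' the residual series, which is orthogonal to every retained regressor.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param X T x K regressor matrix (no intercept column needed).
#' @return a [RoiTimeSeries-class] of residuals; dropped columns recorded in
#'   attribute `"dropped"`.
#' @export
regressOut <- function(ts, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  M <- cbind(`(intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    aliased <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("regressor matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- qr.resid(qrM, ts@data)
  colnames(res) <- colnames(ts@data)
  out <- fastTs(res, ts@subject, ts@condition, ts@tr)
  attr(out, "dropped") <- dropped
  out
}

#' Detrend and band-pass a resting run
#'
#' Removes, in a single least-squares projection per ROI, an order-2
#' polynomial trend together with every Fourier component outside the
#' `bandLow`-`bandHigh` Hz band. Realizing detrend + band-pass as one
#' orthogonal projection gives exact band edges, zero phase distortion, and
#' makes the operation idempotent to machine precision (re-running the rest
#' pipeline on its own output changes nothing).
#'
#' @param ts a [RoiTimeSeries-class] (trimmed).
#' @param config a [signalConfig()].
#' @return a [RoiTimeSeries-class].
#' @export
bandpassDetrendRest <- function(ts, config = signalConfig()) {
  x <- ts@data
  n <- nrow(x)
  nyq <- 1 / (2 * ts@tr)
  if (config$bandHigh >= nyq)
    stop("band edge ", config$bandHigh, " Hz not below Nyquist (", nyq, " Hz)")
  qrB <- bandstopBasisQr(n, ts@tr, config$bandLow, config$bandHigh,
                         config$polyOrder)
  filt <- qr.resid(qrB, x)
  colnames(filt) <- colnames(ts@data)
  fastTs(filt, ts@subject, ts@condition, ts@tr)
}

# QR of the nuisance basis spanned by the polynomial trend and the
# out-of-band Fourier components, memoised per (n, tr, band, order).
.bandBasisCache <- new.env(parent = emptyenv())
bandstopBasisQr <- function(n, tr, low, high, polyOrder) {
  key <- paste(n, tr, low, high, polyOrder, sep = "|")
  if (!is.null(.bandBasisCache[[key]])) return(.bandBasisCache[[key]])
  tt <- seq_len(n)
  B <- cbind(1, stats::poly(tt, degree = polyOrder))
  kmax <- floor((n - 1) / 2)
  k <- seq_len(kmax)
  f <- k / (n * tr)
  excl <- k[f < low | f > high]
  if (length(excl)) {
    ang <- outer(tt, 2 * pi * excl / n)
    B <- cbind(B, cos(ang), sin(ang))
  }
  if (n %% 2 == 0 && (0.5 / tr < low || 0.5 / tr > high))
    B <- cbind(B, rep_len(c(1, -1), n))  # Nyquist bin
  .bandBasisCache[[key]] <- qr(B)
  .bandBasisCache[[key]]
}

#' Extract and concatenate load-specific task blocks
#'
#' For each run, keeps the volumes whose midpoints fall inside the load's
#' block interval (first trial onset to last trial end, including the
#' within-block inter-trial blanks); the 4 s inter-block baselines are
#' discarded. Each run's segment is mean-centered per ROI, then segments are
#' concatenated in run order.
#'
#' @param runs list of residual [RoiTimeSeries-class], one per run.
#' @param eventsList list of matching event tables.
#' @param load 1, 3, or 5.
#' @param perRun if TRUE return the per-run segments separately (for the
#'   within-load stability analysis) instead of concatenating.
#' @return a [RoiTimeSeries-class] labeled `dot<load>` (or a list of two,
#'   labeled `dot<load>_run<r>`, when `perRun = TRUE`).
#' @export
extractLoadBlocks <- function(runs, eventsList, load, perRun = FALSE) {
  stopifnot(length(runs) == length(eventsList))
  segs <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    ts <- runs[[r]]
    iv <- loadInterval(eventsList[[r]], load)
    mid <- (seq_len(nrow(ts@data)) - 0.5) * ts@tr
    keep <- mid >= iv[1] & mid <= iv[2]
    if (!any(keep)) stop("no volumes fall inside load ", load, " block of run ", r)
    seg <- ts@data[keep, , drop = FALSE]
    segs[[r]] <- sweep(seg, 2, colMeans(seg))
  }
  if (perRun) {
    return(lapply(seq_along(segs), function(r)
      fastTs(segs[[r]], runs[[1]]@subject,
             sprintf("dot%d_run%d", load, r), runs[[1]]@tr)))
  }
  fastTs(do.call(rbind, segs), runs[[1]]@subject,
         sprintf("dot%d", load), runs[[1]]@tr)
}

# Framewise displacement series (Power convention): sum of absolute
# translation differences plus radius-scaled absolute rotation differences.
framewiseDisplacement <- function(motion, radius = 50) {
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Motion summaries from rigid-body parameters
#'
#' @param motion T x 6 matrix (3 translations mm, 3 rotations rad).
#' @param config a [signalConfig()] (supplies the rotation radius).
#' @return list: `fd` (length T - 1 series, mm), `mean_fd`, `max_fd`,
#'   `max_abs_displacement` (max Euclidean translation from the reference
#'   position, mm).
#' @export
computeFD <- function(motion, config = signalConfig()) {
  if (ncol(motion) != 6) stop("motion must have 6 columns, got ", ncol(motion))
  if (nrow(motion) < 2) stop("need at least 2 volumes of motion parameters")
  fd <- framewiseDisplacement(motion, config$fdRadius)
  list(fd = fd, mean_fd = mean(fd), max_fd = max(fd),
       max_abs_displacement = max(sqrt(rowSums(motion[, 1:3, drop = FALSE]^2))))
}

# ---- per-subject conditioning pipelines ------------------------------------

trimTs <- function(ts, nTrim) {
  fastTs(ts@data[-seq_len(nTrim), , drop = FALSE], ts@subject,
         ts@condition, ts@tr)
}

#' Condition one subject's runs
#'
#' Task pipeline: trim leading volumes, then one joint OLS regression of
#' task-activation regressors (all seven classes plus derivatives) and
#' nuisance series (six motion parameters, CSF, WM, global signal), then
#' load-block extraction. Rest pipeline: trim, nuisance regression, then
#' detrend and band-pass.
#'
#' @param subject a [SubjectRecord-class].
#' @param config a [signalConfig()].
#' @param perRun also return per-run load segments (within-load mode).
#' @param loads which loads to extract (default all three).
#' @return list: `rest` (conditioned [RoiTimeSeries-class]), `loads` (list
#'   dot1/dot3/dot5), `perRun` (optional list of per-run segments), `motion`
#'   (data.frame of per-run FD summaries), `taskResiduals` (list of residual
#'   runs).
#' @export
conditionSubject <- function(subject, config = signalConfig(), perRun = FALSE,
                             loads = c(1L, 3L, 5L)) {
  k <- config$volumesToTrim
  nuisanceFor <- function(ts, motion, nuis) {
    cbind(motion, nuis, global = rowMeans(ts@data))
  }

  restTs <- trimTs(subject@rest, k)
  restMotion <- subject@motion$rest[-seq_len(k), , drop = FALSE]
  restNuis <- subject@nuisance$rest[-seq_len(k), , drop = FALSE]
  colnames(restMotion) <- paste0("mp", 1:6)
  rest <- regressOut(restTs, nuisanceFor(restTs, restMotion, restNuis))
  rest <- bandpassDetrendRest(rest, config)

  motionRows <- list(data.frame(subject = subject@subject, run = "rest",
                                as.data.frame(computeFD(restMotion, config)[-1]),
                                stringsAsFactors = FALSE))
  residRuns <- list()
  for (r in 1:2) {
    ts <- trimTs(subject@taskRuns[[r]], k)
    lab <- paste0("task_run", r)
    mot <- subject@motion[[lab]][-seq_len(k), , drop = FALSE]
    colnames(mot) <- paste0("mp", 1:6)
    nuis <- subject@nuisance[[lab]][-seq_len(k), , drop = FALSE]
    dm <- buildTaskRegressors(subject@events[[r]], nrow(ts@data), ts@tr, config)
    residRuns[[r]] <- regressOut(ts, cbind(dm$X, nuisanceFor(ts, mot, nuis)))
    motionRows[[r + 1]] <- data.frame(subject = subject@subject, run = lab,
                                      as.data.frame(computeFD(mot, config)[-1]),
                                      stringsAsFactors = FALSE)
  }
  loadTs <- lapply(loads, function(l)
    extractLoadBlocks(residRuns, subject@events, l))
  names(loadTs) <- paste0("dot", loads)
  out <- list(rest = rest, loads = loadTs,
              motion = do.call(rbind, motionRows), taskResiduals = residRuns)
  if (perRun) {
    pr <- list()
    for (l in loads)
      pr <- c(pr, extractLoadBlocks(residRuns, subject@events, l, perRun = TRUE))
    names(pr) <- vapply(pr, function(x) x@condition, character(1))
    out$perRun <- pr
  }
  out
}
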