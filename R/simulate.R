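#' @include cohort-spec.R utils.R
NULL

#' Block-structured network covariance
#'
#' Unit-diagonal covariance with correlation `w` for same-network ROI pairs
#' and `b` for between-network pairs: the ground-truth segregation structure
#' the FC-similarity metric must detect.
#'
#' @param scheme a [ParcellationScheme-class].
#' @param w within-network correlation, in (-1, 1).
#' @param b between-network correlation, in (-1, 1).
#' @return R x R positive-definite covariance matrix.
#' @export
buildNetworkCovariance <- function(scheme, w, b) {
  if (w <= -1 || w >= 1 || b <= -1 || b >= 1)
    stop("correlations must lie strictly in (-1, 1)")
  net <- scheme@network
  same <- outer(net, net, "==")
  sigma <- ifelse(same, w, b)
  diag(sigma) <- 1
  ev <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ev))
    stop(sprintf("covariance with (w = %g, b = %g) is not positive definite", w, b))
  sigma
}

# Fixed, seeded ROI permutation defining the alternative ("task") topology.
# Permuting rows/columns of the rest covariance is a relabeling: spectrum is
# preserved (so positive definiteness is guaranteed) but the intra/inter
# block structure genuinely changes.
altPermutation <- function(spec) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(deriveSeed(spec$seed, "alt_topology"))
  sample.int(spec$R)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Load-specific covariance for one subject
#'
#' Convex mixture `(1 - lambda) * Sigma_rest + lambda * Sigma_alt`, where
#' `Sigma_alt` is the rest covariance under the cohort spec's fixed seeded ROI
#' permutation. `lambda = 0` returns the rest covariance exactly;
#' `lambda = 1` the fully reconfigured topology.
#'
#' @param sigmaRest group rest covariance (from [buildNetworkCovariance()]).
#' @param perm ROI permutation defining the alternative topology.
#' @param lambda mixing weight in `[0, 1]`.
#' @return covariance matrix.
#' @export
mixCovariance <- function(sigmaRest, perm, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda == 0) return(sigmaRest)
  sigmaAlt <- sigmaRest[perm, perm]
  (1 - lambda) * sigmaRest + lambda * sigmaAlt
}

#' @describeIn mixCovariance convenience wrapper resolving group covariance
#'   and permutation from a [cohortSpec()].
#' @param spec a [cohortSpec()].
#' @param group `"young"` or `"old"`.
#' @export
subjectConditionCovariance <- function(spec, group, lambda) {
  sigmaRest <- buildNetworkCovariance(spec$scheme, spec$w[[group]], spec$b[[group]])
  mixCovariance(sigmaRest, altPermutation(spec), lambda)
}

# ---- event schedule ---------------------------------------------------------

# One run's event table. Onsets are seconds from the first retained volume.
# Run layout: 4 s baseline, three 10-trial blocks (one load each, in
# blockOrder) separated by 4 s baselines, 4 s final baseline. Trial layout:
# blank 1 s, fixation 0.5 s, encoding 0.5 s per dot, maintenance 3 s, probe
# 2 s (response within the probe window), inter-trial blank jittered
# 2.5-4.5 s.
simulateRunEvents <- function(blockOrder, outcomes) {
  nmax <- 300L
  onset <- duration <- rt <- numeric(nmax)
  type <- character(nmax)
  load <- trial_id <- integer(nmax)
  correct <- logical(nmax)
  load[] <- NA_integer_; trial_id[] <- NA_integer_
  correct[] <- NA; rt[] <- NA_real_
  k <- 0L
  add <- function(o, d, ty, l = NA_integer_, tr = NA_integer_,
                  co = NA, r = NA_real_) {
    k <<- k + 1L
    onset[k] <<- o; duration[k] <<- d; type[k] <<- ty
    load[k] <<- l; trial_id[k] <<- tr; correct[k] <<- co; rt[k] <<- r
  }
  t <- 0
  add(t, 4, "baseline"); t <- t + 4
  trial <- 0L
  for (bi in seq_along(blockOrder)) {
    l <- blockOrder[bi]
    out <- outcomes[[as.character(l)]]
    for (j in 1:10) {
      trial <- trial + 1L
      co <- out$correct[j]; r <- out$rt[j]
      add(t, 1, "blank", l, trial); t <- t + 1
      add(t, 0.5, "fixation", l, trial); t <- t + 0.5
      add(t, 0.5 * l, "encoding", l, trial, co, r); t <- t + 0.5 * l
      add(t, 3, "maintenance", l, trial); t <- t + 3
      add(t, 2, "probe", l, trial, co, r)
      if (!is.na(r)) add(t + r, 0, "response", l, trial, co, r)
      t <- t + 2
      add(t, out$iti[j], "inter_trial_blank", l, trial); t <- t + out$iti[j]
    }
    add(t, 4, "baseline"); t <- t + 4
  }
  idx <- order(onset[seq_len(k)])
  data.frame(onset = onset[idx], duration = duration[idx],
             event_type = type[idx], load = load[idx],
             trial_id = trial_id[idx], correct = correct[idx],
             response_time = rt[idx], stringsAsFactors = FALSE)
}

# Per-block trial outcomes under the planted behavior model.
drawTrialOutcomes <- function(spec, group, lambda, loadIndex, epsilon, n = 10) {
  p <- stats::plogis(spec$a0 - spec$a1 * lambda - spec$loadPenalty[loadIndex] -
                       spec$groupPenalty[[group]] + epsilon)
  correct <- stats::rbinom(n, 1, p) == 1
  rt <- pmin(1.95, stats::rlnorm(
    n, log(spec$rtBase) + spec$rtLoad * (loadIndex - 1) + spec$rtLambda * lambda,
    spec$rtSdlog))
  list(correct = correct, rt = rt, iti = stats::runif(n, 2.5, 4.5), p = p)
}

#' Simulate behavioral outcomes for one subject
#'
#' Draws 20 trials per load (two runs of 10) under the planted coupling
#' between accuracy and the subject's reconfiguration weights. Exposed
#' separately so the behavior model can be studied without simulating fMRI.
#'
#' @param spec a [cohortSpec()].
#' @param lambdas named numeric of subject mixing weights for loads
#'   `"1"`, `"3"`, `"5"`.
#' @param group `"young"` or `"old"`.
#' @param seed integer seed.
#' @return data.frame with columns run, load, trial, correct, rt, p.
#' @export
simulateBehavior <- function(spec, lambdas, group, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  epsilon <- stats::rnorm(1, 0, spec$noiseSd)
  out <- list()
  for (run in 1:2) for (li in 1:3) {
    load <- c(1L, 3L, 5L)[li]
    o <- drawTrialOutcomes(spec, group, lambdas[[as.character(load)]], li, epsilon)
    out[[length(out) + 1L]] <- data.frame(
      run = run, load = load, trial = seq_len(10), correct = o$correct,
      rt = o$rt, p = o$p)
  }
  do.call(rbind, out)
}

# ---- fMRI data generation ---------------------------------------------------

# Random-walk motion parameters whose expected framewise displacement is mu;
# translation and rotation innovations are scaled so each contributes half
# under the 50 mm rotation radius.
simulateMotion <- function(T, mu) {
  sdT <- mu * sqrt(pi / 2) / 6
  innov <- cbind(matrix(stats::rnorm(3 * T, 0, sdT), T, 3),
                 matrix(stats::rnorm(3 * T, 0, sdT / 50), T, 3))
  innov[1, ] <- 0
  apply(innov, 2, cumsum)
}

# AR(1) nuisance series (CSF, WM means).
simulateNuisance <- function(T, phi = 0.5) {
  m <- matrix(stats::rnorm(2 * T), T, 2)
  m <- apply(m, 2, function(e) stats::filter(e, phi, method = "recursive"))
  colnames(m) <- c("csf", "wm")
  m
}

# Multivariate normal rows given an upper-triangular Cholesky factor.
mvnRows <- function(n, cholU) {
  matrix(stats::rnorm(n * ncol(cholU)), n) %*% cholU
}

# Quadratic drift with random per-ROI coefficients.
simulateDrift <- function(T, R, sd) {
  tt <- seq(-1, 1, length.out = T)
  cbind(tt, tt^2) %*% matrix(stats::rnorm(2 * R, 0, sd), 2, R)
}

#' Simulate one subject's full record
#'
#' Generates the rest run (retained volumes plus leading dummies), two task
#' runs with randomized block order, event tables with planted behavioral
#' outcomes, motion traces with an FD-locked artifact component injected into
#' the data, CSF/WM nuisance series with leakage, quadratic drift, and an
#' HRF-convolved task-evoked component. Task-block volumes are drawn from the
#' subject's load-specific mixed covariance; all other volumes from the
#' group rest covariance.
#'
#' @param spec a [cohortSpec()].
#' @param meta list with subject, ageGroup, sex, scanner, age.
#' @param seed integer seed; identical seeds give identical records.
#' @param cache optional precomputed list (restChol per group, perm) from
#'   [simulateCohort()]; built on the fly if NULL.
#' @return a [SubjectRecord-class]; `@truth` holds lambda, delta, epsilon and
#'   per-load accuracy probabilities.
#' @export
simulateSubject <- function(spec, meta, seed, cache = NULL) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (is.null(cache)) cache <- cohortCache(spec)
  g <- meta$ageGroup
  R <- spec$R
  tr <- spec$trSeconds
  scheme <- spec$scheme

  delta <- stats::rnorm(1, 0, spec$tau)
  lambdas <- pmin(1, pmax(0, spec$lambda[g, ] + delta))
  names(lambdas) <- c("1", "3", "5")
  epsilon <- stats::rnorm(1, 0, spec$noiseSd)
  # subject motion level: lognormal around the group mean FD with ~40%
  # between-subject coefficient of variation, shared by all three runs
  muMotion <- stats::rlnorm(1, log(spec$motionMu[[g]]) - 0.08, 0.4)

  addCommonComponents <- function(x, Ttot, motion) {
    x <- x + simulateDrift(Ttot, R, spec$driftSd)
    fd <- c(0, framewiseDisplacement(motion))
    x <- x + fd %*% t(stats::rnorm(R)) * spec$motionArtifactScale
    nuis <- simulateNuisance(Ttot)
    x <- x + nuis %*% matrix(stats::rnorm(2 * R, 0, spec$nuisanceLeak), 2, R)
    list(data = x, nuisance = nuis)
  }

  # rest run
  Trest <- spec$nRestVolumes + spec$nTrim
  restRaw <- mvnRows(Trest, cache$restChol[[g]])
  restMotion <- simulateMotion(Trest, muMotion)
  cc <- addCommonComponents(restRaw, Trest, restMotion)
  colnames(cc$data) <- roiNames(scheme)
  rest <- fastTs(cc$data, meta$subject, "rest", tr)
  nuisance <- list(rest = cc$nuisance)
  motion <- list(rest = restMotion)

  # load-specific cholesky factors for this subject
  loadChol <- lapply(lambdas, function(l)
    chol(mixCovariance(cache$sigmaRest[[g]], cache$perm, l)))

  taskRuns <- list(); events <- list()
  for (run in 1:2) {
    blockOrder <- sample(c(1L, 3L, 5L))
    outcomes <- stats::setNames(lapply(seq_along(blockOrder), function(i) {
      li <- match(blockOrder[i], c(1L, 3L, 5L))
      drawTrialOutcomes(spec, g, lambdas[[as.character(blockOrder[i])]], li, epsilon)
    }), as.character(blockOrder))
    ev <- simulateRunEvents(blockOrder, outcomes)
    runEnd <- max(ev$onset + ev$duration)
    Tret <- as.integer(ceiling(runEnd / tr))
    Ttot <- Tret + spec$nTrim

    # per-volume covariance state by the same midpoint rule used downstream
    mid <- (seq_len(Tret) - 0.5) * tr
    state <- rep("rest", Tret)
    for (load in c(1L, 3L, 5L)) {
      iv <- loadInterval(ev, load)
      state[mid >= iv[1] & mid <= iv[2]] <- as.character(load)
    }
    x <- matrix(0, Ttot, R)
    x[seq_len(spec$nTrim), ] <- mvnRows(spec$nTrim, cache$restChol[[g]])
    r <- rle(state)
    pos <- cumsum(c(0, r$lengths))
    for (i in seq_along(r$values)) {
      rows <- spec$nTrim + (pos[i] + 1):pos[i + 1]
      U <- if (r$values[i] == "rest") cache$restChol[[g]] else
        loadChol[[r$values[i]]]
      x[rows, ] <- mvnRows(length(rows), U)
    }

    # task-evoked component on the retained grid
    dm <- buildTaskRegressors(ev, Tret, tr, derivatives = FALSE,
                              classes = c("encoding", "maintenance", "probe",
                                          "response", "iti"))
    evoked <- dm$X %*% matrix(stats::rnorm(ncol(dm$X) * R), ncol(dm$X), R) *
      spec$activationGain
    x[spec$nTrim + seq_len(Tret), ] <- x[spec$nTrim + seq_len(Tret), ] + evoked

    runMotion <- simulateMotion(Ttot, muMotion)
    cc <- addCommonComponents(x, Ttot, runMotion)
    colnames(cc$data) <- roiNames(scheme)
    lab <- paste0("task_run", run)
    taskRuns[[run]] <- fastTs(cc$data, meta$subject, lab, tr)
    events[[run]] <- ev
    motion[[lab]] <- runMotion
    nuisance[[lab]] <- cc$nuisance
  }

  new("SubjectRecord", subject = meta$subject, ageGroup = g, sex = meta$sex,
      scanner = meta$scanner, age = meta$age, rest = rest,
      taskRuns = taskRuns, events = events, motion = motion,
      nuisance = nuisance,
      truth = list(lambda = lambdas, delta = delta, epsilon = epsilon,
                   pAccuracy = stats::plogis(
                     spec$a0 - spec$a1 * lambdas - spec$loadPenalty -
                       spec$groupPenalty[[g]] + epsilon)))
}

# Shared precomputations for a cohort draw.
cohortCache <- function(spec) {
  sigmaRest <- lapply(c(young = "young", old = "old"), function(g)
    buildNetworkCovariance(spec$scheme, spec$w[[g]], spec$b[[g]]))
  list(sigmaRest = sigmaRest,
       restChol = lapply(sigmaRest, chol),
       perm = altPermutation(spec))
}

#' Simulate a full two-group cohort
#'
#' @param spec a [cohortSpec()].
#' @param seed integer global seed (defaults to `spec$seed`); per-subject
#'   seeds are derived with [deriveSeed()] so subjects are independent and
#'   reproducible in isolation.
#' @return a [Cohort-class].
#' @export
simulateCohort <- function(spec, seed = spec$seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  cache <- cohortCache(spec)
  metas <- list()
  set.seed(deriveSeed(seed, "demographics"))
  for (i in seq_len(spec$nYoung))
    metas[[length(metas) + 1L]] <- list(
      subject = sprintf("Y%03d", i), ageGroup = "young",
      sex = sample(c("M", "F"), 1), scanner = "pre",
      age = min(35, max(18, stats::rnorm(1, 24.8, 4.2))))
  for (i in seq_len(spec$nOld))
    metas[[length(metas) + 1L]] <- list(
      subject = sprintf("O%03d", i), ageGroup = "old",
      sex = sample(c("M", "F"), 1),
      scanner = sample(c("pre", "post"), 1, prob = c(21, 13)),
      age = min(85, max(55, stats::rnorm(1, 65.1, 6.6))))
  subjects <- lapply(metas, function(m)
    simulateSubject(spec, m, deriveSeed(seed, "subject", m$subject), cache))
  participants <- do.call(rbind, lapply(metas, function(m)
    data.frame(subject = m$subject, age_group = m$ageGroup, sex = m$sex,
               scanner = m$scanner, age = m$age, stringsAsFactors = FALSE)))
  new("Cohort", subjects = subjects, participants = participants)
}

#' Write a cohort to disk in the package's exchange formats
#'
#' One directory per subject with time-series, events, and motion TSVs, plus
#' `participants.tsv`, `parcellation.tsv`, and a ground-truth table
#' (subject, load, lambda, true accuracy probability).
#'
#' @param cohort a [Cohort-class].
#' @param spec the generating [cohortSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeCohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeParcellation(spec$scheme, file.path(dir, "parcellation.tsv"))
  utils::write.table(participants(cohort), file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list()
  for (s in subjects(cohort)) {
    sd <- file.path(dir, s@subject)
    dir.create(sd, showWarnings = FALSE)
    writeTimeSeries(s@rest, file.path(sd, "rest_timeseries.tsv"))
    writeMotion(s@motion$rest, file.path(sd, "rest_motion.tsv"))
    for (run in 1:2) {
      writeTimeSeries(s@taskRuns[[run]],
                      file.path(sd, sprintf("task_run%d_timeseries.tsv", run)))
      writeEvents(s@events[[run]],
                  file.path(sd, sprintf("task_run%d_events.tsv", run)))
      writeMotion(s@motion[[paste0("task_run", run)]],
                  file.path(sd, sprintf("task_run%d_motion.tsv", run)))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      subject = s@subject, load = c(1L, 3L, 5L),
      lambda = unname(s@truth$lambda), p_accuracy = unname(s@truth$pAccuracy),
      stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, truth), file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
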