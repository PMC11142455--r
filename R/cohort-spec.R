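#' @include parcellation.R
NULL

#' Specification of a synthetic two-group cohort
#'
#' Collects every generative parameter of the synthetic cohort: group-wise
#' network segregation (within- vs between-network correlation), group- and
#' load-dependent reconfiguration mixing weights, subject heterogeneity,
#' task-evoked activation, motion, and the behavior model that couples
#' accuracy to reconfiguration. Defaults encode the structure the analysis
#' is built to detect: older adults have lower segregation (`w` down, `b`
#' up), reconfigure more at every load (`lambda` higher), and load increases
#' reconfiguration in both groups; accuracy decreases with the subject's
#' reconfiguration weight (`a1 > 0`).
#'
#' @param nYoung,nOld subjects per group.
#' @param R ROI count (430 full scheme; reducible, see [makeParcellation()]).
#' @param scheme optional [ParcellationScheme-class]; built from `R` if NULL.
#' @param w named numeric, within-network correlation per group.
#' @param b named numeric, between-network correlation per group.
#' @param lambda 2 x 3 matrix (rows young/old, cols loads 1/3/5) of
#'   reconfiguration mixing weights in `[0, 1]`, non-decreasing across load,
#'   old >= young elementwise.
#' @param tau SD of the per-subject offset added to the group lambdas.
#' @param activationGain amplitude of the HRF-convolved task-evoked
#'   component, in units of the unit-variance BOLD signal.
#' @param motionMu named numeric, group mean framewise displacement (mm).
#' @param motionArtifactScale amplitude of the rank-one FD-locked artifact.
#' @param driftSd amplitude of the per-ROI quadratic drift.
#' @param nuisanceLeak coupling of the CSF/WM nuisance series into ROI data.
#' @param a0,a1,noiseSd behavior model: per-trial accuracy is Bernoulli with
#'   `p = plogis(a0 - a1 * lambda - loadPenalty - groupPenalty + eps)`,
#'   `eps ~ N(0, noiseSd)` per subject; `a1 > 0` plants the positive
#'   similarity-accuracy association.
#' @param loadPenalty length-3 numeric, per-load difficulty on the logit.
#' @param groupPenalty named numeric, extra difficulty for each group.
#' @param rtBase,rtLoad,rtLambda,rtSdlog lognormal response-time model:
#'   `log RT ~ N(log(rtBase) + rtLoad * loadIndex + rtLambda * lambda,
#'   rtSdlog^2)`, truncated at the 1.95 s response window.
#' @param trSeconds sampling interval (s).
#' @param nRestVolumes retained rest volumes (first `nTrim` extra volumes are
#'   prepended and later discarded by conditioning).
#' @param nTrim leading volumes to discard.
#' @param seed integer seed used for the fixed topology permutation and as
#'   the default cohort seed.
#' @return a validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(nYoung = 40L, nOld = 40L, R = 430L, scheme = NULL,
                       w = c(young = 0.35, old = 0.25),
                       b = c(young = 0.05, old = 0.12),
                       lambda = rbind(young = c(0.10, 0.18, 0.26),
                                      old   = c(0.28, 0.36, 0.44)),
                       tau = 0.08,
                       activationGain = 1.0,
                       motionMu = c(young = 0.05, old = 0.07),
                       motionArtifactScale = 5,
                       driftSd = 0.5,
                       nuisanceLeak = 0.3,
                       a0 = 3.2, a1 = 6, noiseSd = 0.25,
                       loadPenalty = c(0, 0.4, 0.8),
                       groupPenalty = c(young = 0, old = 0),
                       rtBase = 0.6, rtLoad = 0.08, rtLambda = 0.3,
                       rtSdlog = 0.25,
                       trSeconds = 2, nRestVolumes = 235L, nTrim = 5L,
                       seed = 20240701L) {
  if (is.null(scheme)) scheme <- makeParcellation(R)
  R <- nRoi(scheme)
  colnames(lambda) <- NULL
  stopifnot(all(c("young", "old") %in% names(w)),
            all(c("young", "old") %in% names(b)),
            identical(rownames(lambda), c("young", "old")),
            ncol(lambda) == 3)
  if (any(w <= -1 | w >= 1) || any(b <= -1 | b >= 1))
    stop("w and b must lie strictly in (-1, 1)")
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  if (any(diff(lambda["young", ]) < 0) || any(diff(lambda["old", ]) < 0))
    stop("lambda must be non-decreasing in load")
  if (any(lambda["old", ] < lambda["young", ]))
    stop("lambda for old must be >= lambda for young at every load")
  if (a1 < 0) stop("a1 must be non-negative")
  spec <- list(nYoung = as.integer(nYoung), nOld = as.integer(nOld),
               R = R, scheme = scheme, w = w, b = b, lambda = lambda,
               tau = tau, activationGain = activationGain,
               motionMu = motionMu,
               motionArtifactScale = motionArtifactScale,
               driftSd = driftSd, nuisanceLeak = nuisanceLeak,
               a0 = a0, a1 = a1, noiseSd = noiseSd,
               loadPenalty = loadPenalty, groupPenalty = groupPenalty,
               rtBase = rtBase, rtLoad = rtLoad, rtLambda = rtLambda,
               rtSdlog = rtSdlog,
               trSeconds = trSeconds, nRestVolumes = as.integer(nRestVolumes),
               nTrim = as.integer(nTrim), seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  # positive definiteness of both group covariances, checked up front
  for (g in c("young", "old")) buildNetworkCovariance(scheme, w[[g]], b[[g]])
  spec
}

#' @export
print.CohortSpec <- function(x, ...) {
  cat(sprintf("CohortSpec: %d young + %d old, %d ROIs\n", x$nYoung, x$nOld, x$R))
  cat(sprintf("  w: young %.2f old %.2f | b: young %.2f old %.2f\n",
              x$w[["young"]], x$w[["old"]], x$b[["young"]], x$b[["old"]]))
  cat("  lambda (loads 1/3/5):\n")
  print(x$lambda)
  invisible(x)
}
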