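#' @include pipeline.R
NULL

# Full per-subject chain: condition, connect, global rest-task similarity.
# Returns one row per load pair plus FD summaries.
subjectGlobalSimilarity <- function(s, scheme, loads = c(1L, 3L, 5L)) {
  cond <- conditionSubject(s, loads = loads)
  fcs <- fcPerCondition(cond, scheme)
  sets <- edgeSets(scheme)
  z <- vapply(paste0("dot", loads), function(nm)
    fcSimilarity(fcs$rest, fcs[[nm]], sets$global)$z, numeric(1))
  list(z = z, motion = cond$motion)
}

#' Replicate study: recovery of the planted age-group effect
#'
#' Simulates replicate cohorts under the planted group difference (and,
#' separately, under a true null with identical generative parameters for
#' both groups), runs the full conditioning/connectivity/similarity chain,
#' fits the group-by-load model on global rest-task similarity, and records
#' the age-group term's p value per replicate.
#'
#' @param nReplicates replicate cohorts per arm.
#' @param spec planted-difference [cohortSpec()] (defaults: 40 + 40
#'   subjects, 60 ROIs).
#' @param nullSpec true-null spec; by default the planted spec with the
#'   young group's segregation and reconfiguration parameters copied to the
#'   old group.
#' @param seed integer seed.
#' @param arms which arms to run.
#' @return data.frame: arm, replicate, p_age (and F_age).
#' @export
groupEffectStudy <- function(nReplicates = 50L,
                             spec = cohortSpec(nYoung = 40L, nOld = 40L,
                                               R = 60L),
                             nullSpec = NULL, seed = 1L,
                             arms = c("planted", "null")) {
  if (is.null(nullSpec)) {
    # a true null for the age-group term: every group-dependent generative
    # parameter (reconfiguration, segregation, motion level) equalized
    nullSpec <- spec
    nullSpec$w["old"] <- nullSpec$w[["young"]]
    nullSpec$b["old"] <- nullSpec$b[["young"]]
    nullSpec$lambda["old", ] <- nullSpec$lambda["young", ]
    nullSpec$motionMu["old"] <- nullSpec$motionMu[["young"]]
  }
  out <- list()
  for (arm in arms) {
    sp <- if (arm == "planted") spec else nullSpec
    for (r in seq_len(nReplicates)) {
      coh <- simulateCohort(sp, deriveSeed(seed, "group_effect", arm, r))
      simRows <- list(); motRows <- list()
      for (s in subjects(coh)) {
        res <- subjectGlobalSimilarity(s, sp$scheme)
        simRows[[s@subject]] <- data.frame(
          subject = s@subject, comparison = "rest_task",
          pair = paste0("dot", c(1, 3, 5), "-rest"), scope = "global",
          z = unname(res$z), stringsAsFactors = FALSE)
        motRows[[s@subject]] <- res$motion
      }
      covTab <- covariateTable(coh, do.call(rbind, motRows))
      rows <- similarityModelRows(do.call(rbind, simRows), covTab)
      fit <- suppressWarnings(fitGroupLoadModel(rows, "paper_ols"))
      i <- match("age_group", fit$terms$term)
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, replicate = r, F_age = fit$terms$F[i],
        p_age = fit$terms$p[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Replicate study: recovery of the planted brain-behavior coupling
#'
#' Simulates single-group replicate cohorts, computes each subject's global
#' rest-task similarity at the intermediate load and task accuracy at that
#' load, and the covariate-adjusted partial Spearman correlation between
#' them (age, sex, task FD, rest FD as covariates). For the null comparison
#' the same similarity values are paired with behavior regenerated under a
#' decoupled model (`a1 = 0`), so calibration is assessed on a true null.
#'
#' @param nReplicates replicate cohorts.
#' @param n subjects per replicate (single young group).
#' @param R ROI count.
#' @param seed integer seed.
#' @return data.frame: replicate, rho, p, rho_null, p_null, n.
#' @export
couplingStudy <- function(nReplicates = 100L, n = 100L, R = 60L, seed = 1L) {
  spec <- cohortSpec(nYoung = n, nOld = 0L, R = R)
  nullSpec <- spec; nullSpec$a1 <- 0
  out <- list()
  for (r in seq_len(nReplicates)) {
    coh <- simulateCohort(spec, deriveSeed(seed, "coupling", r))
    z <- numeric(0); acc <- numeric(0); accNull <- numeric(0)
    motRows <- list()
    for (s in subjects(coh)) {
      res <- subjectGlobalSimilarity(s, spec$scheme, loads = 3L)
      z[s@subject] <- res$z[["dot3"]]
      beh <- scoreBehavior(s@events, s@subject)
      acc[s@subject] <- beh$accuracy[beh$load == 3L]
      bnull <- simulateBehavior(nullSpec, s@truth$lambda, s@ageGroup,
                                deriveSeed(seed, "null_behavior", r,
                                           s@subject))
      accNull[s@subject] <- mean(bnull$correct[bnull$load == 3L])
      motRows[[s@subject]] <- res$motion
    }
    covTab <- covariateTable(coh, do.call(rbind, motRows))
    C <- data.frame(age = covTab$age, sex = as.integer(factor(covTab$sex)),
                    task_fd = covTab$task_fd, rest_fd = covTab$rest_fd)
    ps <- partialSpearman(z, acc[names(z)], C)
    psNull <- partialSpearman(z, accNull[names(z)], C)
    out[[r]] <- data.frame(replicate = r, rho = ps$rho, p = ps$p,
                           rho_null = psNull$rho, p_null = psNull$p,
                           n = ps$n)
  }
  do.call(rbind, out)
}

#' Calibration studies for the partial Spearman machinery
#'
#' `spearmanCalibrationStudy()` draws independent x, y and covariates and
#' records the rejection rate at `alpha` (type-I error).
#' `bootstrapCalibrationStudy()` draws replicate bivariate-normal datasets
#' with correlation `rho`, and compares the mean bootstrap SE against the
#' empirical SD of the partial Spearman estimate over replicates.
#'
#' @param nSim null simulations.
#' @param n sample size per simulation.
#' @param k number of (irrelevant) covariates.
#' @param alpha test level.
#' @param seed integer seed.
#' @return `spearmanCalibrationStudy`: list with `rate` and `nSim`;
#'   `bootstrapCalibrationStudy`: list with `meanBootSe`, `empiricalSd`,
#'   `ratio`, `nReplicates`.
#' @export
spearmanCalibrationStudy <- function(nSim = 2000L, n = 60L, k = 3L,
                                     alpha = 0.05, seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(deriveSeed(seed, "spearman_calibration"))
  rej <- logical(nSim)
  for (i in seq_len(nSim)) {
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    C <- matrix(stats::rnorm(n * k), n, k)
    rej[i] <- partialSpearman(x, y, C)$p < alpha
  }
  list(rate = mean(rej), nSim = nSim)
}

#' @rdname spearmanCalibrationStudy
#' @param nReplicates replicate datasets.
#' @param rho true correlation of the bivariate normal.
#' @param iterations bootstrap resamples per dataset.
#' @export
bootstrapCalibrationStudy <- function(nReplicates = 200L, n = 100L,
                                      rho = 0.3, iterations = 1000L,
                                      seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(deriveSeed(seed, "bootstrap_calibration"))
  rhos <- numeric(nReplicates); ses <- numeric(nReplicates)
  for (i in seq_len(nReplicates)) {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    rhos[i] <- partialSpearman(x, y)$rho
    ses[i] <- as.numeric(bootstrapSE(x, y, iterations = iterations,
                                     seed = deriveSeed(seed, "boot", i)))
  }
  list(meanBootSe = mean(ses), empiricalSd = stats::sd(rhos),
       ratio = mean(ses) / stats::sd(rhos), nReplicates = nReplicates)
}
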