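#' @include simulate.R connectivity.R reconfiguration.R behavior.R stats.R
NULL

#' Pipeline configuration
#'
#' Bundles the cohort, signal and stats configurations with the analysis
#' toggles mirroring the validation reruns: within-load stability,
#' averaged-FC tables, motion-matched young subset, and response time as an
#' additional association covariate. Every stochastic stage derives its seed
#' from `seed` and the stage name via [deriveSeed()].
#'
#' @param spec a [cohortSpec()].
#' @param signal a [signalConfig()].
#' @param stats a [statsConfig()].
#' @param withinLoad compute within-load run-to-run similarity?
#' @param averagedFc compute averaged-FC tables?
#' @param motionMatched rerun group models on a motion-matched young subset?
#' @param rtCovariate add mean RT at the paired load as an association
#'   covariate?
#' @param applyFilters apply the cohort inclusion filters before analysis?
#' @param bootstrap compute bootstrap SEs in the association battery?
#' @param seed global seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(spec = cohortSpec(), signal = signalConfig(),
                           stats = statsConfig(), withinLoad = FALSE,
                           averagedFc = FALSE, motionMatched = FALSE,
                           rtCovariate = FALSE, applyFilters = TRUE,
                           bootstrap = FALSE, seed = 1L) {
  cfg <- list(spec = spec, signal = signal, stats = stats,
              withinLoad = withinLoad, averagedFc = averagedFc,
              motionMatched = motionMatched, rtCovariate = rtCovariate,
              applyFilters = applyFilters, bootstrap = bootstrap,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Per-subject covariate table
#'
#' @param cohort a [Cohort-class].
#' @param motionSummary per subject x run FD summaries (from
#'   [conditionSubject()] `$motion`, row-bound over subjects).
#' @return data.frame: subject, age_group, age, sex, scanner, rest_fd,
#'   task_fd.
#' @export
covariateTable <- function(cohort, motionSummary) {
  pt <- participants(cohort)
  restFd <- motionSummary[motionSummary$run == "rest", ]
  taskFd <- stats::aggregate(mean_fd ~ subject,
                             motionSummary[motionSummary$run != "rest", ],
                             mean)
  pt$rest_fd <- restFd$mean_fd[match(pt$subject, restFd$subject)]
  pt$task_fd <- taskFd$mean_fd[match(pt$subject, taskFd$subject)]
  pt
}

#' Long model table for a behavioral outcome
#'
#' @param behavior [scoreBehavior()] rows over subjects.
#' @param covTable a [covariateTable()].
#' @param outcome `"accuracy"` or `"mean_rt_correct"`.
#' @return data.frame ready for [fitGroupLoadModel()] (load = task load).
#' @export
behaviorModelRows <- function(behavior, covTable, outcome = "accuracy") {
  i <- match(behavior$subject, covTable$subject)
  data.frame(y = behavior[[outcome]], age_group = covTable$age_group[i],
             load = paste0("dot", behavior$load), sex = covTable$sex[i],
             task_motion = covTable$task_fd[i],
             rest_motion = covTable$rest_fd[i],
             scanner = covTable$scanner[i], subject = behavior$subject,
             stringsAsFactors = FALSE)
}

#' Long model table for FC similarity
#'
#' `load` is the pair label (load or load-pair categorical). For stepwise
#' pairs between two task loads, rest motion is set to zero exactly.
#'
#' @param similarity long similarity records (one comparison type).
#' @param covTable a [covariateTable()].
#' @param scope scope to model (default `"global"`).
#' @return data.frame ready for [fitGroupLoadModel()].
#' @export
similarityModelRows <- function(similarity, covTable, scope = "global") {
  sim <- similarity[similarity$scope == scope & !is.na(similarity$z), ]
  i <- match(sim$subject, covTable$subject)
  restMotion <- ifelse(grepl("rest", sim$pair), covTable$rest_fd[i], 0)
  data.frame(y = sim$z, age_group = covTable$age_group[i], load = sim$pair,
             sex = covTable$sex[i], task_motion = covTable$task_fd[i],
             rest_motion = restMotion, scanner = covTable$scanner[i],
             subject = sim$subject, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate -> condition -> connect -> similarity -> behavior -> stats, with
#' structured outputs written to `outDir` (long-format TSVs, a manifest, and
#' report tables). Rerunning with the same config and seed reproduces every
#' output.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory, created if needed; NULL skips writing.
#' @param cohort optionally, a pre-simulated [Cohort-class] (e.g. read from
#'   disk); simulated from `config$spec` when NULL.
#' @return list with cohort, similarity, behavior, covariates, anova fits,
#'   post hocs, associations, and any toggled extras.
#' @export
runPipeline <- function(config, outDir = NULL, cohort = NULL) {
  spec <- config$spec
  scheme <- spec$scheme
  if (is.null(cohort))
    cohort <- simulateCohort(spec, deriveSeed(config$seed, "simulate"))

  simRows <- list(); behRows <- list(); motRows <- list()
  avgRows <- list(); withinRows <- list()
  for (s in subjects(cohort)) {
    cond <- conditionSubject(s, config$signal, perRun = config$withinLoad)
    fcs <- fcPerCondition(cond, scheme, withinLoad = config$withinLoad)
    simRows[[s@subject]] <- rbind(
      restTaskSimilarities(fcs, scheme, s@subject),
      stepwiseSimilarities(fcs, scheme, s@subject))
    if (config$withinLoad)
      withinRows[[s@subject]] <- withinLoadSimilarity(fcs, scheme, s@subject)
    if (config$averagedFc)
      avgRows[[s@subject]] <- do.call(rbind, lapply(
        paste0("dot", c(1, 3, 5)), function(nm)
          cbind(subject = s@subject, averagedFC(fcs[[nm]], scheme))))
    behRows[[s@subject]] <- scoreBehavior(s@events, s@subject)
    motRows[[s@subject]] <- cond$motion
  }
  similarity <- do.call(rbind, simRows)
  behavior <- do.call(rbind, behRows)
  motionSummary <- do.call(rbind, motRows)
  covTable <- covariateTable(cohort, motionSummary)

  exclusions <- NULL
  if (config$applyFilters) {
    flt <- applyInclusionFilters(behavior, motionSummary)
    exclusions <- flt$exclusions
    keep <- flt$included
    similarity <- similarity[similarity$subject %in% keep, ]
    behavior <- behavior[behavior$subject %in% keep, ]
    covTable <- covTable[covTable$subject %in% keep, ]
  }

  fits <- list(
    accuracy = fitGroupLoadModel(
      behaviorModelRows(behavior, covTable, "accuracy"), config$stats$dfMode),
    response_time = fitGroupLoadModel(
      behaviorModelRows(behavior, covTable, "mean_rt_correct"),
      config$stats$dfMode),
    rest_task_global = fitGroupLoadModel(
      similarityModelRows(similarity[similarity$comparison == "rest_task", ],
                          covTable), config$stats$dfMode),
    stepwise_global = fitGroupLoadModel(
      similarityModelRows(similarity[similarity$comparison == "stepwise", ],
                          covTable), config$stats$dfMode))
  posthocs <- lapply(fits, tukeyPosthoc)

  # per-network main-effect p values with the 9-network Bonferroni gate
  networkTests <- list()
  for (comp in c("rest_task", "stepwise")) for (side in c("intra", "inter")) {
    ps <- list()
    for (n in NETWORKS) {
      rows <- similarityModelRows(
        similarity[similarity$comparison == comp, ], covTable,
        scope = paste0(side, ":", n))
      ps[[n]] <- tryCatch({
        f <- fitGroupLoadModel(rows, config$stats$dfMode)
        f$terms[match(c("age_group", "load", "age_group:load"),
                      f$terms$term), "p"]
      }, error = function(e) rep(NA_real_, 3))
    }
    pm <- do.call(rbind, ps)
    colnames(pm) <- c("age_group", "load", "interaction")
    sig <- apply(pm, 2, function(p) bonferroniGate(p, config$stats))
    networkTests[[paste(comp, side, sep = "_")]] <-
      data.frame(network = NETWORKS, pm, significant_age = sig[, 1],
                 significant_load = sig[, 2],
                 significant_interaction = sig[, 3], row.names = NULL)
  }

  assocCov <- covTable
  associations <- associationBattery(similarity, behavior, assocCov,
                                     config$stats,
                                     bootstrap = config$bootstrap)

  results <- list(cohort = cohort, config = config, similarity = similarity,
                  behavior = behavior, covariates = covTable,
                  exclusions = exclusions, fits = fits, posthocs = posthocs,
                  networkTests = networkTests, associations = associations)

  if (config$withinLoad) {
    results$withinLoad <- do.call(rbind, withinRows)
    wrows <- similarityModelRows(results$withinLoad, covTable)
    results$fits$within_load_global <-
      fitGroupLoadModel(wrows, config$stats$dfMode)
  }
  if (config$averagedFc) results$averagedFc <- do.call(rbind, avgRows)
  if (config$motionMatched) {
    keep <- motionMatchedSubset(covTable)
    results$motionMatched <- list(
      subjects = keep,
      rest_task_global = fitGroupLoadModel(
        similarityModelRows(
          similarity[similarity$comparison == "rest_task" &
                       similarity$subject %in% keep, ],
          covTable[covTable$subject %in% keep, ]), config$stats$dfMode))
  }

  if (!is.null(outDir)) writePipelineOutputs(results, outDir)
  results
}

writePipelineOutputs <- function(results, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(results$similarity, "similarity.tsv")
  wt(results$behavior, "behavior.tsv")
  wt(results$covariates, "covariates.tsv")
  if (!is.null(results$exclusions)) wt(results$exclusions, "exclusions.tsv")
  anova <- do.call(rbind, lapply(names(results$fits), function(nm)
    cbind(outcome = nm, results$fits[[nm]]$terms)))
  wt(anova, "anova_terms.tsv")
  posthoc <- do.call(rbind, lapply(names(results$posthocs), function(nm)
    cbind(outcome = nm, results$posthocs[[nm]])))
  wt(posthoc, "posthoc.tsv")
  wt(results$associations, "associations.tsv")
  for (nm in names(results$networkTests))
    wt(results$networkTests[[nm]], paste0("network_", nm, ".tsv"))
  if (!is.null(results$averagedFc)) wt(results$averagedFc, "averaged_fc.tsv")
  if (!is.null(results$withinLoad)) wt(results$withinLoad, "within_load.tsv")
  nFc <- 4L + if (results$config$withinLoad) 6L else 0L
  manifest <- list(
    seed = results$config$seed,
    n_subjects = length(subjects(results$cohort)),
    n_included = length(unique(results$similarity$subject)),
    fc_matrices_per_subject = nFc,
    similarity_rows = nrow(results$similarity),
    behavior_rows = nrow(results$behavior),
    association_rows = nrow(results$associations),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Report tables (and optional figures) from a pipeline run
#'
#' Group-by-load mean and standard-error tables for behavior and global
#' similarity, the three rest-task and three stepwise pair menus, and the
#' association table with explicit "none significant" rows. If ggplot2 is
#' installed, bar figures are written alongside the tables.
#'
#' @param results a [runPipeline()] result.
#' @param outDir directory for the report files.
#' @return list of report tables, invisibly.
#' @export
writeReport <- function(results, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  cov <- results$covariates
  beh <- results$behavior
  beh$age_group <- cov$age_group[match(beh$subject, cov$subject)]
  behTab <- do.call(rbind, lapply(split(beh, list(beh$age_group, beh$load)),
    function(d) data.frame(age_group = d$age_group[1], load = d$load[1],
                           mean_accuracy = mean(d$accuracy),
                           se_accuracy = se(d$accuracy),
                           mean_rt = mean(d$mean_rt_correct, na.rm = TRUE),
                           se_rt = se(d$mean_rt_correct[!is.na(d$mean_rt_correct)]))))
  sim <- results$similarity
  sim$age_group <- cov$age_group[match(sim$subject, cov$subject)]
  simG <- sim[sim$scope == "global" & !is.na(sim$z), ]
  simTab <- do.call(rbind, lapply(
    split(simG, list(simG$age_group, simG$comparison, simG$pair), drop = TRUE),
    function(d) data.frame(age_group = d$age_group[1],
                           comparison = d$comparison[1], pair = d$pair[1],
                           mean_z = mean(d$z), se_z = se(d$z))))
  assoc <- results$associations
  sigAssoc <- assoc[assoc$significant, , drop = FALSE]
  if (nrow(sigAssoc) == 0)
    sigAssoc <- data.frame(group = "none significant", comparison = NA,
                           pair = NA, scope = NA, outcome = NA, n = NA,
                           rho = NA, p = NA, gate = NA, significant = FALSE,
                           bootstrap_se = NA)
  wt <- function(df, name) utils::write.table(
    df, file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(behTab, "report_behavior.tsv")
  wt(simTab, "report_similarity.tsv")
  wt(sigAssoc, "report_significant_associations.tsv")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    g <- ggplot2::ggplot(behTab, ggplot2::aes(
      x = factor(load), y = mean_accuracy, fill = age_group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = mean_accuracy - se_accuracy,
        ymax = mean_accuracy + se_accuracy),
        position = ggplot2::position_dodge(0.9), width = 0.3) +
      ggplot2::labs(x = "memory load (dots)", y = "accuracy")
    ggplot2::ggsave(file.path(outDir, "behavior.pdf"), g, width = 5,
                    height = 4)
    g2 <- ggplot2::ggplot(simTab, ggplot2::aes(
      x = pair, y = mean_z, fill = age_group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_z - se_z,
                                          ymax = mean_z + se_z),
        position = ggplot2::position_dodge(0.9), width = 0.3) +
      ggplot2::facet_wrap(~comparison, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "FC similarity (Fisher z)")
    ggplot2::ggsave(file.path(outDir, "similarity.pdf"), g2, width = 7,
                    height = 4)
  }
  invisible(list(behavior = behTab, similarity = simTab,
                 significant = sigAssoc))
}
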