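#' @include utils.R
NULL

#' Statistical configuration
#'
#' @param nNetworks networks in the Bonferroni family (9).
#' @param familyAlpha family-wise level (0.05); the per-network gate is
#'   `familyAlpha / nNetworks` (about 0.006).
#' @param bootstrapIterations bootstrap resamples for association SEs.
#' @param seed integer seed for the bootstrap.
#' @param dfMode `"paper_ols"` (fixed-effects least squares, denominator df
#'   = N - number of estimable coefficients) or `"lmm_satterthwaite"`
#'   (random subject intercept, Satterthwaite df).
#' @return list of class `StatsConfig`.
#' @export
statsConfig <- function(nNetworks = 9L, familyAlpha = 0.05,
                        bootstrapIterations = 10000L, seed = 1L,
                        dfMode = c("paper_ols", "lmm_satterthwaite")) {
  cfg <- list(nNetworks = as.integer(nNetworks), familyAlpha = familyAlpha,
              perNetworkAlpha = familyAlpha / nNetworks,
              bootstrapIterations = as.integer(bootstrapIterations),
              seed = as.integer(seed), dfMode = match.arg(dfMode))
  class(cfg) <- "StatsConfig"
  cfg
}

GROUP_LOAD_TERMS <- c("age_group", "load", "sex", "task_motion",
                      "rest_motion", "scanner", "age_group:load")

#' Group-by-load model with covariates
#'
#' Fits `y ~ age_group * load + sex + task_motion + rest_motion + scanner`
#' on a long table (one row per subject per load or load-pair) and reports
#' an F test for every term. Under `paper_ols` the fit is fixed-effects
#' least squares; each term's F is the extra-sum-of-squares F of dropping
#' that term's columns from the full model, with denominator df
#' `N - (number of estimable coefficients)`. Under `lmm_satterthwaite` a
#' random subject intercept is added and Satterthwaite-approximated
#' denominator df are used. Covariate factors that are constant in the data
#' are dropped with a warning; a scanner assignment confounded within one
#' group crossing is warned about but retained.
#'
#' @param rows data.frame with columns y, age_group, load, sex,
#'   task_motion, rest_motion, scanner, subject.
#' @param dfMode see [statsConfig()].
#' @return list of class `GroupLoadFit`: `terms` (data.frame term, F, df1,
#'   df2, p), `fit` (the underlying lm or lmerMod), `dfMode`, `dropped`.
#' @export
fitGroupLoadModel <- function(rows, dfMode = c("paper_ols", "lmm_satterthwaite")) {
  dfMode <- match.arg(dfMode)
  need <- c("y", "age_group", "load", "sex", "task_motion", "rest_motion",
            "scanner", "subject")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("model table missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- rows
  d$age_group <- factor(d$age_group, levels = intersect(c("young", "old"),
                                                        unique(d$age_group)))
  d$load <- factor(d$load)
  d$sex <- factor(d$sex)
  d$scanner <- factor(d$scanner)
  if (nlevels(d$age_group) < 2) stop("age_group must have two levels")
  if (nlevels(d$load) < 2) stop("load must have at least two levels")

  dropped <- character()
  for (cv in c("sex", "scanner")) {
    if (nlevels(d[[cv]]) < 2) {
      dropped <- c(dropped, cv)
      warning(cv, " is constant; term dropped from the model")
    }
  }
  for (cv in c("task_motion", "rest_motion")) {
    if (stats::sd(d[[cv]]) == 0) {
      dropped <- c(dropped, cv)
      warning(cv, " is constant; term dropped from the model")
    }
  }
  if (!"scanner" %in% dropped) {
    tab <- table(d$age_group, d$scanner)
    if (all(rowSums(tab > 0) == 1)) {
      # scanner exactly aliased with age_group: not estimable alongside it
      dropped <- c(dropped, "scanner")
      warning("scanner is fully confounded with age_group; term dropped")
    } else if (any(rowSums(tab > 0) == 1)) {
      warning("scanner has a single level within one age group; ",
              "term retained but partially confounded with age_group")
    }
  }
  terms <- setdiff(GROUP_LOAD_TERMS, dropped)
  rhs <- paste(c("age_group * load", setdiff(terms, c("age_group", "load",
                                                      "age_group:load"))),
               collapse = " + ")

  if (dfMode == "paper_ols") {
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design; aliased coefficient(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    mm <- stats::model.matrix(fit)
    assign <- attr(mm, "assign")
    labels <- attr(stats::terms(fit), "term.labels")
    y <- d$y
    qrFull <- qr(mm)
    rssFull <- sum(qr.resid(qrFull, y)^2)
    p <- ncol(mm)
    df2 <- nrow(d) - p
    res <- lapply(seq_along(labels), function(i) {
      cols <- which(assign == i)
      red <- mm[, -cols, drop = FALSE]
      rssRed <- sum(qr.resid(qr(red), y)^2)
      Fv <- ((rssRed - rssFull) / length(cols)) / (rssFull / df2)
      data.frame(term = labels[i], F = Fv, df1 = length(cols), df2 = df2,
                 p = stats::pf(Fv, length(cols), df2, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
  } else {
    fit <- lmerTest::lmer(
      stats::as.formula(paste("y ~", rhs, "+ (1 | subject)")), data = d)
    a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    out <- data.frame(term = rownames(a), F = a$`F value`, df1 = a$NumDF,
                      df2 = a$DenDF,
                      p = a$`Pr(>F)`, stringsAsFactors = FALSE)
  }
  structure(list(terms = out, fit = fit, dfMode = dfMode, dropped = dropped,
                 data = d),
            class = "GroupLoadFit")
}

#' @export
print.GroupLoadFit <- function(x, ...) {
  cat(sprintf("Group x load model (%s)\n", x$dfMode))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post hoc contrasts on the group-by-load cell means
#'
#' All pairwise contrasts between age_group x load cell means of a fitted
#' [fitGroupLoadModel()], with studentized-range (Tukey) adjustment over the
#' family (15 contrasts for a 2 x 3 grid).
#'
#' @param fit a `GroupLoadFit`.
#' @return data.frame: contrast, estimate, SE, df, t, p_adj.
#' @export
tukeyPosthoc <- function(fit) {
  tab <- table(fit$data$age_group, fit$data$load)
  if (any(tab == 0))
    stop("empty age_group x load cell(s): ",
         paste(which(tab == 0, arr.ind = TRUE), collapse = ", "))
  em <- emmeans::emmeans(fit$fit, ~ age_group * load, data = fit$data)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             df = pr$df, t = pr$t.ratio, p_adj = pr$p.value,
             stringsAsFactors = FALSE)
}

#' Per-network Bonferroni gate
#'
#' Flags each network's p value significant iff
#' `p < familyAlpha / nNetworks` (0.05 / 9, about 0.006, at defaults).
#'
#' @param pValues numeric vector, exactly one p per network.
#' @param config a [statsConfig()].
#' @return logical vector, same names as `pValues`.
#' @export
bonferroniGate <- function(pValues, config = statsConfig()) {
  if (length(pValues) != config$nNetworks)
    stop("expected exactly ", config$nNetworks, " p values, got ",
         length(pValues))
  pValues < config$perNetworkAlpha
}

# Rank-residualized partial Spearman correlation (internal fast path).
partialSpearmanRho <- function(x, y, covariates = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant variable after ranking; partial Spearman undefined")
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- apply(as.matrix(covariates), 2, rank)
    qrC <- qr(cbind(1, C))
    rx <- qr.resid(qrC, rx)
    ry <- qr.resid(qrC, ry)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
      stop("variable fully explained by covariates; partial Spearman undefined")
  }
  stats::cor(rx, ry)
}

#' Covariate-adjusted partial Spearman correlation
#'
#' Rank-transforms x, y and every covariate (average ranks for ties),
#' residualizes the ranked x and y on the ranked covariates plus an
#' intercept, and correlates the residuals. The p value uses
#' `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on `n - 2 - k` df, where `k`
#' is the number of covariates. With no covariates this is the ordinary
#' Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return list of class `AssociationResult`: rho, p, t, df, n, k,
#'   covariates (names), bootstrap_se (NA until [bootstrapSE()]).
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < k + 4) stop("need n >= k + 4 observations, got n = ", n)
  rho <- partialSpearmanRho(x, y, covariates)
  df <- n - 2 - k
  t <- rho * sqrt(df / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(rho = rho, p = p, t = t, df = df, n = n, k = k,
                 covariates = if (k) colnames(as.matrix(covariates)) else
                   character(),
                 bootstrap_se = NA_real_),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("partial Spearman rho = %.3f (n = %d, k = %d, p = %.3g)\n",
              x$rho, x$n, x$k, x$p))
  if (!is.na(x$bootstrap_se))
    cat(sprintf("  bootstrap SE = %.3f\n", x$bootstrap_se))
  invisible(x)
}

#' Bootstrap standard error of a partial Spearman correlation
#'
#' Resamples subjects (rows) with replacement, recomputes the partial
#' Spearman correlation per iteration, and returns the sample SD over
#' iterations. Degenerate resamples (a variable constant after resampling)
#' are skipped and counted; more than 10% skipped triggers a warning.
#'
#' @param x,y numeric vectors.
#' @param covariates optional covariate matrix.
#' @param iterations resamples (paper-scale default 10000).
#' @param seed integer seed.
#' @return numeric SE with attributes `skipped` and `iterations`.
#' @export
bootstrapSE <- function(x, y, covariates = NULL, iterations = 10000L,
                        seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n <- length(x)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rhos <- numeric(iterations)
  skipped <- 0L
  for (i in seq_len(iterations)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(
      partialSpearmanRho(x[idx], y[idx],
                         if (is.null(C)) NULL else C[idx, , drop = FALSE]),
      error = function(e) NA_real_)
    if (is.na(r)) skipped <- skipped + 1L else rhos[i - skipped] <- r
  }
  if (skipped > 0.1 * iterations)
    warning(sprintf("%d of %d bootstrap resamples were degenerate",
                    skipped, iterations))
  se <- stats::sd(rhos[seq_len(iterations - skipped)])
  attr(se, "skipped") <- skipped
  attr(se, "iterations") <- iterations
  se
}

# Behavioral load paired with a similarity pair label: the task load of the
# pair, and for stepwise pairs the higher load.
pairedLoad <- function(pair) {
  switch(pair,
         "dot1-rest" = 1L, "dot3-rest" = 3L, "dot5-rest" = 5L,
         "dot3-dot1" = 3L, "dot5-dot3" = 5L,
         stop("no behavioral pairing for pair ", pair))
}

#' Brain-behavior association battery
#'
#' Partial Spearman correlations between FC similarity and task performance
#' within each age group, using the load-matched pairing rule (a similarity pair
#' is correlated with behavior at its task load; stepwise pairs use the
#' higher load) and covariate menu: age, sex and mean task FD always; mean
#' rest FD additionally for pairs involving rest; scanner additionally for
#' the older group (when it varies). Global-scope associations are judged
#' at uncorrected alpha; network scopes at the per-network Bonferroni gate.
#'
#' @param similarity long similarity table ([restTaskSimilarities()] /
#'   [stepwiseSimilarities()] rows over subjects).
#' @param behavior behavior summaries ([scoreBehavior()] rows over subjects).
#' @param covariateTable data.frame per subject: subject, age_group, age,
#'   sex, scanner, task_fd, rest_fd.
#' @param config a [statsConfig()].
#' @param outcomes behavioral outcomes to test
#'   (`"accuracy"`, `"mean_rt_correct"`).
#' @param bootstrap compute bootstrap SEs (uses `config$bootstrapIterations`)?
#' @return data.frame: group, comparison, pair, scope, outcome, n, rho, p,
#'   gate, significant, bootstrap_se.
#' @export
associationBattery <- function(similarity, behavior, covariateTable,
                               config = statsConfig(),
                               outcomes = "accuracy", bootstrap = FALSE) {
  similarity <- similarity[!is.na(similarity$z), , drop = FALSE]
  badSubj <- setdiff(unique(similarity$subject), covariateTable$subject)
  if (length(badSubj))
    stop("subjects missing from covariate table: ",
         paste(badSubj, collapse = ", "))
  out <- list()
  cells <- unique(similarity[, c("comparison", "pair", "scope")])
  for (g in unique(covariateTable$age_group)) {
    subj <- covariateTable$subject[covariateTable$age_group == g]
    cov <- covariateTable[match(subj, covariateTable$subject), ]
    for (ci in seq_len(nrow(cells))) {
      comparison <- cells$comparison[ci]; pair <- cells$pair[ci]
      scope <- cells$scope[ci]
      if (comparison == "within_load") next
      load <- pairedLoad(pair)
      sim <- similarity[similarity$comparison == comparison &
                          similarity$pair == pair &
                          similarity$scope == scope, ]
      x <- sim$z[match(subj, sim$subject)]
      for (outc in outcomes) {
        beh <- behavior[behavior$load == load, ]
        y <- beh[[outc]][match(subj, beh$subject)]
        ok <- !is.na(x) & !is.na(y)
        C <- data.frame(age = cov$age, sex = as.integer(factor(cov$sex)),
                        task_fd = cov$task_fd)
        if (grepl("rest", pair)) C$rest_fd <- cov$rest_fd
        if (g == "old" && length(unique(cov$scanner[ok])) > 1)
          C$scanner <- as.integer(factor(cov$scanner))
        res <- tryCatch(
          partialSpearman(x[ok], y[ok], C[ok, , drop = FALSE]),
          error = function(e) NULL)
        if (is.null(res)) next
        gate <- if (scope == "global") "uncorrected" else "bonferroni9"
        alpha <- if (scope == "global") config$familyAlpha else
          config$perNetworkAlpha
        se <- if (bootstrap)
          as.numeric(bootstrapSE(x[ok], y[ok], C[ok, , drop = FALSE],
                                 config$bootstrapIterations,
                                 deriveSeed(config$seed, comparison, pair,
                                            scope, g, outc)))
        else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          group = g, comparison = comparison, pair = pair, scope = scope,
          outcome = outc, n = sum(ok), rho = res$rho, p = res$p,
          gate = gate, significant = res$p < alpha, bootstrap_se = se,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(group = character(), comparison = character(),
                      pair = character(), scope = character(),
                      outcome = character(), n = integer(), rho = numeric(),
                      p = numeric(), gate = character(),
                      significant = logical(), bootstrap_se = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Motion-matched young subset
#'
#' Greedily removes the young adult with the lowest mean FD (rest + task)
#' until two-sample t tests comparing young and old mean FD, separately for
#' rest and task, are both non-significant at `alpha`; returns the largest
#' such subset found.
#'
#' @param covariateTable as in [associationBattery()].
#' @param alpha matching threshold (two-sample t test).
#' @return character vector: the matched young subject ids plus all old ids.
#' @export
motionMatchedSubset <- function(covariateTable, alpha = 0.05) {
  young <- covariateTable[covariateTable$age_group == "young", ]
  oldg <- covariateTable[covariateTable$age_group == "old", ]
  matched <- function(y) {
    pr <- stats::t.test(y$rest_fd, oldg$rest_fd)$p.value
    pt <- stats::t.test(y$task_fd, oldg$task_fd)$p.value
    pr > alpha && pt > alpha
  }
  while (nrow(young) > 3 && !matched(young)) {
    young <- young[-which.min(young$rest_fd + young$task_fd), ]
  }
  c(young$subject, oldg$subject)
}
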