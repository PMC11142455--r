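mkModelTable <- function(nYoung = 20, nOld = 20, scanner = c("pre", "post"),
                         seed = 3, effect = 0) {
  set.seed(seed)
  n <- nYoung + nOld
  subj <- sprintf("s%03d", seq_len(n))
  d <- expand.grid(subject = subj, load = c("dot1", "dot3", "dot5"),
                   stringsAsFactors = FALSE)
  grp <- setNames(rep(c("young", "old"), c(nYoung, nOld)), subj)
  d$age_group <- grp[d$subject]
  d$sex <- setNames(sample(c("M", "F"), n, TRUE), subj)[d$subject]
  d$scanner <- setNames(sample(scanner, n, TRUE), subj)[d$subject]
  d$task_motion <- runif(nrow(d), 0.02, 0.1)
  d$rest_motion <- runif(nrow(d), 0.02, 0.1)
  d$y <- rnorm(nrow(d)) + effect * (d$age_group == "old")
  d
}

test_that("OLS denominator df is N minus the estimable coefficient count", {
  d <- mkModelTable(109, 34, scanner = "pre")  # single-scanner cohort
  expect_warning(f <- fitGroupLoadModel(d), "scanner is constant")
  # 429 rows, 9 estimable coefficients -> denominator df 420 for every term
  expect_equal(unique(f$terms$df2), 429 - 9)
  expect_equal(f$terms$df1[f$terms$term == "age_group:load"], 2L)
  expect_false("scanner" %in% f$terms$term)
  # with a varying scanner the coefficient count rises to 10
  d2 <- mkModelTable(109, 34)
  f2 <- fitGroupLoadModel(d2)
  expect_equal(unique(f2$terms$df2), 429 - 10)
  expect_true("scanner" %in% f2$terms$term)
})

test_that("every term F equals the classical extra-sum-of-squares oracle", {
  d <- mkModelTable(15, 15, seed = 9)
  f <- fitGroupLoadModel(d)
  full <- lm(y ~ age_group * load + sex + task_motion + rest_motion + scanner,
             data = d)
  oracle <- list(
    "age_group:load" = update(full, . ~ . - age_group:load),
    "task_motion" = update(full, . ~ . - task_motion),
    "sex" = update(full, . ~ . - sex))
  for (term in names(oracle)) {
    a <- anova(oracle[[term]], full)
    expect_equal(f$terms$F[f$terms$term == term], a$F[2], tolerance = 1e-10)
    expect_equal(f$terms$p[f$terms$term == term], a$`Pr(>F)`[2],
                 tolerance = 1e-10)
  }
})

test_that("mixed-model mode reports Satterthwaite df for all terms", {
  d <- mkModelTable(15, 15, seed = 10, effect = 0.8)
  f <- fitGroupLoadModel(d, "lmm_satterthwaite")
  expect_setequal(f$terms$term,
                  c("age_group", "load", "sex", "task_motion", "rest_motion",
                    "scanner", "age_group:load"))
  expect_true(all(f$terms$df2 > 0))
  expect_lt(f$terms$p[f$terms$term == "age_group"], 0.05)
})

test_that("model table validation catches structural problems", {
  d <- mkModelTable(10, 10)
  expect_error(fitGroupLoadModel(d[, -1]), "missing column")
  d2 <- d; d2$age_group <- "young"
  expect_error(fitGroupLoadModel(d2), "two levels")
  d3 <- d; d3$task_motion <- 0.05
  expect_warning(fitGroupLoadModel(d3), "task_motion is constant")
  # scanner fully confounded within a group crossing: warned, retained
  d4 <- mkModelTable(10, 10)
  d4$scanner <- ifelse(d4$age_group == "young", "pre",
                       sample(c("pre", "post"), nrow(d4), TRUE))
  expect_warning(f4 <- fitGroupLoadModel(d4), "single level within")
  expect_true("scanner" %in% f4$terms$term)
})

test_that("Tukey post hocs cover the 2x3 grid with monotone adjustment", {
  d <- mkModelTable(12, 12, seed = 12)
  f <- fitGroupLoadModel(d)
  th <- tukeyPosthoc(f)
  expect_equal(nrow(th), choose(6, 2))
  un <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(f$fit, ~ age_group * load, data = f$data),
    method = "pairwise", adjust = "none"))
  expect_true(all(th$p_adj >= un$p.value - 1e-12))
  # null data: no contrast is significant, p values near 1
  expect_gt(min(th$p_adj), 0.2)
})

test_that("the per-network Bonferroni gate splits 0.0055 from 0.0060", {
  ps <- c(0.0055, 0.0060, rep(1, 7))
  names(ps) <- NETWORKS
  flags <- bonferroniGate(ps)
  expect_true(flags[["ECN"]])    # 0.0055 < 0.05/9
  expect_false(flags[["DMN"]])   # 0.0060 > 0.05/9
  expect_false(any(bonferroniGate(rep(1, 9))))
  expect_error(bonferroniGate(rep(0.01, 5)), "exactly 9")
  expect_equal(statsConfig()$perNetworkAlpha, 0.05 / 9)
})

test_that("partial Spearman equals an explicit rank-regression oracle", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 6)
  y <- c(2, 3, 1, 7, 6, 8, 4, 5)
  cv <- c(1, 1, 2, 2, 3, 3, 4, 4)
  res <- partialSpearman(x, y, data.frame(cv = cv))
  # oracle: rank everything, solve the two small regressions explicitly
  rx <- rank(x); ry <- rank(y); rc <- rank(cv)
  px <- rx - cbind(1, rc) %*% solve(crossprod(cbind(1, rc)),
                                    crossprod(cbind(1, rc), rx))
  py <- ry - cbind(1, rc) %*% solve(crossprod(cbind(1, rc)),
                                    crossprod(cbind(1, rc), ry))
  rhoOracle <- sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  expect_equal(res$rho, rhoOracle, tolerance = 1e-12)
  expect_equal(res$df, 8 - 2 - 1)
  tOracle <- rhoOracle * sqrt(5 / (1 - rhoOracle^2))
  expect_equal(res$p, 2 * pt(-abs(tOracle), 5), tolerance = 1e-12)
})

test_that("partial Spearman degenerates to plain Spearman and absorbs covariates", {
  set.seed(31)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partialSpearman(x, y)$rho, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(partialSpearman(x, x)$rho, 1)
  # covariate equal to x absorbs all of x
  expect_lt(abs(partialSpearman(x, y, data.frame(c1 = x))$rho), 0.15)
  expect_error(partialSpearman(rep(1, 40), y), "constant")
  expect_error(partialSpearman(x[1:5], y[1:5], data.frame(a = 1:5, b = 5:1)),
               "n >= k \\+ 4")
})

test_that("partial Spearman is invariant under monotone transforms", {
  set.seed(33)
  x <- runif(30); y <- x + rnorm(30, 0, 0.4)
  cv <- data.frame(c1 = rnorm(30), c2 = runif(30))
  base <- partialSpearman(x, y, cv)$rho
  expect_equal(partialSpearman(exp(3 * x), y, cv)$rho, base,
               tolerance = 1e-12)
  expect_equal(partialSpearman(x, y^3, cv)$rho, base, tolerance = 1e-12)
  expect_equal(partialSpearman(x, y, data.frame(c1 = qlogis(pnorm(cv$c1)),
                                                c2 = cv$c2^5))$rho,
               base, tolerance = 1e-12)
})

test_that("bootstrap SE is deterministic under a seed and zero for exact ties", {
  set.seed(35)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.5)
  se1 <- bootstrapSE(x, y, iterations = 300, seed = 4)
  se2 <- bootstrapSE(x, y, iterations = 300, seed = 4)
  expect_identical(as.numeric(se1), as.numeric(se2))
  expect_gt(as.numeric(se1), 0)
  expect_equal(as.numeric(bootstrapSE(x, x, iterations = 100, seed = 1)), 0)
})

test_that("association battery applies the pairing rule and covariate menu", {
  set.seed(40)
  n <- 30
  subj <- sprintf("s%02d", 1:n)
  covTab <- data.frame(subject = subj, age_group = "young",
                       age = rnorm(n, 25, 3),
                       sex = sample(c("M", "F"), n, TRUE), scanner = "pre",
                       task_fd = runif(n, 0.02, 0.08),
                       rest_fd = runif(n, 0.02, 0.08))
  simVal <- rnorm(n)
  similarity <- data.frame(subject = subj, comparison = "stepwise",
                           pair = "dot3-dot1", scope = "global", r = NA,
                           z = simVal, n_edges = 1770, reason = NA)
  behavior <- do.call(rbind, lapply(c(1, 3, 5), function(l)
    data.frame(subject = subj, load = l, n_trials = 20,
               n_correct = 10, accuracy = if (l == 3) simVal * 0.05 + 0.7 +
                 rnorm(n, 0, 0.02) else rnorm(n, 0.8, 0.05),
               mean_rt_correct = 0.7)))
  res <- associationBattery(similarity, behavior, covTab)
  expect_equal(nrow(res), 1L)
  # dot3-dot1 stepwise pairs with load-3 behavior; task-task pair excludes
  # rest FD from the covariates
  y3 <- behavior$accuracy[behavior$load == 3]
  C <- data.frame(age = covTab$age, sex = as.integer(factor(covTab$sex)),
                  task_fd = covTab$task_fd)
  expect_equal(res$rho, partialSpearman(simVal, y3, C)$rho,
               tolerance = 1e-12)
  expect_gt(res$rho, 0.5)
  # a rest-involving pair adds rest FD to the covariates
  simRT <- similarity; simRT$comparison <- "rest_task"
  simRT$pair <- "dot3-rest"
  resRT <- associationBattery(simRT, behavior, covTab)
  expect_equal(resRT$rho,
               partialSpearman(simVal, y3, cbind(C, rest_fd = covTab$rest_fd))$rho,
               tolerance = 1e-12)
  # subject mismatch is a join error naming the offender
  expect_error(associationBattery(similarity, behavior, covTab[-1, ]), "s01")
})

test_that("motion matching trims the young tail until FD distributions agree", {
  set.seed(44)
  covTab <- data.frame(
    subject = c(sprintf("Y%02d", 1:40), sprintf("O%02d", 1:15)),
    age_group = rep(c("young", "old"), c(40, 15)),
    age = 30, sex = "F", scanner = "pre",
    task_fd = c(rnorm(40, 0.05, 0.02), rnorm(15, 0.07, 0.03)),
    rest_fd = c(rnorm(40, 0.05, 0.02), rnorm(15, 0.07, 0.03)))
  keep <- motionMatchedSubset(covTab)
  youngKeep <- covTab[covTab$subject %in% keep &
                        covTab$age_group == "young", ]
  oldAll <- covTab[covTab$age_group == "old", ]
  expect_true(all(oldAll$subject %in% keep))
  expect_lt(nrow(youngKeep), 40)
  expect_gt(t.test(youngKeep$task_fd, oldAll$task_fd)$p.value, 0.05)
  expect_gt(t.test(youngKeep$rest_fd, oldAll$rest_fd)$p.value, 0.05)
})
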