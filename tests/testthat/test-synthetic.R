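test_that("network covariance has the block pattern and is positive definite", {
  sc <- tinyScheme()
  sig <- buildNetworkCovariance(sc, 0.5, 0.1)
  expect_equal(diag(sig), rep(1, 4))
  expect_equal(sig[1, 2], 0.5)  # same network (ECN)
  expect_equal(sig[3, 4], 0.5)  # same network (DMN)
  expect_equal(sig[1, 3], 0.1)  # across networks
  # w = b collapses to compound symmetry: intra and inter entries equal
  cs <- buildNetworkCovariance(sc, 0.2, 0.2)
  off <- cs[upper.tri(cs)]
  expect_true(all(off == 0.2))
  # eigenvalues of the default young covariance are all positive
  spec <- cohortSpec(nYoung = 1, nOld = 1, R = 60)
  sig60 <- buildNetworkCovariance(spec$scheme, spec$w[["young"]],
                                  spec$b[["young"]])
  expect_true(min(eigen(sig60, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
  expect_error(buildNetworkCovariance(sc, 0.01, 0.9), "not positive definite")
  expect_error(buildNetworkCovariance(sc, 1.2, 0), "strictly")
})

test_that("mixed covariance interpolates linearly between rest and permuted topology", {
  spec <- quickSpec()
  sig <- buildNetworkCovariance(spec$scheme, 0.35, 0.05)
  perm <- fcreconfig:::altPermutation(spec)
  expect_identical(mixCovariance(sig, perm, 0), sig)
  expect_equal(mixCovariance(sig, perm, 1), sig[perm, perm])
  half <- mixCovariance(sig, perm, 0.5)
  expect_equal(half, (sig + sig[perm, perm]) / 2)
  # the permuted topology genuinely differs from the rest topology
  expect_gt(max(abs(sig - sig[perm, perm])), 0.1)
  # every mixture actually sampled remains positive definite
  for (l in c(0.25, 0.5, 0.75, 1))
    expect_silent(chol(mixCovariance(sig, perm, l)))
})

test_that("simulated subjects satisfy the design invariants deterministically", {
  fx <- quickSubject()
  s <- fx$subject
  for (run in 1:2) expect_silent(validateEvents(s@events[[run]]))
  expect_equal(nrow(s@rest@data), 235L + 5L)
  beh <- scoreBehavior(s@events, s@subject)
  expect_equal(beh$n_trials, rep(20L, 3))
  # same seed, byte-identical output
  cache <- fcreconfig:::cohortCache(fx$spec)
  s2 <- simulateSubject(fx$spec, quickMeta(), seed = 123, cache = cache)
  expect_identical(s@rest@data, s2@rest@data)
  expect_identical(s@taskRuns[[2]]@data, s2@taskRuns[[2]]@data)
  expect_identical(s@events, s2@events)
  expect_identical(s@truth, s2@truth)
  # different seed, different data
  s3 <- simulateSubject(fx$spec, quickMeta(), seed = 124, cache = cache)
  expect_false(identical(s@rest@data, s3@rest@data))
})

test_that("sample FC from the generative covariance converges with series length", {
  spec <- quickSpec()
  sig <- buildNetworkCovariance(spec$scheme, 0.35, 0.05)
  U <- chol(sig)
  zTrue <- atanh(sig * (1 - diag(60)) * (1 - 1e-7))
  diffAt <- function(T, seed) {
    set.seed(seed)
    x <- matrix(rnorm(T * 60), T) %*% U
    z <- atanh(pmax(pmin(cor(x), 1 - 1e-7), -1 + 1e-7))
    diag(z) <- 0
    mean(abs(z - zTrue)[lower.tri(z)])
  }
  d <- sapply(1:20, function(s) c(diffAt(60, s), diffAt(240, s),
                                  diffAt(960, s)))
  means <- rowMeans(d)
  expect_true(all(diff(means) < 0))          # shrinks as T grows
  expect_lt(means[3], means[1] / 2)          # and substantially so
})

test_that("behavior model plants the intended coupling and trial counts", {
  spec <- quickSpec()
  lam <- c(`1` = 0.2, `3` = 0.3, `5` = 0.4)
  beh <- simulateBehavior(spec, lam, "young", seed = 5)
  expect_equal(nrow(beh), 60L)
  expect_equal(unname(table(beh$load)), rep(20L, 3), ignore_attr = TRUE)

  # a1 = 0 and no penalties: accuracy independent of lambda
  null <- cohortSpec(nYoung = 1, nOld = 1, R = 60, a1 = 0,
                     loadPenalty = c(0, 0, 0), noiseSd = 0)
  lams <- seq(0.05, 0.95, length.out = 120)
  acc <- vapply(seq_along(lams), function(i) {
    b <- simulateBehavior(null, setNames(rep(lams[i], 3), c("1", "3", "5")),
                          "young", seed = 1000 + i)
    mean(b$correct)
  }, numeric(1))
  expect_lt(abs(cor(lams, acc)), 0.2)

  # a1 large, noise 0: accuracy ordering inverts the lambda ordering
  steep <- cohortSpec(nYoung = 1, nOld = 1, R = 60, a0 = 2, a1 = 10,
                      noiseSd = 0, loadPenalty = c(0, 0, 0))
  accS <- vapply(seq_along(lams), function(i) {
    b <- simulateBehavior(steep, setNames(rep(lams[i], 3), c("1", "3", "5")),
                          "young", seed = 2000 + i)
    mean(b$correct)
  }, numeric(1))
  expect_lt(cor(lams, accS, method = "spearman"), -0.8)
})

test_that("expected rest-task similarity is non-increasing in the mixing weight", {
  spec <- quickSpec()
  sig <- buildNetworkCovariance(spec$scheme, 0.35, 0.05)
  perm <- fcreconfig:::altPermutation(spec)
  U <- chol(sig)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  simAt <- function(lambda, seed) {
    set.seed(seed)
    rest <- matrix(rnorm(240 * 60), 240) %*% U
    task <- matrix(rnorm(240 * 60), 240) %*% chol(mixCovariance(sig, perm,
                                                                lambda))
    zr <- atanh(pmax(pmin(cor(rest), 1 - 1e-7), -1 + 1e-7))
    zt <- atanh(pmax(pmin(cor(task), 1 - 1e-7), -1 + 1e-7))
    cor(zr[lower.tri(zr)], zt[lower.tri(zt)])
  }
  curves <- sapply(1:10, function(s) vapply(grid, simAt, numeric(1),
                                            seed = 3000 + s))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) < 0))
})

test_that("planted group difference appears in sample similarity; null cohorts show none", {
  # reduced-size version of the cohort-level ground-truth recovery property
  spec <- cohortSpec(nYoung = 4, nOld = 4, R = 60)
  nullSpec <- cohortSpec(nYoung = 4, nOld = 4, R = 60,
                         w = c(young = 0.35, old = 0.35),
                         b = c(young = 0.05, old = 0.05),
                         lambda = rbind(young = c(0.10, 0.18, 0.26),
                                        old = c(0.10, 0.18, 0.26)))
  groupMeans <- function(sp, seed) {
    coh <- simulateCohort(sp, seed)
    sets <- edgeSets(sp$scheme)
    vals <- vapply(subjects(coh), function(s) {
      cond <- conditionSubject(s)
      fcs <- fcPerCondition(cond, sp$scheme)
      mean(vapply(paste0("dot", c(1, 3, 5)), function(nm)
        fcSimilarity(fcs$rest, fcs[[nm]], sets$global)$z, numeric(1)))
    }, numeric(1))
    grp <- participants(coh)$age_group
    c(young = mean(vals[grp == "young"]), old = mean(vals[grp == "old"]))
  }
  planted <- sapply(1:4, function(s) groupMeans(spec, 5000 + s))
  expect_true(all(planted["young", ] > planted["old", ]))
  nulls <- sapply(1:4, function(s) groupMeans(nullSpec, 6000 + s))
  expect_lt(abs(mean(nulls["young", ] - nulls["old", ])), 0.05)
})

test_that("cohort writer emits a complete readable on-disk layout", {
  spec <- cohortSpec(nYoung = 1, nOld = 1, R = 60)
  coh <- simulateCohort(spec, 9)
  dir <- withr::local_tempdir()
  writeCohort(coh, spec, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(nrow(gt), 6L)  # 2 subjects x 3 loads
  s1 <- subjects(coh)[[1]]
  back <- readTimeSeries(file.path(dir, s1@subject, "rest_timeseries.tsv"),
                         spec$scheme, s1@subject, "rest", 2)
  expect_equal(back@data, s1@rest@data, tolerance = 0)
  ev <- readEvents(file.path(dir, s1@subject, "task_run1_events.tsv"))
  expect_equal(nrow(ev), nrow(s1@events[[1]]))
})
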