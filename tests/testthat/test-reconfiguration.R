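test_that("edge sets partition the lower triangle with the half-weight identity", {
  for (sc in list(tinyScheme(), randomScheme(4, 5), makeParcellation(430))) {
    sets <- edgeSets(sc)
    R <- nRoi(sc)
    expect_length(sets$global, R * (R - 1) / 2)
    intra <- sum(lengths(sets[grep("^intra:", names(sets))]))
    inter <- sum(lengths(sets[grep("^inter:", names(sets))]))
    expect_equal(intra + inter / 2, length(sets$global))
    # intra and inter sets are consistent with network membership
    net <- unname(networkAssignment(sc))
    lt <- which(lower.tri(matrix(0, R, R)))
    ri <- row(matrix(0, R, R))[lt]; ci <- col(matrix(0, R, R))[lt]
    n1 <- names(table(net))[1]
    expect_identical(sets[[paste0("intra:", n1)]],
                     which(net[ri] == n1 & net[ci] == n1))
    expect_identical(sets[[paste0("inter:", n1)]],
                     which(xor(net[ri] == n1, net[ci] == n1)))
  }
})

test_that("similarity matches a brute-force edge enumeration oracle", {
  sc <- tinyScheme()
  A <- randomZMatrix(4, 31); B <- randomZMatrix(4, 32)
  fa <- asFc(A, sc); fb <- asFc(B, sc)
  sets <- edgeSets(sc)
  res <- fcSimilarity(fa, fb, sets$global)
  oracle <- bruteSimilarity(A, B, sc, "global")
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  expect_equal(res$n, oracle$n)
  expect_equal(res$z, atanh(res$r))
  # symmetry in the two arguments
  expect_equal(fcSimilarity(fb, fa, sets$global)$r, res$r, tolerance = 1e-15)
  # identity and sign flip hit the clip ceiling
  expect_equal(fcSimilarity(fa, fa, sets$global)$z, atanh(1 - 1e-7))
  fneg <- asFc(-A, sc)
  expect_equal(fcSimilarity(fa, fneg, sets$global)$z, -atanh(1 - 1e-7))
  # a 2-ROI network's intra set is a scope error
  expect_error(fcSimilarity(fa, fb, sets[["intra:ECN"]]), "too small")
})

test_that("blocked similarity equals brute force on random multi-network instances", {
  for (i in 1:10) {
    sc <- randomScheme(4, 5)
    A <- randomZMatrix(20, 100 + i); B <- randomZMatrix(20, 200 + i)
    fa <- asFc(A, sc); fb <- asFc(B, sc)
    sets <- edgeSets(sc)
    for (scope in c("global", "intra:DMN", "inter:LN")) {
      expect_equal(fcSimilarity(fa, fb, sets[[scope]])$r,
                   bruteSimilarity(A, B, sc, scope)$r, tolerance = 1e-12)
    }
  }
})

test_that("similarity is invariant under joint ROI relabeling", {
  sc <- randomScheme(3, 4)
  A <- randomZMatrix(12, 51); B <- randomZMatrix(12, 52)
  set.seed(53)
  perm <- sample(12)
  names <- roiNames(sc)[perm]
  net <- unname(networkAssignment(sc))[perm]
  scP <- ParcellationScheme(names, net)
  ord <- match(roiNames(scP), roiNames(sc)[perm])
  AP <- A[perm, perm][ord, ord]; BP <- B[perm, perm][ord, ord]
  for (scope in c("global", "intra:DMN", "inter:ECN")) {
    expect_equal(
      fcSimilarity(asFc(AP, scP), asFc(BP, scP), edgeSets(scP)[[scope]])$r,
      fcSimilarity(asFc(A, sc), asFc(B, sc), edgeSets(sc)[[scope]])$r,
      tolerance = 1e-12)
  }
})

test_that("rest-task and stepwise menus emit the full 57-record inventory", {
  sc <- randomScheme(9, 4)  # all nine networks, 4 ROIs each
  fcs <- list(rest = asFc(randomZMatrix(36, 1), sc, "rest"),
              dot1 = asFc(randomZMatrix(36, 2), sc, "dot1"),
              dot3 = asFc(randomZMatrix(36, 3), sc, "dot3"),
              dot5 = asFc(randomZMatrix(36, 4), sc, "dot5"))
  rt <- restTaskSimilarities(fcs, sc, "s1")
  expect_equal(nrow(rt), 57L)  # 3 pairs x (1 global + 9 intra + 9 inter)
  expect_setequal(unique(rt$pair), c("dot1-rest", "dot3-rest", "dot5-rest"))
  expect_true(all(!is.na(rt$z)))
  sw <- stepwiseSimilarities(fcs, sc, "s1")
  expect_equal(nrow(sw), 57L)
  expect_setequal(unique(sw$pair), c("dot1-rest", "dot3-dot1", "dot5-dot3"))
  # the shared dot1-rest pair is the same computation in both menus
  expect_equal(sw$z[sw$pair == "dot1-rest"], rt$z[rt$pair == "dot1-rest"])
  # identical rest and task matrices give the ceiling everywhere
  same <- list(rest = fcs$rest, dot1 = fcs$rest, dot3 = fcs$rest,
               dot5 = fcs$rest)
  rtSame <- restTaskSimilarities(same, sc, "s1")
  expect_true(all(rtSame$z == atanh(1 - 1e-7)))
  expect_error(restTaskSimilarities(fcs[-2], sc), "dot1")
})

test_that("degenerate scopes become missing records with reasons, not drops", {
  sc <- ParcellationScheme(sprintf("r%d", 1:6),
                           c("ECN", "ECN", "ECN", "ECN", "DMN", "DMN"))
  fcs <- list(rest = asFc(randomZMatrix(6, 9), sc),
              dot1 = asFc(randomZMatrix(6, 10), sc),
              dot3 = asFc(randomZMatrix(6, 11), sc),
              dot5 = asFc(randomZMatrix(6, 12), sc))
  rt <- restTaskSimilarities(fcs, sc, "s1")
  expect_equal(nrow(rt), 3 * 5)  # 1 global + 2 intra + 2 inter per pair
  dmn <- rt[rt$scope == "intra:DMN", ]
  expect_true(all(is.na(dmn$z)))
  expect_match(dmn$reason, "too small")
  expect_true(all(!is.na(rt$z[rt$scope == "global"])))
})

test_that("within-load similarity compares the two runs at each load", {
  sc <- randomScheme(4, 5)
  fcs <- list()
  for (l in c(1, 3, 5)) for (r in 1:2)
    fcs[[sprintf("dot%d_run%d", l, r)]] <-
      asFc(randomZMatrix(20, l * 10 + r), sc)
  wl <- withinLoadSimilarity(fcs, sc, "s1")
  expect_equal(nrow(wl), 3L)
  expect_setequal(wl$pair, c("dot1r1-dot1r2", "dot3r1-dot3r2",
                             "dot5r1-dot5r2"))
  # identical runs hit the ceiling
  fcs2 <- fcs; fcs2$dot1_run2 <- fcs2$dot1_run1
  wl2 <- withinLoadSimilarity(fcs2, sc, "s1")
  expect_equal(wl2$z[wl2$pair == "dot1r1-dot1r2"], atanh(1 - 1e-7))
  # independent-noise run matrices: similarity near 0 on average
  zs <- vapply(1:30, function(s) {
    a <- asFc(randomZMatrix(20, 700 + s), sc)
    b <- asFc(randomZMatrix(20, 900 + s), sc)
    fcSimilarity(a, b, edgeSets(sc)$global)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.05)
  expect_error(withinLoadSimilarity(fcs[-1], sc), "dot1_run1")
})

test_that("averaged FC reproduces explicit edge-list means and recombines", {
  sc <- tinyScheme()
  # constant matrix: every scope mean equals the constant
  cst <- matrix(0.4, 4, 4); diag(cst) <- 0
  av <- averagedFC(asFc(cst, sc), sc)
  expect_equal(nrow(av), 5L)  # global + 2 networks x (intra, inter)
  expect_true(all(av$mean_z == 0.4))
  # hand example against explicit edge lists
  A <- randomZMatrix(4, 77)
  av2 <- averagedFC(asFc(A, sc), sc)
  expect_equal(av2$mean_z[av2$scope == "intra:ECN"], A[2, 1])
  expect_equal(av2$mean_z[av2$scope == "intra:DMN"], A[4, 3])
  expect_equal(av2$mean_z[av2$scope == "inter:ECN"],
               mean(c(A[3, 1], A[4, 1], A[3, 2], A[4, 2])))
  expect_equal(av2$mean_z[av2$scope == "global"],
               mean(A[lower.tri(A)]))
  # partition identity: global mean from weighted intra/inter recombination
  sc9 <- randomScheme(5, 4)
  B <- randomZMatrix(20, 88)
  av3 <- averagedFC(asFc(B, sc9), sc9)
  g <- av3[av3$scope == "global", ]
  intra <- av3[grepl("^intra:", av3$scope), ]
  inter <- av3[grepl("^inter:", av3$scope), ]
  recomb <- (sum(intra$mean_z * intra$n_edges) +
               sum(inter$mean_z * inter$n_edges) / 2) / g$n_edges
  expect_equal(recomb, g$mean_z, tolerance = 1e-12)
})

test_that("sample rest-task similarity decreases in the planted mixing weight", {
  spec <- quickSpec()
  cache <- fcreconfig:::cohortCache(spec)
  sets <- edgeSets(spec$scheme)
  simFor <- function(lambda, seed) {
    sp <- spec
    sp$lambda <- rbind(young = rep(lambda, 3), old = rep(lambda, 3))
    sp$tau <- 0
    s <- simulateSubject(sp, quickMeta(), seed, cache)
    cond <- conditionSubject(s, loads = 3L)
    fcs <- fcPerCondition(cond, spec$scheme)
    fcSimilarity(fcs$rest, fcs$dot3, sets$global)$z
  }
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  curves <- sapply(1:6, function(s)
    vapply(grid, simFor, numeric(1), seed = 4000 + s))
  expect_true(all(diff(rowMeans(curves)) < 0))
})
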