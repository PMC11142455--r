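# Shared fixtures, all generated in code.

# Minimal 4-ROI scheme: two networks of two ROIs.
tinyScheme <- function() {
  ParcellationScheme(c("e1", "e2", "d1", "d2"),
                     c("ECN", "ECN", "DMN", "DMN"))
}

# Random scheme with nNet networks of sizePer ROIs each.
randomScheme <- function(nNet = 4, sizePer = 5) {
  nets <- NETWORKS[seq_len(nNet)]
  ParcellationScheme(sprintf("r%02d", seq_len(nNet * sizePer)),
                     rep(nets, each = sizePer))
}

# Fast cohort spec used by most pipeline-level tests.
quickSpec <- function(...) cohortSpec(nYoung = 3L, nOld = 3L, R = 60L, ...)

quickMeta <- function(subject = "Y001", ageGroup = "young") {
  list(subject = subject, ageGroup = ageGroup, sex = "F", scanner = "pre",
       age = if (ageGroup == "young") 25 else 65)
}

# One simulated subject under the quick spec (memoised per session).
.fixtureEnv <- new.env()
quickSubject <- function() {
  if (is.null(.fixtureEnv$subj)) {
    spec <- quickSpec()
    .fixtureEnv$spec <- spec
    .fixtureEnv$subj <- simulateSubject(spec, quickMeta(), seed = 123,
                                        cache = fcreconfig:::cohortCache(spec))
  }
  list(spec = .fixtureEnv$spec, subject = .fixtureEnv$subj)
}

# A symmetric z matrix with zero diagonal, for similarity tests.
randomZMatrix <- function(R, seed) {
  set.seed(seed)
  m <- matrix(rnorm(R * R, sd = 0.3), R, R)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

asFc <- function(values, scheme, condition = "rest") {
  new("FCMatrix", values = values, condition = condition,
      nTimepoints = 100L, scheme = scheme)
}

# Brute-force similarity oracle: enumerate edges explicitly and apply the
# textbook correlation formula.
bruteSimilarity <- function(A, B, scheme, scope) {
  net <- networkAssignment(scheme)
  R <- nrow(A)
  va <- c(); vb <- c()
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i <= j) next
    keep <- switch(
      scope_kind(scope),
      global = TRUE,
      intra = net[i] == scope_net(scope) && net[j] == scope_net(scope),
      inter = xor(net[i] == scope_net(scope), net[j] == scope_net(scope)))
    if (keep) { va <- c(va, A[i, j]); vb <- c(vb, B[i, j]) }
  }
  n <- length(va)
  num <- sum((va - mean(va)) * (vb - mean(vb)))
  den <- sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  list(r = num / den, n = n)
}
scope_kind <- function(scope) sub(":.*", "", scope)
scope_net <- function(scope) sub(".*:", "", scope)

# Event-table builder for unit tests: one run with given per-block loads and
# outcomes (all correct unless stated).
buildTestEvents <- function(blockOrder = c(1L, 3L, 5L), correct = NULL,
                            rt = 0.8, iti = 3) {
  outcomes <- list()
  for (l in blockOrder) {
    co <- if (is.null(correct)) rep(TRUE, 10) else correct[[as.character(l)]]
    outcomes[[as.character(l)]] <- list(correct = co, rt = rep(rt, 10),
                                        iti = rep(iti, 10))
  }
  fcreconfig:::simulateRunEvents(blockOrder, outcomes)
}
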