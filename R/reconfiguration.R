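#' @include AllClasses.R utils.R connectivity.R
NULL

#' Edge sets of a parcellation
#'
#' Partitions the R(R-1)/2 unordered ROI pairs into scopes: `global` (all
#' pairs), `intra:<network>` (both ROIs in the network), and
#' `inter:<network>` (exactly one ROI in the network). Each cross-network
#' edge belongs to the inter sets of both endpoint networks, so the inter
#' sets overlap pairwise and the partition identity
#' `sum |intra| + 1/2 sum |inter| = |global|` holds exactly.
#'
#' Indices address the lower-triangle vector of an FC matrix in column-major
#' order, as produced by `m[lower.tri(m)]`.
#'
#' @param scheme a [ParcellationScheme-class].
#' @return named list of integer index vectors (`global`, `intra:ECN`, ...,
#'   `inter:SUB`).
#' @export
edgeSets <- function(scheme) {
  R <- nRoi(scheme)
  net <- scheme@network
  ri <- sequence((R - 1):1) + rep(1:(R - 1), (R - 1):1)  # row index, i > j
  ci <- rep(1:(R - 1), (R - 1):1)
  ni <- net[ri]; nj <- net[ci]
  sets <- list(global = seq_along(ri))
  for (n in NETWORKS) {
    if (!n %in% net) next
    sets[[paste0("intra:", n)]] <- which(ni == n & nj == n)
    sets[[paste0("inter:", n)]] <- which(xor(ni == n, nj == n))
  }
  sets
}

#' FC similarity between two matrices over an edge set
#'
#' Pearson correlation of the two Fisher-z edge-value vectors over the given
#' edges, clipped and r-to-z transformed exactly as [computeFC()]. High
#' similarity means little reconfiguration between the two conditions.
#'
#' @param fcA,fcB two [FCMatrix-class] built against the same scheme.
#' @param edges integer indices into the lower-triangle vector (one element
#'   of [edgeSets()]).
#' @return list: `r` (raw correlation), `z` (Fisher z), `n` (edge count).
#' @export
fcSimilarity <- function(fcA, fcB, edges) {
  if (!identical(fcA@scheme@roiName, fcB@scheme@roiName))
    stop("FC matrices do not share a parcellation scheme")
  if (length(edges) < 3)
    stop("edge set too small (", length(edges), " < 3) for a similarity value")
  a <- ltVector(fcA@values)[edges]
  b <- ltVector(fcB@values)[edges]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance over the edge set; similarity undefined")
  r <- stats::cor(a, b)
  list(r = r, z = clipAtanh(r), n = length(edges))
}

# One similarity record row, or a missing record with a reason code when the
# scope is degenerate (too few edges), never a silent drop.
similarityRecord <- function(subject, comparison, pair, scope, fcA, fcB, edges) {
  res <- tryCatch(fcSimilarity(fcA, fcB, edges), error = function(e) e)
  if (inherits(res, "error"))
    data.frame(subject = subject, comparison = comparison, pair = pair,
               scope = scope, r = NA_real_, z = NA_real_,
               n_edges = length(edges), reason = conditionMessage(res),
               stringsAsFactors = FALSE)
  else
    data.frame(subject = subject, comparison = comparison, pair = pair,
               scope = scope, r = res$r, z = res$z, n_edges = res$n,
               reason = NA_character_, stringsAsFactors = FALSE)
}

pairRecords <- function(subject, comparison, pairs, fcs, scheme,
                        scopes = NULL) {
  sets <- edgeSets(scheme)
  if (!is.null(scopes)) sets <- sets[scopes]
  out <- vector("list", length(pairs) * length(sets))
  k <- 0L
  for (p in names(pairs)) {
    ab <- pairs[[p]]
    for (sc in names(sets)) {
      k <- k + 1L
      out[[k]] <- similarityRecord(subject, comparison, p, sc,
                                   fcs[[ab[1]]], fcs[[ab[2]]], sets[[sc]])
    }
  }
  do.call(rbind, out)
}

#' Rest-task FC similarity records for one subject
#'
#' Similarity between the rest FC matrix and each load-specific task FC
#' matrix (pairs `dot1-rest`, `dot3-rest`, `dot5-rest`), at global scope and
#' per-network intra/inter scopes: up to 57 records on the full nine-network
#' scheme. Scopes with fewer than 3 edges are emitted as missing with a
#' reason code.
#'
#' @param fcs named list from [fcPerCondition()] (needs `rest`, `dot1`,
#'   `dot3`, `dot5`).
#' @param scheme the [ParcellationScheme-class].
#' @param subject subject id for the records.
#' @param scopes optional subset of scope names (e.g. `"global"`) for speed.
#' @return data.frame: subject, comparison, pair, scope, r, z, n_edges,
#'   reason.
#' @export
restTaskSimilarities <- function(fcs, scheme, subject = "unknown",
                                 scopes = NULL) {
  need <- c("rest", "dot1", "dot3", "dot5")
  miss <- setdiff(need, names(fcs))
  if (length(miss)) stop("missing condition FC: ", paste(miss, collapse = ", "))
  pairs <- list(`dot1-rest` = c("dot1", "rest"),
                `dot3-rest` = c("dot3", "rest"),
                `dot5-rest` = c("dot5", "rest"))
  pairRecords(subject, "rest_task", pairs, fcs, scheme, scopes)
}

#' Stepwise FC similarity records for one subject
#'
#' Similarity between FC matrices of adjacent demand levels: pairs
#' `dot1-rest`, `dot3-dot1`, `dot5-dot3`, same scope menu as
#' [restTaskSimilarities()].
#'
#' @inheritParams restTaskSimilarities
#' @return data.frame as in [restTaskSimilarities()].
#' @export
stepwiseSimilarities <- function(fcs, scheme, subject = "unknown",
                                 scopes = NULL) {
  need <- c("rest", "dot1", "dot3", "dot5")
  miss <- setdiff(need, names(fcs))
  if (length(miss)) stop("missing condition FC: ", paste(miss, collapse = ", "))
  pairs <- list(`dot1-rest` = c("dot1", "rest"),
                `dot3-dot1` = c("dot3", "dot1"),
                `dot5-dot3` = c("dot5", "dot3"))
  pairRecords(subject, "stepwise", pairs, fcs, scheme, scopes)
}

#' Within-load FC similarity (run-to-run stability)
#'
#' Global similarity between the two runs' FC matrices at the same load:
#' three records with pairs `dot<l>r1-dot<l>r2`.
#'
#' @param fcs named list containing the six per-run matrices
#'   (`dot1_run1`, ..., `dot5_run2`), e.g. from
#'   `fcPerCondition(..., withinLoad = TRUE)`.
#' @param scheme the [ParcellationScheme-class].
#' @param subject subject id.
#' @return data.frame with 3 records (comparison `within_load`, scope
#'   `global`).
#' @export
withinLoadSimilarity <- function(fcs, scheme, subject = "unknown") {
  need <- as.vector(outer(paste0("dot", c(1, 3, 5)), paste0("_run", 1:2),
                          paste0))
  miss <- setdiff(need, names(fcs))
  if (length(miss)) stop("missing per-run FC: ", paste(miss, collapse = ", "))
  pairs <- list()
  for (l in c(1, 3, 5))
    pairs[[sprintf("dot%dr1-dot%dr2", l, l)]] <-
      sprintf("dot%d_run%d", l, 1:2)
  pairRecords(subject, "within_load", pairs, fcs, scheme, scopes = "global")
}

#' Averaged FC over edge sets
#'
#' Mean Fisher-z connectivity over the global edge set and each network's
#' intra and inter sets: the connectivity-strength counterpart of the
#' similarity measures (1 + 9 + 9 = 19 values per FC matrix).
#'
#' @param fc an [FCMatrix-class].
#' @param scheme the [ParcellationScheme-class].
#' @return data.frame: condition, scope, mean_z, n_edges.
#' @export
averagedFC <- function(fc, scheme) {
  sets <- edgeSets(scheme)
  v <- ltVector(fc@values)
  do.call(rbind, lapply(names(sets), function(sc)
    data.frame(condition = fc@condition, scope = sc,
               mean_z = mean(v[sets[[sc]]]), n_edges = length(sets[[sc]]),
               stringsAsFactors = FALSE)))
}
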