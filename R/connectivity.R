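#' @include AllClasses.R utils.R conditioning.R
NULL

#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time courses, clipped to
#' `|r| <= 1 - 1e-7` and Fisher r-to-z transformed. The diagonal is stored
#' as 0 and excluded from every downstream edge set.
#'
#' @param ts a conditioned [RoiTimeSeries-class] (T >= 3, every ROI with
#'   nonzero variance).
#' @param scheme the [ParcellationScheme-class] the columns follow.
#' @param condition condition label; defaults to the time series' label.
#' @return an [FCMatrix-class].
#' @export
computeFC <- function(ts, scheme, condition = ts@condition) {
  x <- ts@data
  if (nrow(x) < 3) stop("need at least 3 timepoints to estimate FC")
  r <- suppressWarnings(stats::cor(x))  # zero variance handled below
  if (anyNA(r)) {
    sds <- apply(x, 2, stats::sd)
    stop("zero-variance ROI(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- clipAtanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against rounding
  fastFc(z, condition, nrow(x), scheme)
}

#' All condition FC matrices for one subject
#'
#' Rest FC from the full conditioned rest run; dot1/dot3/dot5 FC from the
#' cross-run concatenated load blocks; with `withinLoad = TRUE` additionally
#' the six per-run-per-load matrices used by the within-load stability
#' analysis.
#'
#' @param conditioned output of [conditionSubject()].
#' @param scheme the [ParcellationScheme-class].
#' @param withinLoad also compute per-run matrices?
#' @return named list of [FCMatrix-class] (`rest`, `dot1`, `dot3`, `dot5`,
#'   and optionally `dot<l>_run<r>`).
#' @export
fcPerCondition <- function(conditioned, scheme, withinLoad = FALSE) {
  out <- list(rest = computeFC(conditioned$rest, scheme, "rest"))
  for (nm in names(conditioned$loads))
    out[[nm]] <- computeFC(conditioned$loads[[nm]], scheme, nm)
  if (withinLoad) {
    if (is.null(conditioned$perRun))
      stop("conditionSubject() must be run with perRun = TRUE for within-load FC")
    for (nm in names(conditioned$perRun))
      out[[nm]] <- computeFC(conditioned$perRun[[nm]], scheme, nm)
  }
  out
}
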