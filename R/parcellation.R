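#' @include AllClasses.R
NULL

#' Construct a ParcellationScheme
#'
#' ROIs are reordered into the canonical network-sorted order (networks in the
#' fixed order of [NETWORKS]; within a network, ROIs keep their input order),
#' so that same-network ROI pairs form the diagonal blocks of any FC matrix
#' built against the scheme.
#'
#' @param roiName character vector of unique ROI names.
#' @param network character vector of network labels, one per ROI; each must
#'   be one of [NETWORKS].
#' @return a [ParcellationScheme-class] object.
#' @examples
#' sc <- ParcellationScheme(paste0("r", 1:4), c("DMN", "ECN", "DMN", "ECN"))
#' networkAssignment(sc)
#' @export
ParcellationScheme <- function(roiName, network) {
  stopifnot(length(roiName) == length(network))
  bad <- setdiff(unique(network), NETWORKS)
  if (length(bad))
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  ord <- order(match(network, NETWORKS))
  new("ParcellationScheme", roiName = as.character(roiName[ord]),
      network = as.character(network[ord]))
}

#' Default 430-ROI parcellation
#'
#' Builds the package's reference parcellation: 400 cortical ROIs in eight
#' networks (Schaefer-400-style counts) plus 30 subcortical ROIs, grouped
#' into nine networks. With `nRoi < 430` a proportionally reduced scheme is
#' returned (at least `minPerNetwork` ROIs per network), which keeps small
#' simulations structurally faithful.
#'
#' @param nRoi total ROI count (default 430).
#' @param minPerNetwork minimum ROIs per network for reduced schemes.
#' @return a [ParcellationScheme-class].
#' @examples
#' sc <- makeParcellation(60)
#' table(networkAssignment(sc))
#' @export
makeParcellation <- function(nRoi = 430L, minPerNetwork = 4L) {
  full <- c(ECN = 52L, DMN = 78L, DAN = 46L, LN = 26L, SN = 47L,
            SMN = 77L, TP = 13L, VIS = 61L, SUB = 30L)
  stopifnot(sum(full) == 430L)
  if (nRoi == 430L) {
    counts <- full
  } else {
    if (nRoi < minPerNetwork * length(full))
      stop("nRoi too small: need at least ", minPerNetwork * length(full), " ROIs")
    counts <- pmax(round(full / sum(full) * nRoi), minPerNetwork)
    # adjust the largest networks until the total matches exactly
    while (sum(counts) != nRoi) {
      i <- if (sum(counts) > nRoi) which.max(counts) else which.min(counts)
      counts[i] <- counts[i] + sign(nRoi - sum(counts))
    }
  }
  network <- rep(names(counts), counts)
  roiName <- unlist(lapply(names(counts), function(n)
    sprintf("%s_%03d", n, seq_len(counts[[n]]))), use.names = FALSE)
  ParcellationScheme(roiName, network)
}

#' Read a parcellation lookup table
#'
#' Expects a two-column tab-separated file with header `roi_name`, `network`.
#'
#' @param path file path.
#' @return a [ParcellationScheme-class].
#' @seealso [writeParcellation()]
#' @export
readParcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_name", "network")
  if (!all(need %in% names(df)))
    stop("parcellation file must have columns: ", paste(need, collapse = ", "))
  ParcellationScheme(df$roi_name, df$network)
}

#' Write a parcellation lookup table
#' @param scheme a [ParcellationScheme-class].
#' @param path output path (TSV).
#' @return invisibly, `path`.
#' @export
writeParcellation <- function(scheme, path) {
  df <- data.frame(roi_name = scheme@roiName, network = scheme@network,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
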