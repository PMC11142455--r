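#' Derive a stage/subject seed from a global seed
#'
#' Deterministic 31-bit hash of the global seed and a label, so every
#' stochastic stage (and every subject) gets an independent, reproducible
#' stream and subjects can be regenerated in isolation.
#'
#' @param seed integer global seed.
#' @param ... labels (stage name, subject id, replicate index, ...).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (part in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(part)) h <- (h * 69069 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Clip a correlation away from +/-1, then Fisher r-to-z. The guard keeps z
# finite on degenerate fixtures while leaving realistic r untouched.
clipAtanh <- function(r, eps = 1e-7) {
  atanh(pmax(pmin(r, 1 - eps), -1 + eps))
}

# Lower-triangle (i > j) vector of a square matrix, column-major.
ltVector <- function(m) m[lower.tri(m)]

# Fast internal constructors: slot assignment on a prototype skips the
# validity scan, safe only for data that is valid by construction.
.proto <- new.env(parent = emptyenv())

fastTs <- function(data, subject, condition, tr) {
  if (is.null(.proto$ts))
    .proto$ts <- methods::new("RoiTimeSeries",
                              data = matrix(0, 2, 1,
                                            dimnames = list(NULL, "r")),
                              subject = "", condition = "rest", tr = 1)
  obj <- .proto$ts
  obj@data <- data; obj@subject <- subject
  obj@condition <- condition; obj@tr <- tr
  obj
}

fastFc <- function(values, condition, nTimepoints, scheme) {
  if (is.null(.proto$fc))
    .proto$fc <- methods::new("FCMatrix",
                              values = matrix(0, 2, 2), condition = "rest",
                              nTimepoints = 3L,
                              scheme = ParcellationScheme(c("a", "b"),
                                                          c("ECN", "ECN")))
  obj <- .proto$fc
  obj@values <- values; obj@condition <- condition
  obj@nTimepoints <- nTimepoints; obj@scheme <- scheme
  obj
}
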