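#' @include AllClasses.R
NULL

#' Number of ROIs in a scheme or data object
#' @param x a ParcellationScheme, RoiTimeSeries, or FCMatrix
#' @return integer count of ROIs
#' @export
setGeneric("nRoi", function(x) standardGeneric("nRoi"))

#' ROI names in canonical order
#' @param x a ParcellationScheme, RoiTimeSeries, or FCMatrix
#' @return character vector
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Network assignment of each ROI
#' @param x a ParcellationScheme or FCMatrix
#' @return character vector named by ROI, values in [NETWORKS]
#' @export
setGeneric("networkAssignment", function(x) standardGeneric("networkAssignment"))

#' Extract the numeric payload
#' @param x a RoiTimeSeries (T x R matrix) or FCMatrix (R x R matrix)
#' @return numeric matrix
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Condition label of a data object
#' @param x a RoiTimeSeries or FCMatrix
#' @return character scalar
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' The ParcellationScheme behind an object
#' @param x an FCMatrix
#' @return a [ParcellationScheme]
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname nRoi
#' @export
setMethod("nRoi", "ParcellationScheme", function(x) length(x@roiName))
#' @rdname nRoi
#' @export
setMethod("nRoi", "RoiTimeSeries", function(x) ncol(x@data))
#' @rdname nRoi
#' @export
setMethod("nRoi", "FCMatrix", function(x) nrow(x@values))

#' @rdname roiNames
#' @export
setMethod("roiNames", "ParcellationScheme", function(x) x@roiName)
#' @rdname roiNames
#' @export
setMethod("roiNames", "RoiTimeSeries", function(x) colnames(x@data))
#' @rdname roiNames
#' @export
setMethod("roiNames", "FCMatrix", function(x) x@scheme@roiName)

#' @rdname networkAssignment
#' @export
setMethod("networkAssignment", "ParcellationScheme", function(x) {
  stats::setNames(x@network, x@roiName)
})
#' @rdname networkAssignment
#' @export
setMethod("networkAssignment", "FCMatrix", function(x) networkAssignment(x@scheme))

#' @rdname values
#' @export
setMethod("values", "RoiTimeSeries", function(x) x@data)
#' @rdname values
#' @export
setMethod("values", "FCMatrix", function(x) x@values)

#' @rdname condition
#' @export
setMethod("condition", "RoiTimeSeries", function(x) x@condition)
#' @rdname condition
#' @export
setMethod("condition", "FCMatrix", function(x) x@condition)

#' @rdname scheme
#' @export
setMethod("scheme", "FCMatrix", function(x) x@scheme)

#' Subjects of a cohort
#' @param x a [Cohort]
#' @return list of [SubjectRecord]
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname subjects
#' @export
setMethod("subjects", "Cohort", function(x) x@subjects)

#' Participants table of a cohort
#' @param x a [Cohort]
#' @return data.frame (subject, age_group, sex, scanner, age)
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname participants
#' @export
setMethod("participants", "Cohort", function(x) x@participants)
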