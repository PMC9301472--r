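#' @rdname ConnectivityMatrix-class
#' @param x,object A ConnectivityMatrix or ConnectivityCohort.
#' @export
setGeneric("connValues", function(x, ...) standardGeneric("connValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("isThresholded", function(x) standardGeneric("isThresholded"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("edgeKind", function(x) standardGeneric("edgeKind"))

#' Proportional thresholding generic
#'
#' @param x A [ConnectivityMatrix-class] or [ConnectivityCohort-class].
#' @param sparsity Fraction of upper-triangle edges to retain, in (0, 1].
#' @param ... Further arguments.
#' @export
setGeneric("proportionalThreshold",
  function(x, sparsity = 0.05, ...) standardGeneric("proportionalThreshold")
)

#' Per-subject edge standardization generic
#'
#' @param x A thresholded [ConnectivityMatrix-class] or
#'   [ConnectivityCohort-class].
#' @param ... Further arguments.
#' @export
setGeneric("standardizeMatrix",
  function(x, ...) standardGeneric("standardizeMatrix")
)

#' Graph-theory nodal measures generic
#'
#' @param x A thresholded [ConnectivityMatrix-class] or a square matrix.
#' @param ... Further arguments.
#' @export
setGeneric("nodeMeasures", function(x, ...) standardGeneric("nodeMeasures"))
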