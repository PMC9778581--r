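#' Line identifiers of a data object
#' @param x an object carrying line labels.
#' @return character vector of line identifiers.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname lineIds
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@genotypes))

#' @rdname lineIds
#' @export
setMethod("lineIds", "KernelMatrix", function(x) rownames(x@K))

#' Gaussian-kernel bandwidth of a kernel matrix
#' @param x a \linkS4class{KernelMatrix}.
#' @return the bandwidth rho, or NA for a linear kernel.
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname bandwidth
#' @export
setMethod("bandwidth", "KernelMatrix", function(x) x@rho)

#' @rdname bandwidth
#' @export
setMethod("bandwidth", "TuningResult", function(x) x@selectedRho)

#' Matrix payload of a wrapped matrix object
#' @param x a MarkerMatrix, DistanceMatrix or KernelMatrix.
#' @param ... unused.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "MarkerMatrix", function(x, ...) x@genotypes)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@D2)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "KernelMatrix", function(x, ...) x@K)

#' Posterior-mean variance components of a fit
#' @param x a \linkS4class{ModelFit}.
#' @return named numeric vector (varG, varGE, varE).
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname varComponents
#' @export
setMethod("varComponents", "ModelFit", function(x)
  c(varG = x@varG, varGE = x@varGE, varE = x@varE))

#' Evaluation log of a tuning run
#' @param x a \linkS4class{TuningResult}.
#' @return data.frame of (rho, nrmse) pairs in evaluation order.
#' @export
setGeneric("evaluations", function(x) standardGeneric("evaluations"))

#' @rdname evaluations
#' @export
setMethod("evaluations", "TuningResult", function(x) x@evaluations)

#' Metric table of an evaluation report
#' @param x an \linkS4class{EvaluationReport}.
#' @return data.frame with one row per scope x strategy.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname metricsTable
#' @export
setMethod("metricsTable", "EvaluationReport", function(x) x@metrics)

#' Relative-efficiency table of an evaluation report
#' @param x an \linkS4class{EvaluationReport}.
#' @return data.frame with one row per comparison x scope.
#' @export
setGeneric("relativeEfficiencies",
           function(x) standardGeneric("relativeEfficiencies"))

#' @rdname relativeEfficiencies
#' @export
setMethod("relativeEfficiencies", "EvaluationReport", function(x) x@relEff)
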