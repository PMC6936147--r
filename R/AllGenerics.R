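#' Gene symbols of an object
#'
#' @param x a dytidriver object carrying a gene axis.
#' @return character vector of gene symbols.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Patient identifiers of an object
#'
#' @param x a MutationCohort or OutlyingCalls.
#' @return character vector of patient identifiers.
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname MutationCohort-class
#' @param x a MutationCohort.
#' @return \code{mutationCalls}: the binary patients x genes matrix.
#' @export
setGeneric("mutationCalls", function(x) standardGeneric("mutationCalls"))

#' @rdname ExpressionMatrix-class
#' @param x an ExpressionMatrix.
#' @return \code{exprValues}: the samples x genes numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname FunctionalNetwork-class
#' @param x a FunctionalNetwork.
#' @return \code{networkNodes}: character vector of node symbols.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname FunctionalNetwork-class
#' @return \code{networkEdges}: two-column character matrix of edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname OutlyingCalls-class
#' @param x an OutlyingCalls.
#' @param patient a single patient identifier.
#' @return \code{outlyingGenes}: character vector of outlying genes for the
#'   patient.
#' @export
setGeneric("outlyingGenes", function(x, patient) standardGeneric("outlyingGenes"))

#' Adjacency / weight matrix of a graph-like object
#'
#' @param x a MutMutMatrix, TissuePCCMatrix, WeightedMutGraph or ECCMatrix.
#' @return the underlying symmetric numeric matrix.
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Per-gene score table
#'
#' @param x a DriverScoreTable or EvaluationCurve.
#' @return the underlying data.frame.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname EvaluationCurve-class
#' @param x an EvaluationCurve.
#' @return \code{curveTable}: data.frame of K, TP, FP, FN, precision, recall,
#'   fscore.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname SyntheticCohort-class
#' @param x a SyntheticCohort.
#' @return \code{plantedDrivers}: the true driver GeneSet.
#' @export
setGeneric("plantedDrivers", function(x) standardGeneric("plantedDrivers"))

#' @rdname SyntheticCohort-class
#' @return \code{moduleAssignments}: named list of module member genes.
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))
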