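#' @describeIn MutationCohort-class gene symbols (columns).
#' @export
setMethod("genes", "MutationCohort", function(x) colnames(x@calls))

#' @describeIn ExpressionMatrix-class gene symbols (columns).
#' @export
setMethod("genes", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn FunctionalNetwork-class node symbols.
#' @export
setMethod("genes", "FunctionalNetwork", function(x) x@nodes)

#' @describeIn GeneSet-class member symbols.
#' @export
setMethod("genes", "GeneSet", function(x) x@symbols)

#' @describeIn MutMutMatrix-class retained mutated genes.
#' @export
setMethod("genes", "MutMutMatrix", function(x) rownames(x@adjacency))

#' @describeIn TissuePCCMatrix-class genes of the weight matrix.
#' @export
setMethod("genes", "TissuePCCMatrix", function(x) rownames(x@weights))

#' @describeIn WeightedMutGraph-class retained mutated genes.
#' @export
setMethod("genes", "WeightedMutGraph", function(x) rownames(x@W))

#' @describeIn ECCMatrix-class genes of the ECC matrix.
#' @export
setMethod("genes", "ECCMatrix", function(x) rownames(x@values))

#' @describeIn DriverScoreTable-class genes, in table order.
#' @export
setMethod("genes", "DriverScoreTable", function(x) x@table$gene)

#' @describeIn MutationCohort-class patient identifiers (rows).
#' @export
setMethod("patients", "MutationCohort", function(x) rownames(x@calls))

#' @describeIn OutlyingCalls-class patient identifiers.
#' @export
setMethod("patients", "OutlyingCalls", function(x) x@patients)

#' @export
setMethod("mutationCalls", "MutationCohort", function(x) x@calls)

#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @export
setMethod("networkNodes", "FunctionalNetwork", function(x) x@nodes)

#' @export
setMethod("networkEdges", "FunctionalNetwork", function(x) x@edges)

#' @export
setMethod("outlyingGenes", "OutlyingCalls", function(x, patient) {
  if (!patient %in% x@patients) stop("unknown patient: ", patient)
  x@outlying[[patient]]
})

#' @export
setMethod("edgeWeights", "MutMutMatrix", function(x) x@adjacency)

#' @export
setMethod("edgeWeights", "TissuePCCMatrix", function(x) x@weights)

#' @export
setMethod("edgeWeights", "WeightedMutGraph", function(x) x@W)

#' @export
setMethod("edgeWeights", "ECCMatrix", function(x) x@values)

#' @export
setMethod("scoreTable", "DriverScoreTable", function(x) x@table)

#' @export
setMethod("curveTable", "EvaluationCurve", function(x) x@table)

#' @export
setMethod("plantedDrivers", "SyntheticCohort", function(x) x@truth)

#' @export
setMethod("moduleAssignments", "SyntheticCohort", function(x) x@modules)

#' Nonzero-weight degree of each gene in a WeightedMutGraph
#'
#' Counts neighbors joined by a nonzero weight; this is the degree d_i used
#' by the edge clustering coefficient denominator.
#'
#' @param x a WeightedMutGraph.
#' @return named integer vector of degrees.
#' @export
neighborCounts <- function(x) {
  stopifnot(is(x, "WeightedMutGraph"))
  d <- rowSums(x@W != 0)
  storage.mode(d) <- "integer"
  d
}

setMethod("show", "MutationCohort", function(object) {
  cat(sprintf("MutationCohort: %d patients x %d genes, %d calls\n",
              nrow(object@calls), ncol(object@calls), sum(object@calls)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d samples x %d genes (%d missing values)\n",
              nrow(object@values), ncol(object@values), sum(is.na(object@values))))
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf("FunctionalNetwork: %d nodes, %d undirected edges\n",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d symbols\n", object@label, length(object@symbols)))
})

setMethod("show", "OutlyingCalls", function(object) {
  n <- lengths(object@outlying)
  cat(sprintf("OutlyingCalls: %d patients, |z| > %g; %d outlier calls (median %g/patient)\n",
              length(object@patients), object@cutoff, sum(n), stats::median(n)))
})

setMethod("show", "MutMutMatrix", function(object) {
  cat(sprintf("MutMutMatrix: %d retained mutated genes, %d edges\n",
              nrow(object@adjacency), sum(object@adjacency) / 2))
})

setMethod("show", "TissuePCCMatrix", function(object) {
  w <- object@weights
  cat(sprintf("TissuePCCMatrix '%s': %d genes, %d weighted pairs\n",
              object@tissueLabel, nrow(w), sum(w[upper.tri(w)] != 0)))
})

setMethod("show", "WeightedMutGraph", function(object) {
  cat(sprintf("WeightedMutGraph: %d genes, %d nonzero-weight edges\n",
              nrow(object@W), sum(object@W[upper.tri(object@W)] != 0)))
})

setMethod("show", "ECCMatrix", function(object) {
  v <- object@values
  cat(sprintf("ECCMatrix: %d genes, %d nonzero ECC edges\n",
              nrow(v), sum(v[upper.tri(v)] != 0)))
})

setMethod("show", "DriverScoreTable", function(object) {
  tab <- object@table
  cat(sprintf("DriverScoreTable: %d genes%s\n", nrow(tab),
              if ("rank" %in% names(tab)) " (ranked)" else " (unranked)"))
  if (nrow(tab) > 0L) {
    print(head(tab, 5L), row.names = FALSE)
    if (nrow(tab) > 5L) cat("  ...\n")
  }
})

setMethod("show", "EvaluationCurve", function(object) {
  cat(sprintf("EvaluationCurve: K = 1..%d, %d benchmark genes in universe (%d total)\n",
              max(object@table$K), object@benchmarkSize, object@benchmarkTotal))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d genes, %d patients, %d planted drivers in %d modules\n",
              length(object@network@nodes), nrow(object@cohort@calls),
              length(object@truth@symbols), length(object@modules)))
})
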