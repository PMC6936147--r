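#' @import methods
#' @importFrom stats cor rnorm rbinom sd setNames median
#' @importFrom utils read.delim write.table head combn
NULL

.checkBinaryMatrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) return("calls must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls must carry patient rownames and gene colnames")
  if (anyDuplicated(rownames(m))) return("duplicate patient identifiers")
  if (anyDuplicated(colnames(m))) return("duplicate gene symbols")
  if (nrow(m) < 1L || ncol(m) < 1L) return("need at least one patient and one gene")
  if (anyNA(m) || !all(m %in% c(0, 1))) return("calls must be 0/1")
  TRUE
}

#' MutationCohort: binary patient-by-gene somatic mutation incidence
#'
#' Rows are patients, columns are gene symbols; an entry is 1 when the gene
#' carries at least one somatic variant call in that patient. Duplicate
#' variant records collapse to a single 1 at construction.
#'
#' @slot calls binary numeric matrix, patients x genes, with dimnames.
#' @aliases MutationCohort
#' @exportClass MutationCohort
setClass("MutationCohort", representation(calls = "matrix"),
  validity = function(object) .checkBinaryMatrix(object@calls))

#' ExpressionMatrix: continuous sample-by-gene expression values
#'
#' Canonical orientation is samples in rows, genes in columns, whatever the
#' on-disk layout was. Missing values are permitted; consumers decide how to
#' handle them (pairwise-complete correlations, zero z-scores).
#'
#' @slot values numeric matrix, samples x genes, with dimnames.
#' @aliases ExpressionMatrix
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.matrix(v) || !is.numeric(v)) return("values must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      return("values must carry sample rownames and gene colnames")
    if (anyDuplicated(rownames(v))) return("duplicate sample identifiers")
    if (anyDuplicated(colnames(v))) return("duplicate gene symbols")
    if (ncol(v) < 1L) return("gene axis is empty")
    if (any(is.infinite(v))) return("non-finite expression values (use NA for missing)")
    TRUE
  })

#' FunctionalNetwork: undirected simple graph over gene symbols
#'
#' Self-loops and duplicate (including reversed) edges are removed at read
#' time, so a valid object is always a simple undirected graph.
#'
#' @slot nodes character vector of gene symbols.
#' @slot edges two-column character matrix; each row one undirected edge,
#'   stored with endpoints in lexicographic order.
#' @aliases FunctionalNetwork
#' @exportClass FunctionalNetwork
setClass("FunctionalNetwork",
  representation(nodes = "character", edges = "matrix"),
  validity = function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) > 0L) {
      if (!is.character(e)) return("edges must be character")
      if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
      if (any(e[, 1L] > e[, 2L])) return("edges must be stored endpoint-sorted")
      if (anyDuplicated(paste(e[, 1L], e[, 2L]))) return("duplicate edges")
      if (!all(e %in% object@nodes)) return("edge endpoint missing from nodes")
    }
    if (anyDuplicated(object@nodes)) return("duplicate node symbols")
    TRUE
  })

#' GeneSet: a set of gene symbols with a provenance label
#'
#' @slot symbols unique character vector of normalized gene symbols.
#' @slot label free-text provenance tag (e.g. the benchmark source).
#' @aliases GeneSet
#' @exportClass GeneSet
setClass("GeneSet", representation(symbols = "character", label = "character"),
  validity = function(object) {
    if (anyDuplicated(object@symbols)) return("duplicate symbols")
    TRUE
  })

#' OutlyingCalls: per-patient sets of dysregulated (outlying) genes
#'
#' A gene is outlying for a patient when its cohort z-score strictly exceeds
#' the cutoff in absolute value.
#'
#' @slot patients ordered patient identifiers.
#' @slot outlying named list, patient -> character vector of outlying genes.
#' @slot cutoff the z-score cutoff used.
#' @aliases OutlyingCalls
#' @exportClass OutlyingCalls
setClass("OutlyingCalls",
  representation(patients = "character", outlying = "list", cutoff = "numeric"),
  validity = function(object) {
    if (!identical(names(object@outlying), object@patients))
      return("outlying list must be named by patients, in order")
    TRUE
  })

.checkSymmetricMatrix <- function(m, what, zeroOne = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) return(sprintf("%s must be a numeric matrix", what))
  if (nrow(m) != ncol(m)) return(sprintf("%s must be square", what))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return(sprintf("%s must have matching gene dimnames", what))
  if (anyNA(m)) return(sprintf("%s contains NA", what))
  if (!isTRUE(all.equal(m, t(m), tolerance = 0, check.attributes = FALSE)))
    return(sprintf("%s must be symmetric", what))
  if (any(diag(m) != 0)) return(sprintf("%s must have a zero diagonal", what))
  if (zeroOne && (any(m < 0) || any(m > 1)))
    return(sprintf("%s entries must lie in [0,1]", what))
  TRUE
}

#' MutMutMatrix: binary adjacency over retained mutated genes
#'
#' The induced subgraph of the functional network over the mutated genes that
#' survived the dysregulation filter. Isolated genes keep their (all-zero)
#' rows and score zero downstream.
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal.
#' @aliases MutMutMatrix
#' @exportClass MutMutMatrix
setClass("MutMutMatrix", representation(adjacency = "matrix"),
  validity = function(object) {
    msg <- .checkSymmetricMatrix(object@adjacency, "adjacency", zeroOne = TRUE)
    if (!isTRUE(msg)) return(msg)
    if (!all(object@adjacency %in% c(0, 1))) return("adjacency entries must be 0/1")
    TRUE
  })

#' TissuePCCMatrix: thresholded absolute co-expression weights
#'
#' Entry (i,j) is |Pearson r| between genes i and j across the tissue's
#' samples when it strictly exceeds the cutoff, else 0. After cross-tissue
#' averaging entries may fall below the single-tissue cutoff; they are kept.
#'
#' @slot weights symmetric matrix in [0,1], zero diagonal, no NA.
#' @slot tissueLabel free-text tissue tag.
#' @aliases TissuePCCMatrix
#' @exportClass TissuePCCMatrix
setClass("TissuePCCMatrix",
  representation(weights = "matrix", tissueLabel = "character"),
  validity = function(object)
    .checkSymmetricMatrix(object@weights, "weights", zeroOne = TRUE))

#' WeightedMutGraph: the weighted mutated co-expression matrix W
#'
#' W(i,j) is the tissue co-expression weight of the Mut-Mut edge (i,j), or 0
#' where no edge exists or the weight fell below threshold. Degrees d_i count
#' nonzero-weight neighbors.
#'
#' @slot W symmetric nonnegative matrix in [0,1], zero diagonal.
#' @aliases WeightedMutGraph
#' @exportClass WeightedMutGraph
setClass("WeightedMutGraph", representation(W = "matrix"),
  validity = function(object)
    .checkSymmetricMatrix(object@W, "W", zeroOne = TRUE))

#' ECCMatrix: per-edge clustering coefficients
#'
#' Nonzero only on edges of the weighted mutated graph it was computed from.
#'
#' @slot values symmetric nonnegative matrix, zero diagonal.
#' @aliases ECCMatrix
#' @exportClass ECCMatrix
setClass("ECCMatrix", representation(values = "matrix"),
  validity = function(object) {
    msg <- .checkSymmetricMatrix(object@values, "values")
    if (!isTRUE(msg)) return(msg)
    if (any(object@values < 0)) return("ECC values must be nonnegative")
    TRUE
  })

#' DriverScoreTable: per-gene variation frequency, module score, final score
#'
#' Holds V (variation frequency), M (module score, the sum of incident ECC
#' values), F = V * M, and after ranking a rank column that is a permutation
#' of 1..n under the deterministic tie-break (F desc, then V desc, then gene
#' symbol asc).
#'
#' @slot table data.frame with columns gene, V, M, F and, when ranked, rank.
#' @aliases DriverScoreTable
#' @exportClass DriverScoreTable
setClass("DriverScoreTable", representation(table = "data.frame"),
  validity = function(object) {
    tab <- object@table
    need <- c("gene", "V", "M", "F")
    if (!all(need %in% names(tab))) return("table needs columns gene, V, M, F")
    if (anyDuplicated(tab$gene)) return("duplicate genes in score table")
    if (nrow(tab) > 0L) {
      if (any(tab$V < 0 | tab$V > 1)) return("V must lie in [0,1]")
      if (any(tab$M < 0)) return("M must be nonnegative")
      if (!isTRUE(all.equal(tab$F, tab$V * tab$M, tolerance = 1e-12)))
        return("F must equal V * M")
      if ("rank" %in% names(tab) &&
          !identical(sort(as.integer(tab$rank)), seq_len(nrow(tab))))
        return("ranks must be a permutation of 1..n")
    }
    TRUE
  })

#' EvaluationCurve: top-K precision/recall/F-score against a benchmark
#'
#' @slot table data.frame with columns K, TP, FP, FN, precision, recall,
#'   fscore for K = 1..Kmax.
#' @slot benchmarkSize number of benchmark genes inside the ranking universe
#'   (the TP+FN denominator).
#' @slot benchmarkTotal number of benchmark genes before restriction to the
#'   universe, reported alongside for transparency.
#' @aliases EvaluationCurve
#' @exportClass EvaluationCurve
setClass("EvaluationCurve",
  representation(table = "data.frame", benchmarkSize = "integer",
                 benchmarkTotal = "integer"),
  validity = function(object) {
    tab <- object@table
    need <- c("K", "TP", "FP", "FN", "precision", "recall", "fscore")
    if (!all(need %in% names(tab))) return("missing curve columns")
    if (nrow(tab) > 0L && !all(tab$TP + tab$FP == tab$K))
      return("TP + FP must equal K")
    TRUE
  })

#' SyntheticConfig: parameters of the synthetic cohort generator
#'
#' Defaults describe the reference simulation: 500 genes, 100 patients, 80
#' tissue samples, 5 planted modules of 10 genes with 2 drivers each,
#' driver/passenger per-patient mutation rates 0.3/0.02, within-module
#' co-expression loading 0.8, dysregulation shift 3 z-units, background edge
#' probability 0.01, expression noise sd 0.5.
#'
#' @slot nGenes,nPatients,nTissueSamples,nModules,moduleSize,driversPerModule
#'   integer sizes.
#' @slot driverMutRate,passengerMutRate,coexprStrength,backgroundEdgeProb
#'   probabilities / loadings in [0,1].
#' @slot dysregulationShift shift (z-units) added to a mutated driver's
#'   network neighbors.
#' @slot withinModuleEdgeProb edge probability inside a planted module.
#' @slot noiseSd positive noise standard deviation.
#' @slot seed integer random seed.
#' @aliases SyntheticConfig
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nGenes = "integer", nPatients = "integer",
    nTissueSamples = "integer", nModules = "integer", moduleSize = "integer",
    driversPerModule = "integer", driverMutRate = "numeric",
    passengerMutRate = "numeric", coexprStrength = "numeric",
    dysregulationShift = "numeric", backgroundEdgeProb = "numeric",
    withinModuleEdgeProb = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nModules * object@moduleSize > object@nGenes)
      return("nModules * moduleSize must not exceed nGenes")
    if (object@driversPerModule > object@moduleSize)
      return("driversPerModule must not exceed moduleSize")
    probs <- c(object@driverMutRate, object@passengerMutRate,
               object@coexprStrength, object@backgroundEdgeProb,
               object@withinModuleEdgeProb)
    if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0,1]")
    if (object@driverMutRate <= object@passengerMutRate)
      return("driverMutRate must exceed passengerMutRate")
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    TRUE
  })

#' SyntheticCohort: all artifacts of one simulated study
#'
#' @slot network the simulated functional interaction network.
#' @slot tissueExpr tissue co-expression matrix (samples x genes).
#' @slot cohort binary somatic-mutation incidence.
#' @slot tumorExpr tumor expression matrix (patients x genes).
#' @slot truth planted driver genes.
#' @slot modules named list: module id -> member gene symbols.
#' @slot config the generating SyntheticConfig.
#' @aliases SyntheticCohort
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(network = "FunctionalNetwork", tissueExpr = "ExpressionMatrix",
    cohort = "MutationCohort", tumorExpr = "ExpressionMatrix",
    truth = "GeneSet", modules = "list", config = "SyntheticConfig"),
  validity = function(object) {
    if (!all(object@truth@symbols %in% object@network@nodes))
      return("planted drivers must be network nodes")
    TRUE
  })
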