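#' Run the full driver-gene prioritization pipeline
#'
#' Chains the four stages: (1) per-patient outlier calling on tumor
#' expression z-scores and the neighbor-dysregulation filter of mutated
#' genes; (2) construction of the binary Mut-Mut matrix over retained genes;
#' (3) tissue co-expression weighting (per-tissue thresholded |PCC|,
#' averaged across tissues) of the Mut-Mut edges; (4) edge-clustering-
#' coefficient module scores, variation frequencies, final scores
#' F = V * M, and the deterministic descending ranking.
#'
#' Variation frequencies use all mutation calls of a retained gene -- the
#' per-patient filter decides membership in the ranking, not the frequency
#' numerator -- and the denominator is the full patient count of the
#' mutation cohort.
#'
#' @param mutations a \linkS4class{MutationCohort}.
#' @param tumorExpr patients x genes \linkS4class{ExpressionMatrix} of the
#'   same cohort (patient identifiers must overlap).
#' @param network a \linkS4class{FunctionalNetwork}.
#' @param tissueExpr one \linkS4class{ExpressionMatrix} or a list of them,
#'   one per disease-relevant tissue. Alternatively pass a precomputed
#'   \linkS4class{TissuePCCMatrix} (or list of them) to reuse cached
#'   weights.
#' @param zCutoff strict z-score cutoff for outlier calls; default 2.0.
#' @param pccCutoff strict absolute-correlation cutoff; default 0.3.
#' @param perPatient per-patient filter matching (default) or pooled.
#' @param classicEcc use the classical ECC denominator; default FALSE.
#' @param log2Transform apply log2(x + 1) to the tumor expression before
#'   z-scoring; default FALSE.
#' @return a ranked \linkS4class{DriverScoreTable} over the retained mutated
#'   genes, with a \code{diagnostics} attribute (dropped-gene counts, sizes
#'   and thresholds of the run).
#' @examples
#' sc <- simulateCohort(syntheticConfig(nGenes = 80L, nPatients = 40L,
#'   nTissueSamples = 30L, nModules = 2L, moduleSize = 8L, seed = 11L))
#' rk <- rankDriverGenes(sc@cohort, sc@tumorExpr, sc@network, sc@tissueExpr)
#' head(scoreTable(rk))
#' @export
rankDriverGenes <- function(mutations, tumorExpr, network, tissueExpr,
                            zCutoff = 2.0, pccCutoff = 0.3,
                            perPatient = TRUE, classicEcc = FALSE,
                            log2Transform = FALSE) {
  stopifnot(is(mutations, "MutationCohort"),
            is(tumorExpr, "ExpressionMatrix"),
            is(network, "FunctionalNetwork"))
  z <- computeZScores(tumorExpr, log2Transform = log2Transform)
  outl <- callOutlying(z, cutoff = zCutoff)
  retained <- filterMutatedGenes(mutations, outl, network,
                                 perPatient = perPatient)
  mutmut <- buildMutMut(retained, network)
  pcc <- .resolveTissueWeights(tissueExpr, pccCutoff)
  wg <- weightMutMut(mutmut, pcc)
  ecc <- computeECC(wg, classic = classicEcc)
  M <- moduleScore(ecc)
  V <- variationFrequency(mutations, geneList = names(M))
  ranked <- rankGenes(finalScores(M, V))
  attr(ranked, "diagnostics") <- list(
    nPatients = length(patients(mutations)),
    nMutatedGenes = sum(colSums(mutations@calls) > 0),
    nRetained = length(retained),
    dropped = attr(retained, "dropped"),
    zCutoff = zCutoff, pccCutoff = pccCutoff,
    perPatient = perPatient, classicEcc = classicEcc)
  ranked
}

.resolveTissueWeights <- function(tissueExpr, pccCutoff) {
  if (is(tissueExpr, "TissuePCCMatrix")) return(tissueExpr)
  if (is(tissueExpr, "ExpressionMatrix")) tissueExpr <- list(tissueExpr)
  if (!is.list(tissueExpr) || length(tissueExpr) == 0L)
    stop("tissueExpr must be an ExpressionMatrix, a TissuePCCMatrix, or a nonempty list of them")
  if (all(vapply(tissueExpr, is, logical(1L), "TissuePCCMatrix")))
    return(averageTissuePCC(tissueExpr))
  stopifnot(all(vapply(tissueExpr, is, logical(1L), "ExpressionMatrix")))
  mats <- lapply(seq_along(tissueExpr), function(i)
    computeTissuePCC(tissueExpr[[i]], pccCutoff = pccCutoff,
                     tissueLabel = sprintf("tissue%d", i)))
  averageTissuePCC(mats)
}
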