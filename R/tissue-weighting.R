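#' Thresholded absolute co-expression matrix for one tissue
#'
#' Pearson correlation of every gene pair across the tissue's samples,
#' computed over pairwise-complete observations. The stored weight is the
#' absolute correlation when it strictly exceeds \code{pccCutoff}, else 0;
#' pairs with fewer than \code{minPairs} complete samples or with zero
#' variance in either gene get weight 0. Self-correlations are excluded
#' (zero diagonal): only inter-gene edges are ever weighted.
#'
#' @param tissueExpr an \linkS4class{ExpressionMatrix} (samples x genes) of
#'   one tissue; at least 3 samples and 2 genes.
#' @param pccCutoff strict absolute-correlation cutoff; default 0.3.
#' @param minPairs minimum pairwise-complete sample count; default 3.
#' @param tissueLabel free-text tag stored on the result.
#' @return a \linkS4class{TissuePCCMatrix}.
#' @export
computeTissuePCC <- function(tissueExpr, pccCutoff = 0.3, minPairs = 3L,
                             tissueLabel = "tissue") {
  stopifnot(is(tissueExpr, "ExpressionMatrix"))
  x <- tissueExpr@values
  if (nrow(x) < 3L) stop("tissue PCC needs at least 3 samples")
  if (ncol(x) < 2L) stop("tissue PCC needs at least 2 genes")
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  nPairs <- crossprod(!is.na(x))
  r[is.na(r) | nPairs < minPairs] <- 0
  w <- abs(r)
  w[!(w > pccCutoff)] <- 0
  diag(w) <- 0
  # exact symmetry despite floating-point cor() asymmetries
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  new("TissuePCCMatrix", weights = w, tissueLabel = tissueLabel)
}

#' Average thresholded co-expression matrices across tissues
#'
#' Element-wise arithmetic mean over the union of the gene sets; a pair
#' absent (or unmeasured) in a tissue contributes 0 for that tissue. The
#' single-tissue case returns the input unchanged. No re-thresholding is
#' applied after averaging, so averaged weights may legitimately fall below
#' the single-tissue cutoff.
#'
#' @param matrices nonempty list of \linkS4class{TissuePCCMatrix}.
#' @return a \linkS4class{TissuePCCMatrix} over the gene union.
#' @export
averageTissuePCC <- function(matrices) {
  if (is(matrices, "TissuePCCMatrix")) matrices <- list(matrices)
  if (length(matrices) == 0L) stop("need at least one tissue PCC matrix")
  stopifnot(all(vapply(matrices, is, logical(1L), "TissuePCCMatrix")))
  if (length(matrices) == 1L) return(matrices[[1L]])
  allGenes <- sort(unique(unlist(lapply(matrices, genes))))
  acc <- matrix(0, length(allGenes), length(allGenes),
                dimnames = list(allGenes, allGenes))
  for (m in matrices) {
    g <- genes(m)
    acc[g, g] <- acc[g, g] + m@weights
  }
  acc <- acc / length(matrices)
  labels <- vapply(matrices, function(m) m@tissueLabel, character(1L))
  new("TissuePCCMatrix", weights = acc,
      tissueLabel = paste0("mean(", paste(labels, collapse = ", "), ")"))
}

#' Weight the Mut-Mut matrix by tissue co-expression
#'
#' W(i,j) is the tissue-specific co-expression weight of genes i and j where
#' the Mut-Mut adjacency has an edge, and 0 elsewhere: co-expression never
#' creates an edge, it only weights existing ones. Retained genes missing
#' from the PCC matrix keep weight 0 on all their edges (their count is
#' reported as a message).
#'
#' @param mutmut a \linkS4class{MutMutMatrix}.
#' @param pcc a \linkS4class{TissuePCCMatrix}.
#' @return a \linkS4class{WeightedMutGraph} over the Mut-Mut genes.
#' @export
weightMutMut <- function(mutmut, pcc) {
  stopifnot(is(mutmut, "MutMutMatrix"), is(pcc, "TissuePCCMatrix"))
  gs <- genes(mutmut)
  P <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  common <- intersect(gs, genes(pcc))
  if (length(common) < length(gs))
    message(sprintf("tissue weighting: %d retained gene(s) absent from the PCC matrix (weight 0)",
                    length(gs) - length(common)))
  if (length(common) > 0L)
    P[common, common] <- pcc@weights[common, common]
  new("WeightedMutGraph", W = P * mutmut@adjacency)
}
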