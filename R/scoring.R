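#' Edge clustering coefficients of the weighted mutated graph
#'
#' For every edge (i,j) with nonzero weight,
#' \deqn{ECC(i,j) = \frac{\sum_{k \in N_i \cap N_j} (W_{ik} + W_{jk})}{\min(d_i, d_j)}}
#' where N_i is the set of nonzero-weight neighbors of i and d_i = |N_i|.
#' The numerator sums, over the common neighbors k of the edge's endpoints,
#' the weights of the two triangle sides through k; the denominator is the
#' printed min-degree normalizer. Pairs without an edge, or edges without a
#' common neighbor, get ECC 0.
#'
#' The classical ECC literature normalizes by min(d_i - 1, d_j - 1), the
#' number of triangles the edge can participate in; the min-degree form is
#' the method's definition and is the default. \code{classic = TRUE} switches
#' to the classical denominator, guarded below by 1.
#'
#' @param graph a \linkS4class{WeightedMutGraph} (symmetric, nonnegative,
#'   zero diagonal).
#' @param classic use the classical min(d_i - 1, d_j - 1) denominator
#'   (guarded by max(., 1)); default FALSE.
#' @return an \linkS4class{ECCMatrix}.
#' @export
computeECC <- function(graph, classic = FALSE) {
  stopifnot(is(graph, "WeightedMutGraph"))
  W <- graph@W
  if (any(W < 0)) stop("negative weights are not allowed")
  if (!isTRUE(all.equal(W, t(W), tolerance = 0, check.attributes = FALSE)))
    stop("W must be symmetric")
  A <- (W != 0) * 1
  d <- rowSums(A)
  # numerator over common neighbors: W_ik = 0 unless k in N_i, A_kj = 0
  # unless k in N_j, so (W A)_ij + (A W)_ij sums W_ik + W_jk over N_i o N_j
  num <- W %*% A + A %*% W
  den <- if (classic) pmax(outer(d - 1, d - 1, pmin), 1)
         else outer(d, d, pmin)
  ecc <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  edge <- A == 1
  ecc[edge] <- num[edge] / den[edge]
  ecc[lower.tri(ecc)] <- t(ecc)[lower.tri(ecc)]
  new("ECCMatrix", values = ecc)
}

#' Per-gene module scores
#'
#' M_i is the sum of the ECC values of gene i's incident edges; genes with
#' no nonzero-ECC edge (including isolated genes) get M = 0. A large M marks
#' a gene whose interactions are embedded in a densely co-expressed module.
#'
#' @param ecc an \linkS4class{ECCMatrix}.
#' @return named numeric vector of module scores.
#' @export
moduleScore <- function(ecc) {
  stopifnot(is(ecc, "ECCMatrix"))
  rowSums(ecc@values)
}

#' Variation frequency of each gene
#'
#' V_i is the fraction of cohort patients in which gene i carries a somatic
#' mutation call. Genes absent from the cohort get V = 0.
#'
#' @param cohort a \linkS4class{MutationCohort} with at least one patient.
#' @param geneList genes to report, in order; defaults to the cohort's genes.
#' @return named numeric vector of frequencies in [0,1].
#' @export
variationFrequency <- function(cohort, geneList = genes(cohort)) {
  stopifnot(is(cohort, "MutationCohort"))
  n <- nrow(cohort@calls)
  if (n == 0L) stop("cohort has no patients")
  v <- setNames(numeric(length(geneList)), geneList)
  present <- intersect(geneList, genes(cohort))
  v[present] <- colSums(cohort@calls[, present, drop = FALSE]) / n
  v
}

#' Combine module scores and variation frequencies into final scores
#'
#' F_i = V_i * M_i for every gene; a gene scores 0 when it is never mutated
#' or when its module score is 0. The returned table is unranked; pass it to
#' \code{\link{rankGenes}}.
#'
#' @param M named numeric vector of module scores.
#' @param V named numeric vector of variation frequencies over the same
#'   genes.
#' @return an unranked \linkS4class{DriverScoreTable}.
#' @export
finalScores <- function(M, V) {
  missingV <- setdiff(names(M), names(V))
  missingM <- setdiff(names(V), names(M))
  if (length(missingV) || length(missingM))
    stop("module-score and frequency gene sets differ; missing from V: ",
         paste(missingV, collapse = ", "), "; missing from M: ",
         paste(missingM, collapse = ", "))
  gs <- names(M)
  V <- V[gs]
  tab <- data.frame(gene = gs, V = unname(V), M = unname(M),
                    F = unname(V * M), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("DriverScoreTable", table = tab)
}

#' Rank genes by final score
#'
#' Deterministic descending order on F, with ties broken by V descending and
#' then gene symbol ascending, so identical inputs always produce
#' byte-identical rankings. Ranks are a permutation of 1..n (no shared
#' ranks).
#'
#' @param table a \linkS4class{DriverScoreTable}.
#' @return the table sorted in rank order with a \code{rank} column.
#' @export
rankGenes <- function(table) {
  stopifnot(is(table, "DriverScoreTable"))
  tab <- table@table
  ord <- order(-tab$F, -tab$V, tab$gene, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("DriverScoreTable", table = tab)
}
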