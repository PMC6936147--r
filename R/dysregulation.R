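#' Per-gene cohort z-scores of a tumor expression matrix
#'
#' For each gene the z-score of sample s is (x - mean) / sd with mean and
#' sample standard deviation (n - 1 denominator) taken across all samples of
#' the cohort, so values are bit-reproducible across platforms. Genes with
#' zero variance, or with fewer than two finite values, get z = 0 for every
#' sample (they can never be called outlying); the latter case also raises a
#' warning.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (samples x genes). Missing
#'   values propagate as z = NA for the missing cells only.
#' @param log2Transform apply log2(x + 1) before standardizing (off by
#'   default; expression inputs are assumed already on a comparable scale).
#' @return an \linkS4class{ExpressionMatrix} of z-scores.
#' @export
computeZScores <- function(expr, log2Transform = FALSE) {
  stopifnot(is(expr, "ExpressionMatrix"))
  x <- expr@values
  if (log2Transform) {
    if (any(x < -1, na.rm = TRUE)) stop("log2(x + 1) undefined for values < -1")
    x <- log2(x + 1)
  }
  nFinite <- colSums(is.finite(x))
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2L, sd, na.rm = TRUE)
  degenerate <- nFinite < 2L
  if (any(degenerate)) {
    warning(sprintf("%d gene(s) with fewer than 2 finite values; z set to 0",
                    sum(degenerate)))
    mu[degenerate] <- 0
    sdv[degenerate] <- NA
  }
  flat <- degenerate | is.na(sdv) | sdv == 0
  sdv[flat] <- Inf   # z collapses to 0 for constant / degenerate genes
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  z[, flat] <- 0
  new("ExpressionMatrix", values = z)
}

#' Call per-patient outlying (dysregulated) genes
#'
#' A gene is outlying for a patient when its z-score strictly exceeds the
#' cutoff or falls strictly below its negative; a z-score of exactly +/- the
#' cutoff is not outlying. Missing z-scores never produce a call.
#'
#' @param z z-score \linkS4class{ExpressionMatrix} from
#'   \code{\link{computeZScores}}.
#' @param cutoff positive z cutoff; default 2.0.
#' @return an \linkS4class{OutlyingCalls}.
#' @export
callOutlying <- function(z, cutoff = 2.0) {
  stopifnot(is(z, "ExpressionMatrix"), is.numeric(cutoff), cutoff > 0)
  zm <- z@values
  hit <- !is.na(zm) & (zm > cutoff | zm < -cutoff)
  pats <- rownames(zm)
  out <- lapply(seq_along(pats), function(i) colnames(zm)[hit[i, ]])
  names(out) <- pats
  new("OutlyingCalls", patients = pats, outlying = out, cutoff = cutoff)
}

# patients x genes logical matrix of outlier calls over the given gene universe
.outlyingMatrix <- function(calls, geneUniverse) {
  m <- matrix(FALSE, nrow = length(calls@patients), ncol = length(geneUniverse),
              dimnames = list(calls@patients, geneUniverse))
  for (p in calls@patients) {
    g <- intersect(calls@outlying[[p]], geneUniverse)
    if (length(g)) m[p, g] <- TRUE
  }
  m
}

.adjacencyMatrix <- function(net, geneUniverse) {
  A <- matrix(0, length(geneUniverse), length(geneUniverse),
              dimnames = list(geneUniverse, geneUniverse))
  e <- net@edges
  keep <- e[, 1L] %in% geneUniverse & e[, 2L] %in% geneUniverse
  e <- e[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Filter mutated genes by neighbor dysregulation
#'
#' The core admission rule of the pipeline: a mutated gene is retained when
#' at least one of its functional-network neighbors is transcriptionally
#' outlying in a patient carrying the mutation. By default the match is
#' per-patient (the mutation and the neighbor's dysregulation must co-occur
#' in the same patient); \code{perPatient = FALSE} relaxes this to a pooled
#' rule where any patient's outlier suffices, for sensitivity analysis. The
#' retained set is the union over patients. A gene's own outlying status
#' never counts -- only neighbors do.
#'
#' @param cohort a \linkS4class{MutationCohort}.
#' @param calls an \linkS4class{OutlyingCalls} over the same patients.
#' @param net a \linkS4class{FunctionalNetwork}.
#' @param perPatient require mutation and neighbor dysregulation in the same
#'   patient (default TRUE).
#' @return sorted character vector of retained mutated gene symbols, with a
#'   \code{dropped} attribute giving counts of mutated genes excluded at each
#'   stage (not in network, no dysregulated neighbor).
#' @export
filterMutatedGenes <- function(cohort, calls, net, perPatient = TRUE) {
  stopifnot(is(cohort, "MutationCohort"), is(calls, "OutlyingCalls"),
            is(net, "FunctionalNetwork"))
  common <- intersect(patients(cohort), calls@patients)
  if (length(common) == 0L)
    stop("no overlap between mutation-cohort patients and expression patients")
  mut <- cohort@calls[common, , drop = FALSE]
  mutated <- colnames(mut)[colSums(mut) > 0]
  inNet <- intersect(mutated, net@nodes)
  universe <- net@nodes
  A <- .adjacencyMatrix(net, universe)
  O <- .outlyingMatrix(calls, universe)[common, , drop = FALSE]
  # count of outlying network neighbors per (patient, gene)
  nOut <- O %*% A
  retained <- character(0)
  if (length(inNet) > 0L) {
    if (perPatient) {
      hits <- mut[, inNet, drop = FALSE] == 1 & nOut[, inNet, drop = FALSE] > 0
      retained <- inNet[colSums(hits) > 0]
    } else {
      anyOut <- colSums(nOut[, inNet, drop = FALSE]) > 0
      retained <- inNet[colSums(mut[, inNet, drop = FALSE]) > 0 & anyOut]
    }
  }
  retained <- sort(retained)
  attr(retained, "dropped") <- c(
    notInNetwork = length(mutated) - length(inNet),
    noDysregulatedNeighbor = length(inNet) - length(retained))
  retained
}

#' Build the binary Mut-Mut matrix
#'
#' The adjacency matrix of the functional-network subgraph induced by the
#' retained mutated genes. Retained genes with no retained neighbor stay as
#' isolated all-zero rows; they score zero downstream.
#'
#' @param retained character vector of retained mutated genes (from
#'   \code{\link{filterMutatedGenes}}).
#' @param net a \linkS4class{FunctionalNetwork}.
#' @return a \linkS4class{MutMutMatrix} over \code{sort(retained)}.
#' @export
buildMutMut <- function(retained, net) {
  stopifnot(is(net, "FunctionalNetwork"))
  retained <- sort(unique(as.character(retained)))
  if (length(retained) == 0L)
    stop("empty retained gene set: the dysregulation filter admitted no gene")
  g <- igraph::graph_from_data_frame(
    as.data.frame(net@edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = net@nodes)
  sub <- igraph::induced_subgraph(g, intersect(retained, net@nodes))
  A <- matrix(0, length(retained), length(retained),
              dimnames = list(retained, retained))
  if (igraph::ecount(sub) > 0L) {
    e <- igraph::as_edgelist(sub)
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  new("MutMutMatrix", adjacency = A)
}
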