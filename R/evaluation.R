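#' Top-K precision, recall and F-score against a benchmark gene set
#'
#' For each K = 1..Kmax the top-K ranked genes are taken as predicted
#' drivers. TP counts predictions in the benchmark, FP = K - TP, and FN
#' counts benchmark genes in the candidate universe (genes present in the
#' ranking) not among the top K: genes the method never scored cannot be
#' retrieved at any K, so the recall denominator is the benchmark restricted
#' to the universe. The unrestricted benchmark size is carried alongside in
#' the result for transparency. F-score is the harmonic mean of precision
#' and recall, defined as 0 when both are 0.
#'
#' @param ranking a ranked \linkS4class{DriverScoreTable}.
#' @param benchmark a nonempty \linkS4class{GeneSet} of known drivers.
#' @param kMax largest K; default 200, truncated with a warning when the
#'   ranking is shorter.
#' @return an \linkS4class{EvaluationCurve}.
#' @export
evaluateTopK <- function(ranking, benchmark, kMax = 200L) {
  stopifnot(is(ranking, "DriverScoreTable"), is(benchmark, "GeneSet"))
  tab <- ranking@table
  if (nrow(tab) == 0L) stop("ranking is empty")
  if (!"rank" %in% names(tab)) stop("ranking must be ranked (see rankGenes)")
  if (length(benchmark@symbols) == 0L) stop("benchmark gene set is empty")
  kMax <- as.integer(kMax)
  if (kMax > nrow(tab)) {
    warning(sprintf("kMax %d exceeds ranking length %d; truncating", kMax, nrow(tab)))
    kMax <- nrow(tab)
  }
  ordGenes <- tab$gene[order(tab$rank)]
  inBench <- ordGenes %in% benchmark@symbols
  nBench <- sum(inBench)                    # benchmark inside the universe
  ks <- seq_len(kMax)
  tp <- cumsum(inBench)[ks]
  fp <- ks - tp
  fn <- nBench - tp
  precision <- tp / ks
  recall <- if (nBench > 0L) tp / nBench else rep(0, kMax)
  fscore <- ifelse(precision + recall > 0,
                   2 * precision * recall / (precision + recall), 0)
  new("EvaluationCurve",
      table = data.frame(K = ks, TP = tp, FP = fp, FN = fn,
                         precision = precision, recall = recall,
                         fscore = fscore),
      benchmarkSize = as.integer(nBench),
      benchmarkTotal = length(benchmark@symbols))
}

#' Frequency-only baseline ranking
#'
#' Ranks genes by variation frequency alone (M fixed at 1 so F = V), with
#' the same deterministic tie-break as \code{\link{rankGenes}}. A sanity
#' baseline: any advantage of the full method over this ranking is
#' attributable to the network/co-expression machinery.
#'
#' @param cohort a \linkS4class{MutationCohort}.
#' @return a ranked \linkS4class{DriverScoreTable} over all cohort genes.
#' @export
frequencyBaseline <- function(cohort) {
  stopifnot(is(cohort, "MutationCohort"))
  V <- variationFrequency(cohort)
  M <- setNames(rep(1, length(V)), names(V))
  rankGenes(finalScores(M, V))
}

#' Write a top-K evaluation curve to TSV
#'
#' @param curve an \linkS4class{EvaluationCurve}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "EvaluationCurve"))
  tab <- curve@table
  for (col in c("precision", "recall", "fscore"))
    tab[[col]] <- sprintf("%.15g", tab[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0L)
    writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  invisible(path)
}

#' Plot precision/recall/F-score curves
#'
#' Draws the three top-K curves of one or more evaluations on a shared axis
#' with base graphics.
#'
#' @param curves a named list of \linkS4class{EvaluationCurve} (names are
#'   used in the legend), or a single curve.
#' @param metric one of \code{"precision"}, \code{"recall"}, \code{"fscore"}.
#' @param ... passed to \code{matplot}.
#' @return invisibly, NULL.
#' @importFrom graphics matplot legend
#' @export
plotCurves <- function(curves, metric = c("fscore", "precision", "recall"), ...) {
  metric <- match.arg(metric)
  if (is(curves, "EvaluationCurve")) curves <- list(curve = curves)
  ys <- lapply(curves, function(cv) cv@table[[metric]])
  kMax <- max(vapply(curves, function(cv) max(cv@table$K), numeric(1L)))
  y <- sapply(ys, function(v) c(v, rep(NA, kMax - length(v))))
  matplot(seq_len(kMax), y, type = "l", lty = 1, xlab = "top K genes",
          ylab = metric, ...)
  legend("bottomright", legend = names(curves), lty = 1,
         col = seq_along(curves), bty = "n")
  invisible(NULL)
}
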