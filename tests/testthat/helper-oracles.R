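# Independent brute-force oracles and small builders shared across tests.
# These deliberately avoid the package's vectorized code paths: the ECC and
# PCC oracles enumerate pair-by-pair with scalar arithmetic.

# edge clustering coefficient by direct pairwise enumeration
bruteECC <- function(W, classic = FALSE) {
  n <- nrow(W)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- sum(W[i, ] != 0)
  ecc <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || W[i, j] == 0) next
    num <- 0
    for (k in seq_len(n))
      if (k != i && k != j && W[i, k] != 0 && W[j, k] != 0)
        num <- num + W[i, k] + W[j, k]
    den <- if (classic) max(min(d[i] - 1, d[j] - 1), 1) else min(d[i], d[j])
    ecc[i, j] <- num / den
  }
  ecc
}

# thresholded |Pearson r| by two-pass scalar covariance, pairwise complete
brutePCC <- function(x, cutoff = 0.3, minPairs = 3L) {
  n <- ncol(x)
  w <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    if (sum(ok) < minPairs) next
    a <- x[ok, i]; b <- x[ok, j]
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    sab <- sum((a - ma) * (b - mb))
    sa <- sum((a - ma)^2); sb <- sum((b - mb)^2)
    if (sa == 0 || sb == 0) next
    r <- abs(sab / sqrt(sa * sb))
    if (r > cutoff) { w[i, j] <- r; w[j, i] <- r }
  }
  w
}

# random symmetric nonnegative weight matrix with zero diagonal
randomWeightedGraph <- function(n, p = 0.3) {
  W <- matrix(0, n, n, dimnames = list(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (runif(1) < p) {
      w <- runif(1)
      W[i, j] <- w; W[j, i] <- w
    }
  }
  new("WeightedMutGraph", W = W)
}

makeExpr <- function(values, samples = NULL, genes = NULL) {
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, genes)
  new("ExpressionMatrix", values = values)
}

makeCohort <- function(calls, patients = NULL, genes = NULL) {
  if (is.null(patients)) patients <- sprintf("P%d", seq_len(nrow(calls)))
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(ncol(calls)))
  dimnames(calls) <- list(patients, genes)
  new("MutationCohort", calls = calls)
}

makeNet <- function(...) FunctionalNetwork(do.call(rbind, list(...)))

toyPath <- function(f) system.file("extdata", "toy", f, package = "dytidriver")
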