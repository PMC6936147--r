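test_that("z-scores use cohort mean and n-1 sd, with degenerate genes zeroed", {
  e <- makeExpr(cbind(c(1, 2, 3), c(5, 5, 5)))
  z <- exprValues(computeZScores(e))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))      # sample sd of (1,2,3) is 1
  expect_equal(unname(z[, 2]), c(0, 0, 0))       # zero-variance rule
  # centering identity
  set.seed(3)
  e2 <- makeExpr(matrix(rnorm(40), nrow = 8))
  z2 <- exprValues(computeZScores(e2))
  expect_true(all(abs(colSums(z2)) < 1e-12))
  # fewer than 2 finite values -> zeroed with a warning
  e3 <- makeExpr(cbind(c(1, NA, NA), c(1, 2, 3)))
  expect_warning(z3 <- computeZScores(e3), "fewer than 2 finite")
  expect_equal(unname(exprValues(z3)[, 1]), c(0, 0, 0))
})

test_that("outlier calls are strict at the cutoff", {
  z <- makeExpr(cbind(c(2.0, -2.5, 0), c(2.0 + 1e-9, -2.0, 1.9)),
                genes = c("GA", "GB"))
  calls <- callOutlying(z, cutoff = 2.0)
  expect_identical(outlyingGenes(calls, "S1"), "GB")  # 2.0 exact is NOT outlying
  expect_identical(outlyingGenes(calls, "S2"), "GA")  # -2.5 is; -2.0 exact is not
  expect_identical(outlyingGenes(calls, "S3"), character(0))
  zeroZ <- makeExpr(matrix(0, 3, 4))
  allEmpty <- callOutlying(zeroZ)
  expect_true(all(lengths(allEmpty@outlying) == 0L))
})

test_that("mutated genes are retained only with a dysregulated neighbor in the same patient", {
  net <- makeNet(c("G", "H"), c("X", "Y"))
  # g mutated in P1 only; neighbor h outlying in P1 -> retained
  cohort <- makeCohort(rbind(c(1, 0), c(0, 0)), genes = c("G", "X"))
  out1 <- new("OutlyingCalls", patients = c("P1", "P2"),
              outlying = list(P1 = "H", P2 = character(0)), cutoff = 2)
  expect_identical(as.character(filterMutatedGenes(cohort, out1, net)), "G")
  # h outlying only in P2 while g mutated in P1 -> not retained per patient
  out2 <- new("OutlyingCalls", patients = c("P1", "P2"),
              outlying = list(P1 = character(0), P2 = "H"), cutoff = 2)
  expect_length(filterMutatedGenes(cohort, out2, net), 0L)
  # ... but retained under the pooled mode
  expect_identical(
    as.character(filterMutatedGenes(cohort, out2, net, perPatient = FALSE)), "G")
  # mutated gene absent from the network is never retained
  cohort2 <- makeCohort(rbind(c(1, 1), c(0, 0)), genes = c("G", "ZZ"))
  r <- filterMutatedGenes(cohort2, out1, net)
  expect_identical(as.character(r), "G")
  expect_equal(attr(r, "dropped")[["notInNetwork"]], 1L)
  # a gene's own outlying status does not count, only neighbors'
  outSelf <- new("OutlyingCalls", patients = c("P1", "P2"),
                 outlying = list(P1 = "G", P2 = character(0)), cutoff = 2)
  expect_length(filterMutatedGenes(cohort, outSelf, net), 0L)
  # no patient overlap is a configuration error
  outQ <- new("OutlyingCalls", patients = "Q9",
              outlying = list(Q9 = "H"), cutoff = 2)
  expect_error(filterMutatedGenes(cohort, outQ, net), "overlap")
})

test_that("enlarging a patient's outlying set never shrinks the retained set", {
  set.seed(202)
  for (rep in 1:10) {
    nG <- 8L; nP <- 4L
    gs <- LETTERS[1:nG]
    calls <- matrix(rbinom(nP * nG, 1, 0.4), nP, nG,
                    dimnames = list(sprintf("P%d", 1:nP), gs))
    pairs <- t(combn(gs, 2))
    net <- FunctionalNetwork(pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE])
    baseSets <- lapply(1:nP, function(i) sample(gs, sample(0:3, 1)))
    names(baseSets) <- sprintf("P%d", 1:nP)
    outA <- new("OutlyingCalls", patients = names(baseSets),
                outlying = baseSets, cutoff = 2)
    grown <- baseSets
    grown[[1]] <- union(grown[[1]], sample(gs, 2))
    outB <- new("OutlyingCalls", patients = names(grown),
                outlying = grown, cutoff = 2)
    cohort <- new("MutationCohort", calls = calls)
    rA <- filterMutatedGenes(cohort, outA, net)
    rB <- filterMutatedGenes(cohort, outB, net)
    expect_true(all(rA %in% rB))
  }
})

test_that("the Mut-Mut matrix is the induced subgraph adjacency", {
  net <- makeNet(c("A", "B"), c("B", "C"), c("C", "D"))
  mm <- buildMutMut(c("A", "B", "C"), net)
  A <- edgeWeights(mm)
  expect_identical(rownames(A), c("A", "B", "C"))
  expect_equal(A["A", "B"], 1); expect_equal(A["B", "C"], 1)
  expect_equal(A["A", "C"], 0)
  expect_identical(A, t(A))
  one <- buildMutMut("A", makeNet(c("X", "Y")))
  expect_equal(unname(edgeWeights(one)), matrix(0, 1, 1))
  expect_error(buildMutMut(character(0), net), "empty retained")
})

test_that("induced adjacency never invents edges absent from the network", {
  set.seed(303)
  for (rep in 1:10) {
    gs <- sprintf("N%02d", 1:12)
    pairs <- t(combn(gs, 2))
    net <- FunctionalNetwork(pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE],
                             nodes = gs)
    retained <- sample(gs, 6)
    A <- edgeWeights(buildMutMut(retained, net))
    e <- networkEdges(net)
    full <- matrix(0, 12, 12, dimnames = list(gs, gs))
    if (nrow(e)) { full[e] <- 1; full[e[, 2:1, drop = FALSE]] <- 1 }
    expect_identical(A, full[rownames(A), colnames(A)])
  }
})
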