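.smallCfg <- function(seed = 5L, ...) {
  syntheticConfig(nGenes = 40L, nPatients = 25L, nTissueSamples = 30L,
                  nModules = 2L, moduleSize = 5L, driversPerModule = 1L,
                  seed = seed, ...)
}

test_that("simulation is fully deterministic under its seed", {
  a <- simulateCohort(.smallCfg())
  b <- simulateCohort(.smallCfg())
  expect_identical(networkEdges(a@network), networkEdges(b@network))
  expect_identical(exprValues(a@tissueExpr), exprValues(b@tissueExpr))
  expect_identical(mutationCalls(a@cohort), mutationCalls(b@cohort))
  expect_identical(exprValues(a@tumorExpr), exprValues(b@tumorExpr))
  expect_identical(genes(plantedDrivers(a)), genes(plantedDrivers(b)))
  c <- simulateCohort(.smallCfg(seed = 6L))
  expect_false(identical(mutationCalls(a@cohort), mutationCalls(c@cohort)))
})

test_that("with zero background probability all edges lie inside the module", {
  cfg <- syntheticConfig(nGenes = 12L, nPatients = 10L, nTissueSamples = 10L,
                         nModules = 1L, moduleSize = 4L, driversPerModule = 1L,
                         backgroundEdgeProb = 0, withinModuleEdgeProb = 1,
                         seed = 2L)
  sc <- simulateCohort(cfg)
  e <- networkEdges(sc@network)
  mod <- moduleAssignments(sc)[[1]]
  expect_true(all(e %in% mod))
  expect_equal(nrow(e), choose(4, 2))   # edge prob 1: the full clique
  expect_true(all(genes(plantedDrivers(sc)) %in% mod))
})

test_that("within-module edge density matches its binomial expectation", {
  counts <- vapply(1:20, function(s) {
    sc <- simulateCohort(.smallCfg(seed = s, backgroundEdgeProb = 0))
    nrow(networkEdges(sc@network))
  }, numeric(1))
  # 2 modules x C(5,2) pairs at prob 0.9
  expect_gte(mean(counts), 0.8 * 2 * choose(5, 2))
  expect_lte(mean(counts), 2 * choose(5, 2))
})

test_that("module co-expression strength drives the within-module correlation", {
  withinAbsPCC <- function(coexpr, noiseSd, seed) {
    set.seed(seed)
    cfg <- .smallCfg(coexprStrength = coexpr, noiseSd = noiseSd)
    net <- generateNetwork(cfg)
    tis <- generateTissueExpression(cfg, net$modules)
    r <- abs(cor(exprValues(tis)))
    mods <- net$modules
    within <- unlist(lapply(mods, function(m) {
      rm <- r[m, m]; rm[upper.tri(rm)]
    }))
    others <- setdiff(colnames(r), unlist(mods))
    rb <- r[others, others]
    list(within = within, background = rb[upper.tri(rb)])
  }
  # strong loading: mean within-module |r| clears the 0.3 weighting cutoff
  strong <- unlist(lapply(1:20, function(s) withinAbsPCC(0.9, 0.3, s)$within))
  expect_gt(mean(strong), 0.3)
  # zero loading: within-module correlations indistinguishable from background
  w0 <- c(); b0 <- c()
  for (s in 1:20) {
    res <- withinAbsPCC(0, 0.5, s)
    w0 <- c(w0, res$within); b0 <- c(b0, res$background)
  }
  expect_gt(t.test(w0, b0)$p.value, 0.01)
})

test_that("planted drivers mutate at the configured rate and dysregulate neighbors", {
  # rate-1 drivers are mutated in every patient
  cfg1 <- .smallCfg(driverMutRate = 1)
  sc1 <- simulateCohort(cfg1)
  V <- variationFrequency(sc1@cohort, genes(plantedDrivers(sc1)))
  expect_true(all(V == 1))
  # a 4-sd shift makes the overwhelming majority of mutated-driver neighbors
  # outlying in the affected patients (aggregated over 30 seeds). The carrier
  # rate is kept low so the cohort z denominator stays near the baseline sd
  # and the Normal-tail prediction P(|z| > 2 | shift 4) ~ 0.97 applies.
  hits <- 0L; total <- 0L
  for (s in 1:30) {
    cfg <- syntheticConfig(nGenes = 60L, nPatients = 200L, nTissueSamples = 20L,
                           nModules = 2L, moduleSize = 6L, driversPerModule = 1L,
                           driverMutRate = 0.005, passengerMutRate = 0.002,
                           dysregulationShift = 4, seed = 1000L + s)
    sc <- simulateCohort(cfg)
    z <- exprValues(computeZScores(sc@tumorExpr))
    adj <- edgeWeights(buildMutMut(networkNodes(sc@network), sc@network))
    for (d in genes(plantedDrivers(sc))) {
      nbrs <- colnames(adj)[adj[d, ] == 1]
      carriers <- rownames(mutationCalls(sc@cohort))[mutationCalls(sc@cohort)[, d] == 1]
      if (!length(nbrs) || !length(carriers)) next
      zz <- abs(z[carriers, nbrs, drop = FALSE])
      hits <- hits + sum(zz > 2); total <- total + length(zz)
    }
  }
  expect_gt(total, 100L)
  expect_gte(hits / total, 0.95)
  # zero shift: outlier rate among neighbors is just the background tail
  set.seed(9)
  cfg0 <- .smallCfg(dysregulationShift = 0)
  rate <- mean(vapply(1:20, function(s) {
    sc <- simulateCohort(.smallCfg(dysregulationShift = 0, seed = 2000L + s))
    z <- exprValues(computeZScores(sc@tumorExpr))
    mean(abs(z) > 2)
  }, numeric(1)))
  expect_gt(rate, 0.02); expect_lt(rate, 0.08)
})

test_that("written cohorts re-read into the pipeline's input types", {
  sc <- simulateCohort(.smallCfg())
  d <- tempfile("cohort")
  paths <- writeCohort(sc, d)
  mc <- readMutations(paths[["mutations"]], format = "binary")
  expect_identical(mutationCalls(mc), mutationCalls(sc@cohort))
  te <- readExpression(paths[["tissue_expr"]])
  expect_equal(exprValues(te), exprValues(sc@tissueExpr), tolerance = 1e-12)
  net <- readNetwork(paths[["network"]])
  expect_identical(networkEdges(net), networkEdges(sc@network))
  truth <- readGeneSet(paths[["truth"]])
  expect_identical(genes(truth), genes(plantedDrivers(sc)))
})
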