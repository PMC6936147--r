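#' Configuration for the synthetic cohort generator
#'
#' The generator encodes exactly the three assumptions the ranking method
#' exploits -- driver genes are (i) recurrently mutated, (ii) embedded in
#' network modules that are co-expressed in the relevant tissue, and (iii)
#' dysregulate their network neighbors when mutated -- and nothing else, so
#' recovery of the planted drivers is attributable to those mechanics.
#'
#' Defaults describe the reference simulation: 500 genes, 100 patients, 80
#' tissue samples; 5 modules of 10 genes, 2 planted drivers per module;
#' per-patient mutation probability 0.3 for drivers and 0.02 for passengers;
#' within-module latent-factor loading 0.8 with expression noise sd 0.5
#' (giving a theoretical within-module correlation of
#' 0.8^2 / (0.8^2 + 0.5^2) ~ 0.72, comfortably above the 0.3 weighting
#' cutoff); a dysregulation shift of 3 z-units on a mutated driver's
#' neighbors; within-module edge probability 0.9 over a background
#' Erdos-Renyi density of 0.01.
#'
#' @param nGenes,nPatients,nTissueSamples,nModules,moduleSize,driversPerModule
#'   integer sizes.
#' @param driverMutRate,passengerMutRate per-patient mutation probabilities;
#'   the driver rate must exceed the passenger rate.
#' @param coexprStrength latent-factor loading of module genes in [0,1].
#' @param dysregulationShift expression shift (in baseline sd units) applied
#'   to each network neighbor of a mutated driver.
#' @param backgroundEdgeProb Erdos-Renyi background edge probability.
#' @param withinModuleEdgeProb edge probability inside a planted module.
#' @param noiseSd tissue expression noise sd.
#' @param seed integer seed for the single random stream of the cohort.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGenes = 500L, nPatients = 100L,
                            nTissueSamples = 80L, nModules = 5L,
                            moduleSize = 10L, driversPerModule = 2L,
                            driverMutRate = 0.3, passengerMutRate = 0.02,
                            coexprStrength = 0.8, dysregulationShift = 3,
                            backgroundEdgeProb = 0.01,
                            withinModuleEdgeProb = 0.9, noiseSd = 0.5,
                            seed = 1L) {
  new("SyntheticConfig", nGenes = as.integer(nGenes),
      nPatients = as.integer(nPatients),
      nTissueSamples = as.integer(nTissueSamples),
      nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
      driversPerModule = as.integer(driversPerModule),
      driverMutRate = driverMutRate, passengerMutRate = passengerMutRate,
      coexprStrength = coexprStrength,
      dysregulationShift = dysregulationShift,
      backgroundEdgeProb = backgroundEdgeProb,
      withinModuleEdgeProb = withinModuleEdgeProb, noiseSd = noiseSd,
      seed = as.integer(seed))
}

.geneNames <- function(n) sprintf("G%04d", seq_len(n))
.patientNames <- function(n) sprintf("P%03d", seq_len(n))
.sampleNames <- function(n) sprintf("S%03d", seq_len(n))

#' Generate a network with planted dense modules
#'
#' Module genes are the first \code{nModules * moduleSize} genes, assigned in
#' consecutive blocks; each module is a dense subgraph (edge probability
#' \code{withinModuleEdgeProb}) over an Erdos-Renyi background at
#' \code{backgroundEdgeProb}. Draws from the current random stream; seed the
#' stream (or use \code{\link{simulateCohort}}) for determinism.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return list with \code{network} (a \linkS4class{FunctionalNetwork} over
#'   all \code{nGenes} genes) and \code{modules} (named list of member gene
#'   symbols).
#' @export
generateNetwork <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  gs <- .geneNames(cfg@nGenes)
  modules <- lapply(seq_len(cfg@nModules), function(m)
    gs[((m - 1L) * cfg@moduleSize + 1L):(m * cfg@moduleSize)])
  names(modules) <- sprintf("module%02d", seq_len(cfg@nModules))
  edges <- list()
  # draw order: module edges first (module by module), then background
  for (m in modules) {
    pairs <- t(combn(m, 2L))
    keep <- rbinom(nrow(pairs), 1L, cfg@withinModuleEdgeProb) == 1L
    edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
  }
  idx <- which(upper.tri(matrix(0, cfg@nGenes, cfg@nGenes)), arr.ind = TRUE)
  keep <- rbinom(nrow(idx), 1L, cfg@backgroundEdgeProb) == 1L
  edges[[length(edges) + 1L]] <-
    cbind(gs[idx[keep, 1L]], gs[idx[keep, 2L]])
  e <- do.call(rbind, edges)
  if (nrow(e) > 0L) {
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, 2:1]
    e <- unique(e)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  list(network = new("FunctionalNetwork", nodes = gs, edges = e),
       modules = modules)
}

#' Generate tissue expression with co-expressed modules
#'
#' One latent factor per module per sample: a module gene's value is
#' \code{coexprStrength * f_m(s) + noise}, a non-module gene's value is pure
#' noise, with noise ~ Normal(0, noiseSd). The expected within-module
#' correlation is lambda^2 / (lambda^2 + sigma^2). Draws from the current
#' random stream (factors first, then the noise matrix).
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param modules named list of module member genes (from
#'   \code{\link{generateNetwork}}).
#' @return an \linkS4class{ExpressionMatrix}, tissue samples x genes.
#' @export
generateTissueExpression <- function(cfg, modules) {
  stopifnot(is(cfg, "SyntheticConfig"))
  gs <- .geneNames(cfg@nGenes)
  ns <- cfg@nTissueSamples
  factors <- matrix(rnorm(ns * length(modules)), nrow = ns)
  x <- matrix(rnorm(ns * cfg@nGenes, sd = cfg@noiseSd), nrow = ns,
              dimnames = list(.sampleNames(ns), gs))
  for (m in seq_along(modules))
    x[, modules[[m]]] <- x[, modules[[m]]] + cfg@coexprStrength * factors[, m]
  new("ExpressionMatrix", values = x)
}

#' Generate somatic mutations and driver-conditioned tumor expression
#'
#' The planted drivers are the first \code{driversPerModule} genes of each
#' module. Each gene mutates independently per patient (drivers at
#' \code{driverMutRate}, all others at \code{passengerMutRate}). Tumor
#' expression starts from i.i.d. Normal(0,1) baselines; in every patient
#' carrying a mutated driver, each network neighbor of that driver is
#' shifted by \code{dysregulationShift} with a sign drawn once per
#' (driver, neighbor) pair and held fixed across patients, mimicking
#' consistent up-/down-regulation. Draw order: mutation calls (gene by
#' gene), then dysregulation signs (driver by driver), then the baseline
#' expression matrix.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param network the \linkS4class{FunctionalNetwork} from
#'   \code{\link{generateNetwork}}.
#' @param modules its module assignment.
#' @return list with \code{cohort} (a \linkS4class{MutationCohort}),
#'   \code{tumorExpr} (patients x genes \linkS4class{ExpressionMatrix}) and
#'   \code{truth} (the planted-driver \linkS4class{GeneSet}).
#' @export
generateMutationsAndExpression <- function(cfg, network, modules) {
  stopifnot(is(cfg, "SyntheticConfig"), is(network, "FunctionalNetwork"))
  gs <- .geneNames(cfg@nGenes)
  np <- cfg@nPatients
  drivers <- unlist(lapply(modules, function(m) m[seq_len(cfg@driversPerModule)]),
                    use.names = FALSE)
  rates <- setNames(rep(cfg@passengerMutRate, cfg@nGenes), gs)
  rates[drivers] <- cfg@driverMutRate
  calls <- matrix(as.numeric(rbinom(np * cfg@nGenes, 1L, rep(rates, each = np))),
                  nrow = np, dimnames = list(.patientNames(np), gs))
  A <- .adjacencyMatrix(network, gs)
  # per-(driver, neighbor) dysregulation signs, fixed across patients
  shiftMat <- matrix(0, length(drivers), cfg@nGenes,
                     dimnames = list(drivers, gs))
  for (d in drivers) {
    nb <- gs[A[d, ] == 1]
    if (length(nb))
      shiftMat[d, nb] <- (2 * rbinom(length(nb), 1L, 0.5) - 1) *
        cfg@dysregulationShift
  }
  baseline <- matrix(rnorm(np * cfg@nGenes), nrow = np,
                     dimnames = list(.patientNames(np), gs))
  tumor <- baseline + calls[, drivers, drop = FALSE] %*% shiftMat
  list(cohort = new("MutationCohort", calls = calls),
       tumorExpr = new("ExpressionMatrix", values = tumor),
       truth = GeneSet(drivers, label = "planted drivers"))
}

#' Simulate a complete synthetic study
#'
#' Seeds a single random stream from \code{cfg@seed} and draws the network,
#' the tissue expression, and the mutations/tumor expression in that fixed
#' order, so every artifact is reproducible from the configuration alone.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' sc <- simulateCohort(syntheticConfig(nGenes = 60L, nPatients = 30L,
#'   nTissueSamples = 20L, nModules = 2L, moduleSize = 5L, seed = 7L))
#' sc
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  set.seed(cfg@seed)
  net <- generateNetwork(cfg)
  tissue <- generateTissueExpression(cfg, net$modules)
  mut <- generateMutationsAndExpression(cfg, net$network, net$modules)
  new("SyntheticCohort", network = net$network, tissueExpr = tissue,
      cohort = mut$cohort, tumorExpr = mut$tumorExpr, truth = mut$truth,
      modules = net$modules, config = cfg)
}

#' Write a synthetic cohort to disk in the standard input formats
#'
#' Writes \code{mutations.tsv} (binary patient x gene), \code{tumor_expr.tsv}
#' and \code{tissue_expr.tsv} (genes in columns), \code{network.tsv}
#' (two-column edge list) and \code{truth.txt} (one planted driver per line)
#' under \code{dir}.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if missing).
#' @return invisibly, named character vector of the five paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             tumor_expr = file.path(dir, "tumor_expr.tsv"),
             tissue_expr = file.path(dir, "tissue_expr.tsv"),
             network = file.path(dir, "network.tsv"),
             truth = file.path(dir, "truth.txt"))
  .writeMatrixTSV(cohort@cohort@calls, "patient", paths["mutations"])
  .writeMatrixTSV(cohort@tumorExpr@values, "patient", paths["tumor_expr"])
  .writeMatrixTSV(cohort@tissueExpr@values, "sample", paths["tissue_expr"])
  e <- cohort@network@edges
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), paths["network"])
  writeLines(cohort@truth@symbols, paths["truth"])
  invisible(paths)
}

.writeMatrixTSV <- function(m, idName, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idName
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
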