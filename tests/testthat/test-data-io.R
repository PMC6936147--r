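test_that("symbol normalization trims, uppercases and is idempotent", {
  expect_identical(normalizeSymbols(c(" tp53 ", "Egfr")), c("TP53", "EGFR"))
  expect_identical(normalizeSymbols("TP53"), "TP53")
  expect_error(normalizeSymbols(c("TP53", "  ")), "empty")
  set.seed(42)
  for (i in 1:20) {
    raw <- paste0("  ", sample(letters, 5), sample(LETTERS, 5), " ")
    once <- normalizeSymbols(raw)
    expect_identical(normalizeSymbols(once), once)
  }
})

test_that("MAF reading collapses duplicate variant records to incidence", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c("#version 2.4",
               "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TP53\tP1\tMissense_Mutation",
               "TP53\tP1\tNonsense_Mutation",
               "KRAS\tP2\tMissense_Mutation"), maf)
  mc <- readMutations(maf, format = "maf")
  calls <- mutationCalls(mc)
  expect_equal(calls["P1", "TP53"], 1)
  expect_equal(calls["P2", "KRAS"], 1)
  expect_equal(calls["P1", "KRAS"], 0)
  expect_equal(sum(calls), 2)
  # class filtering is opt-in
  mc2 <- readMutations(maf, format = "maf",
                       excludeClasses = "Nonsense_Mutation")
  expect_equal(sum(mutationCalls(mc2)), 2)  # TP53/P1 still covered by missense
  bad <- tempfile()
  writeLines(c("Hugo_Symbol\tSample", "TP53\tP1"), bad)
  expect_error(readMutations(bad, format = "maf"), "Tumor_Sample_Barcode")
})

test_that("binary mutation TSV accepts all-zero cohorts and rejects non-binary entries", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("patient\tTP53\tKRAS\tEGFR", "P1\t0\t0\t0", "P2\t0\t0\t0"), tsv)
  mc <- readMutations(tsv, format = "binary")
  expect_equal(sum(mutationCalls(mc)), 0)
  expect_equal(dim(mutationCalls(mc)), c(2L, 3L))
  writeLines(c("patient\tTP53\tKRAS", "P1\t0\t2"), tsv)
  expect_error(readMutations(tsv, format = "binary"), "non-binary.*KRAS")
})

test_that("expression reading is orientation-invariant and mean-collapses duplicate genes", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("sample\tTP53\tKRAS", "S1\t1\t4", "S2\t2\t5", "S3\t3\t6"), f1)
  writeLines(c("gene\tS1\tS2\tS3", "TP53\t1\t2\t3", "KRAS\t4\t5\t6"), f2)
  e1 <- readExpression(f1, orientation = "genes-in-columns")
  e2 <- readExpression(f2, orientation = "genes-in-rows")
  expect_equal(dim(exprValues(e1)), c(3L, 2L))
  expect_identical(exprValues(e1), exprValues(e2))
  f3 <- tempfile()
  writeLines(c("sample\tEGFR\tEGFR", "S1\t1\t3", "S2\t2\t4", "S3\t3\t5"), f3)
  e3 <- readExpression(f3)
  expect_identical(unname(exprValues(e3)[, "EGFR"]), c(2, 3, 4))
  f4 <- tempfile()
  writeLines(c("sample\tTP53", "S1\tlow", "S2\t2"), f4)
  expect_error(readExpression(f4), "non-numeric.*S1")
  f5 <- tempfile()
  writeLines(c("sample\tTP53", "S1\t1", "S1\t2"), f5)
  expect_error(readExpression(f5), "duplicate sample")
})

test_that("network reading drops self-loops, merges reversed duplicates, reads SIF", {
  f <- tempfile()
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  expect_message(net <- readNetwork(f), "1 self-loop.*1 duplicate")
  expect_identical(networkNodes(net), c("A", "B"))
  expect_identical(unname(networkEdges(net)), matrix(c("A", "B"), ncol = 2))
  writeLines(character(0), f)
  empty <- readNetwork(f)
  expect_equal(length(networkNodes(empty)), 0L)
  writeLines("A pp B", f)
  sif <- readNetwork(f, format = "sif")
  expect_identical(unname(networkEdges(sif)), matrix(c("A", "B"), ncol = 2))
  writeLines(c("A\tB", "C"), f)
  expect_error(readNetwork(f), "line 2")
})

test_that("network reading yields a simple graph for arbitrary edge files", {
  set.seed(101)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    syms <- LETTERS[1:n]
    lines <- replicate(sample(5:25, 1),
                       paste(sample(syms, 1), sample(syms, 1), sep = "\t"))
    f <- tempfile()
    writeLines(lines, f)
    net <- suppressMessages(readNetwork(f))
    e <- networkEdges(net)
    if (nrow(e) == 0L) next
    expect_true(all(e[, 1] != e[, 2]))
    expect_false(anyDuplicated(paste(pmin(e[, 1], e[, 2]),
                                     pmax(e[, 1], e[, 2]))) > 0)
    expect_true(all(e %in% networkNodes(net)))
  }
})

test_that("ranking round-trips through TSV with exact ranks and 1e-9 scores", {
  set.seed(7)
  n <- 25L
  M <- setNames(runif(n, 0, 5), sprintf("G%02d", 1:n))
  V <- setNames(runif(n), names(M))
  ranked <- rankGenes(finalScores(M, V))
  f <- tempfile(fileext = ".tsv")
  writeRanking(ranked, f)
  back <- readRanking(f)
  expect_identical(scoreTable(back)$rank, scoreTable(ranked)$rank)
  expect_identical(scoreTable(back)$gene, scoreTable(ranked)$gene)
  expect_true(all(abs(scoreTable(back)$F - scoreTable(ranked)$F) < 1e-9))
  expect_true(all(abs(scoreTable(back)$V - scoreTable(ranked)$V) < 1e-9))
  expect_true(all(abs(scoreTable(back)$M - scoreTable(ranked)$M) < 1e-9))
  # empty table -> header-only file
  emptyTab <- new("DriverScoreTable",
                  table = data.frame(gene = character(0), V = numeric(0),
                                     M = numeric(0), F = numeric(0),
                                     rank = integer(0)))
  writeRanking(emptyTab, f)
  expect_identical(readLines(f),
    "rank\tgene\tvariation_frequency\tmodule_score\tfinal_score\tin_benchmark")
  # a 2-gene table gives header + 2 rows
  two <- rankGenes(finalScores(c(A = 1, B = 2), c(A = 0.5, B = 0.25)))
  writeRanking(two, f)
  expect_length(readLines(f), 3L)
})
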