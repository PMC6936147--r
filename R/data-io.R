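#' Normalize gene symbols
#'
#' Trims surrounding whitespace and uppercases, preserving order. This is the
#' only identifier harmonization performed anywhere in the package: matching
#' across inputs is exact after this normalization, and genes present in one
#' input but not another are dropped (with counts reported) by the consuming
#' step.
#'
#' @param raw character vector of raw symbols.
#' @return character vector of normalized symbols, same length and order.
#' @examples
#' normalizeSymbols(c(" tp53 ", "Egfr"))
#' @export
normalizeSymbols <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- toupper(trimws(as.character(raw)))
  if (any(!nzchar(out)))
    stop("empty gene symbol at position(s): ",
         paste(which(!nzchar(out)), collapse = ", "))
  out
}

#' Construct a MutationCohort from a binary matrix
#'
#' @param calls numeric patients x genes matrix with 0/1 entries and dimnames.
#' @return a \linkS4class{MutationCohort}.
#' @export
MutationCohort <- function(calls) {
  rownames(calls) <- trimws(rownames(calls))
  colnames(calls) <- normalizeSymbols(colnames(calls))
  new("MutationCohort", calls = calls)
}

#' Construct an ExpressionMatrix from a samples x genes matrix
#'
#' Duplicate gene columns (e.g. multiple array probes mapping to one symbol)
#' are collapsed to their arithmetic mean.
#'
#' @param values numeric samples x genes matrix with dimnames.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values) {
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- normalizeSymbols(colnames(values))
  values <- .collapseDuplicateColumns(values)
  new("ExpressionMatrix", values = values)
}

.collapseDuplicateColumns <- function(values) {
  if (!anyDuplicated(colnames(values))) return(values)
  syms <- colnames(values)
  keep <- unique(syms)
  out <- vapply(keep, function(s) {
    cols <- values[, syms == s, drop = FALSE]
    rowMeans(cols)
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(values), keep))
  out
}

#' Construct a FunctionalNetwork from an edge table
#'
#' Self-loops are dropped and duplicate edges (including reversed duplicates)
#' are merged; the numbers removed are reported as a message.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param nodes optional extra isolated nodes to include.
#' @return a \linkS4class{FunctionalNetwork}.
#' @export
FunctionalNetwork <- function(edges, nodes = character(0)) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    edges <- matrix(normalizeSymbols(edges), ncol = 2L)
    loops <- edges[, 1L] == edges[, 2L]
    # endpoint-sort each edge so reversed duplicates collide
    edges <- edges[!loops, , drop = FALSE]
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    dup <- duplicated(paste(edges[, 1L], edges[, 2L]))
    if (any(loops) || any(dup))
      message(sprintf("network read: dropped %d self-loop(s), merged %d duplicate edge(s)",
                      sum(loops), sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  } else {
    edges <- matrix(character(0), ncol = 2L)
  }
  allNodes <- sort(unique(c(as.vector(edges), normalizeSymbols(nodes))))
  new("FunctionalNetwork", nodes = allNodes, edges = edges)
}

#' Construct a GeneSet
#'
#' @param symbols character vector of gene symbols (normalized, deduplicated).
#' @param label free-text provenance tag.
#' @return a \linkS4class{GeneSet}.
#' @export
GeneSet <- function(symbols, label = "gene set") {
  new("GeneSet", symbols = unique(normalizeSymbols(symbols)), label = label)
}

#' Read somatic mutation calls
#'
#' Two dialects are supported. \code{format = "maf"} expects a tab-separated
#' MAF-like file with at least the columns \code{Hugo_Symbol} and
#' \code{Tumor_Sample_Barcode} (others are ignored; \code{#} comment lines are
#' skipped); one or more variant records for a (patient, gene) pair collapse
#' to a single incidence call. \code{format = "binary"} expects a TSV whose
#' first column is the patient identifier and whose remaining columns are
#' gene symbols with 0/1 entries.
#'
#' Variant-class filtering (e.g. removing silent mutations) is off by
#' default: pass \code{excludeClasses} to drop MAF records whose
#' \code{Variant_Classification} matches.
#'
#' @param path file path.
#' @param format \code{"maf"} or \code{"binary"}.
#' @param excludeClasses optional character vector of
#'   \code{Variant_Classification} values to drop (MAF only).
#' @return a \linkS4class{MutationCohort}.
#' @export
readMutations <- function(path, format = c("binary", "maf"),
                          excludeClasses = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "maf") {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
    missing <- setdiff(need, names(tab))
    if (length(missing))
      stop("MAF file is missing required column(s): ",
           paste(missing, collapse = ", "))
    if (!is.null(excludeClasses)) {
      if (!"Variant_Classification" %in% names(tab))
        stop("excludeClasses given but no Variant_Classification column")
      tab <- tab[!tab$Variant_Classification %in% excludeClasses, , drop = FALSE]
    }
    gene <- normalizeSymbols(tab$Hugo_Symbol)
    pat <- trimws(as.character(tab$Tumor_Sample_Barcode))
    patients <- unique(pat)
    geneLevels <- unique(gene)
    calls <- matrix(0, nrow = length(patients), ncol = length(geneLevels),
                    dimnames = list(patients, geneLevels))
    calls[cbind(pat, gene)] <- 1
    return(new("MutationCohort", calls = calls))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("binary mutation TSV needs patient column plus gene columns")
  pat <- trimws(as.character(tab[[1L]]))
  if (anyDuplicated(pat)) stop("duplicate patient identifiers in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary entry at row %d (patient %s), column %s",
                 bad[1L, 1L], pat[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- pat
  MutationCohort(m)
}

#' Read an expression matrix
#'
#' Reads a TSV with row identifiers in the first column and column
#' identifiers in the header, and returns the canonical samples x genes
#' orientation regardless of the on-disk layout. Duplicate gene columns
#' (multi-probe arrays) are mean-collapsed.
#'
#' @param path file path.
#' @param orientation which axis carries the genes on disk:
#'   \code{"genes-in-columns"} (rows are samples) or \code{"genes-in-rows"}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path,
                           orientation = c("genes-in-columns", "genes-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- trimws(as.character(tab[[1L]]))
  mchr <- as.matrix(tab[, -1L, drop = FALSE])
  colnames(mchr) <- names(tab)[-1L]   # as.matrix mangles duplicate headers
  m <- suppressWarnings(
    matrix(as.numeric(mchr), nrow(mchr), ncol(mchr), dimnames = dimnames(mchr)))
  orig <- trimws(as.character(mchr))
  bad <- which(is.na(m) & nzchar(orig) & toupper(orig) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric expression value at row %s, column %s",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- ids
  if (orientation == "genes-in-rows") m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample identifiers in ", path)
  ExpressionMatrix(m)
}

#' Read an undirected gene network
#'
#' Accepts a two-column whitespace/tab-separated edge list or a three-column
#' SIF file (the middle relation column is ignored). Lines starting with
#' \code{#} are skipped. Self-loops and duplicate (incl. reversed) edges are
#' removed.
#'
#' @param path file path.
#' @param format \code{"edgelist"} or \code{"sif"}.
#' @return a \linkS4class{FunctionalNetwork}.
#' @export
readNetwork <- function(path, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineNo <- which(keep)
  if (length(lines) == 0L)
    return(new("FunctionalNetwork", nodes = character(0),
               edges = matrix(character(0), ncol = 2L)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  needed <- if (format == "sif") 3L else 2L
  short <- lengths(fields) < needed
  if (any(short))
    stop(sprintf("network line %d has fewer than %d columns",
                 lineNo[which(short)[1L]], needed))
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), needed)
  FunctionalNetwork(cbind(a, b))
}

#' Read a gene list (one symbol per line)
#'
#' @param path file path; \code{#} comment lines and blank lines are skipped.
#' @param label provenance tag stored on the returned set.
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  GeneSet(lines, label = label)
}

#' Write a ranked driver table to TSV
#'
#' Columns are \code{rank}, \code{gene}, \code{variation_frequency},
#' \code{module_score}, \code{final_score}, \code{in_benchmark}; rows in rank
#' order. Scores are serialized with 15 significant digits so a
#' write-then-read round trip reproduces them to well below 1e-9.
#'
#' @param table a ranked \linkS4class{DriverScoreTable}.
#' @param path output file path.
#' @param benchmark optional \linkS4class{GeneSet}; fills the
#'   \code{in_benchmark} column with 0/1 (NA when absent).
#' @return invisibly, the path.
#' @export
writeRanking <- function(table, path, benchmark = NULL) {
  stopifnot(is(table, "DriverScoreTable"))
  tab <- table@table
  if (nrow(tab) > 0L && !"rank" %in% names(tab))
    stop("rank the table with rankGenes() before writing")
  inBench <- if (is.null(benchmark)) rep(NA_integer_, nrow(tab))
             else as.integer(tab$gene %in% benchmark@symbols)
  out <- data.frame(rank = if (nrow(tab)) tab$rank else integer(0),
                    gene = tab$gene,
                    variation_frequency = sprintf("%.15g", tab$V),
                    module_score = sprintf("%.15g", tab$M),
                    final_score = sprintf("%.15g", tab$F),
                    in_benchmark = inBench,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L) out <- out[order(out$rank), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("rank", "gene", "variation_frequency", "module_score",
                     "final_score", "in_benchmark"), collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a ranked driver table written by writeRanking
#'
#' @param path file path.
#' @return a ranked \linkS4class{DriverScoreTable}.
#' @export
readRanking <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  df <- data.frame(gene = as.character(tab$gene),
                   V = as.numeric(tab$variation_frequency),
                   M = as.numeric(tab$module_score),
                   F = as.numeric(tab$final_score),
                   rank = as.integer(tab$rank),
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  # F is re-derived so the stored product identity holds to machine precision
  df$F <- df$V * df$M
  new("DriverScoreTable", table = df)
}
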