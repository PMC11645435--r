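#' @importFrom data.table fread
#' @importFrom utils write.table
NULL

# Delimiter auto-detection restricted to tab and comma. A file whose header
# line contains both is rejected rather than guessed: silently misparsing an
# expression matrix is the worst possible failure mode here.
.detectDelim <- function(path) {
  head <- readLines(path, n = 1L, warn = FALSE)
  if (length(head) == 0L || !nzchar(head))
    .stopFormat(sprintf("'%s' is empty", path))
  hasTab <- grepl("\t", head, fixed = TRUE)
  hasComma <- grepl(",", head, fixed = TRUE)
  if (hasTab && hasComma)
    .stopFormat(sprintf(
      "'%s' mixes tab and comma in its header line; cannot detect delimiter",
      path))
  if (hasTab) "\t" else if (hasComma) "," else
    .stopFormat(sprintf("'%s': no tab or comma delimiter found", path))
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV expression table (delimiter auto-detected) into an
#' [ExpressionDataset-class]. With `orientation = "genes_by_cells"` the file
#' has genes as rows, a leading gene-identifier column, and cell identifiers
#' in the header; `"cells_by_genes"` is the transpose (cells as rows, gene
#' identifiers in the header) and is transposed on read, so the returned
#' matrix is always genes x cells. Input ordering of genes and cells is
#' preserved. Pseudotime and selection are not set by this reader; attach
#' them with [readTrajectory()] / [readCellSelect()].
#'
#' @param path path to a delimited text file.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @return An [ExpressionDataset-class] without pseudotime.
#' @export
readExpression <- function(path,
                           orientation = c("genes_by_cells",
                                           "cells_by_genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) .stopIO(sprintf("expression file '%s' not found", path))
  if (file.size(path) == 0L) .stopFormat(sprintf("'%s' is empty", path))
  sep <- .detectDelim(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    .stopFormat(sprintf("'%s' has no data beyond identifiers", path))
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      .stopParse(sprintf(
        "non-numeric value '%s' at data row %d, column '%s' of '%s'",
        col[bad], bad, colnames(vals)[j], path))
    }
    if (anyNA(col) || any(!is.finite(col)))
      .stopParse(sprintf("missing or non-finite value in column '%s' of '%s'",
                         colnames(vals)[j], path))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "cells_by_genes") m <- t(m)
  if (anyDuplicated(rownames(m)))
    .stopDuplicate(sprintf(
      "duplicate gene identifier(s) in '%s': %s", path,
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    .stopDuplicate(sprintf("duplicate cell identifier(s) in '%s'", path))
  ExpressionDataset(m)
}

#' Read an expression matrix in Matrix Market triplet format
#'
#' Reads a `.mtx` sparse matrix with companion one-identifier-per-line gene
#' and cell name files, densifying into an [ExpressionDataset-class].
#'
#' @param mtxPath path to the Matrix Market file (genes x cells).
#' @param genesPath,cellsPath paths to the row / column name files.
#' @return An [ExpressionDataset-class] without pseudotime.
#' @export
readExpressionMM <- function(mtxPath, genesPath, cellsPath) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    .stopCapability("Matrix package is required for Matrix Market input")
  for (p in c(mtxPath, genesPath, cellsPath))
    if (!file.exists(p)) .stopIO(sprintf("file '%s' not found", p))
  m <- as.matrix(Matrix::readMM(mtxPath))
  genes <- readLines(genesPath, warn = FALSE)
  cells <- readLines(cellsPath, warn = FALSE)
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    .stopLength("row/column name files do not match the matrix dimensions")
  dimnames(m) <- list(genes, cells)
  ExpressionDataset(m)
}

# Read whitespace-trimmed lines, dropping trailing blank lines only (a
# final newline must not count as an extra record).
.readLinesTrimmed <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

#' Read a pseudotime trajectory file
#'
#' One numeric pseudotime value per line, aligned positionally with the
#' columns of the expression matrix (no cell-ID matching is attempted).
#'
#' @param path path to the pseudotime file.
#' @param nCells expected number of cells.
#' @return numeric vector of length `nCells` in file order.
#' @export
readTrajectory <- function(path, nCells) {
  if (!file.exists(path)) .stopIO(sprintf("pseudotime file '%s' not found", path))
  lines <- .readLinesTrimmed(path)
  if (length(lines) != nCells)
    .stopLength(sprintf("pseudotime file '%s' has %d lines, expected %d",
                        path, length(lines), nCells))
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))[1L]
  if (!is.na(bad))
    .stopParse(sprintf("non-numeric pseudotime '%s' at line %d of '%s'",
                       lines[bad], bad, path))
  vals
}

#' Read a cell-selection file
#'
#' One `0`/`1` flag per line, aligned positionally with the matrix columns.
#' A missing file (`NULL` path or non-existent file) means all cells are
#' selected.
#'
#' @param path path to the cell-select file, or `NULL`.
#' @param nCells expected number of cells.
#' @return logical vector of length `nCells`.
#' @export
readCellSelect <- function(path, nCells) {
  if (is.null(path) || !file.exists(path)) return(rep(TRUE, nCells))
  lines <- .readLinesTrimmed(path)
  if (length(lines) != nCells)
    .stopLength(sprintf("cell-select file '%s' has %d lines, expected %d",
                        path, length(lines), nCells))
  if (!all(lines %in% c("0", "1")))
    .stopFormat(sprintf("cell-select file '%s' contains values other than 0/1",
                        path))
  lines == "1"
}

# Full-precision numeric formatting: 17 significant digits round-trip
# doubles exactly through text.
.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a transfer-entropy matrix to delimited text
#'
#' Writes the matrix as tab-delimited text with gene names as the first row
#' and first column. Entry (i, j) is the TE from gene i (source) to gene j
#' (target). Values are printed with 17 significant digits so a read-back
#' reproduces them exactly.
#'
#' @param te a [TEMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTEMatrix <- function(te, path) {
  stopifnot(is(te, "TEMatrix"))
  v <- te@values
  out <- matrix(.fmtNum(v), nrow = nrow(v), dimnames = dimnames(v))
  con <- tryCatch(file(path, "w"), error = function(e)
    .stopIO(sprintf("cannot open '%s' for writing: %s", path,
                    conditionMessage(e))),
    warning = function(w)
      .stopIO(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a transfer-entropy matrix written by [writeTEMatrix()]
#'
#' @param path path to the TE matrix file.
#' @param logBase logarithm base the stored values are in (not recorded in
#'   the file; defaults to bits).
#' @return A [TEMatrix-class].
#' @export
readTEMatrix <- function(path, logBase = 2) {
  if (!file.exists(path)) .stopIO(sprintf("TE matrix file '%s' not found", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1L]])
  new("TEMatrix", values = m, logBase = logBase)
}

#' Write an edge list to TSV or SIF
#'
#' Edges are written in descending score order, ties broken by (source,
#' target) lexicographic order. The TSV format is
#' `source<TAB>target<TAB>score`; the SIF format is
#' `source<TAB>te<TAB>target` (relation label `te`), the convention network
#' viewers such as Cytoscape read directly.
#'
#' @param edges an [EdgeList-class].
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path, format = c("tsv", "sif")) {
  stopifnot(is(edges, "EdgeList"))
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("tsv", "sif"))
    .stopUsage(sprintf("unknown edge-list format '%s'", format))
  format <- match.arg(format)
  e <- edges@edges
  ord <- order(-e$te, e$source, e$target, method = "radix")
  e <- e[ord, , drop = FALSE]
  lines <- if (nrow(e) == 0L) character(0)
  else if (format == "tsv")
    paste(e$source, e$target, .fmtNum(e$te), sep = "\t")
  else paste(e$source, "te", e$target, sep = "\t")
  con <- tryCatch(file(path, "w"), error = function(err)
    .stopIO(sprintf("cannot open '%s' for writing", path)),
    warning = function(w)
      .stopIO(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write an expression dataset to delimited text
#'
#' Writes the genes x cells matrix as TSV (gene identifiers in the first
#' column, cell identifiers in the header), plus optional pseudotime and
#' cell-select companion files in the positional one-value-per-line
#' convention the readers expect.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output path for the matrix.
#' @param pseudotimePath,cellSelectPath optional companion file paths.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(ds, path, pseudotimePath = NULL,
                            cellSelectPath = NULL) {
  stopifnot(is(ds, "ExpressionDataset"))
  m <- exprMatrix(ds)
  out <- matrix(.fmtNum(m), nrow = nrow(m), dimnames = dimnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(pseudotimePath))
    writeLines(.fmtNum(pseudotime(ds)), pseudotimePath)
  if (!is.null(cellSelectPath))
    writeLines(as.character(as.integer(selectedCells(ds))), cellSelectPath)
  invisible(path)
}
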