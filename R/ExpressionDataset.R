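#' Construct an ExpressionDataset
#'
#' Bundles a genes x cells expression matrix with gene names, cell
#' identifiers, per-cell pseudotime and cell-selection flags. Pseudotime may
#' be left out at construction (e.g. straight after reading an expression
#' file) and attached later with [`pseudotime<-`].
#'
#' @param expr numeric genes x cells matrix of non-negative expression
#'   values.
#' @param geneNames unique gene identifiers; defaults to `rownames(expr)`.
#' @param cellIds unique cell identifiers; defaults to `colnames(expr)`.
#' @param pseudotime numeric pseudotime per cell, or `NULL` (all `NA`).
#' @param selected logical selection flag per cell, or `NULL` (all `TRUE`).
#' @param rowData optional `DataFrame` of per-gene annotation.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' ds <- ExpressionDataset(m, pseudotime = c(0.1, 0.3, 0.2))
#' pseudotime(ds)
#' @export
ExpressionDataset <- function(expr, geneNames = rownames(expr),
                              cellIds = colnames(expr), pseudotime = NULL,
                              selected = NULL, rowData = NULL) {
  expr <- as.matrix(expr)
  if (is.null(geneNames))
    .stopUsage("gene names are required (rownames or geneNames=)")
  if (is.null(cellIds))
    cellIds <- paste0("cell", seq_len(ncol(expr)))
  if (anyDuplicated(geneNames))
    .stopDuplicate(sprintf(
      "duplicate gene identifier(s): %s",
      paste(unique(geneNames[duplicated(geneNames)]), collapse = ", ")))
  if (is.null(pseudotime)) pseudotime <- rep(NA_real_, ncol(expr))
  if (is.null(selected)) selected <- rep(TRUE, ncol(expr))
  if (length(pseudotime) != ncol(expr) || length(selected) != ncol(expr))
    .stopLength("pseudotime and selected must have one entry per cell")
  dimnames(expr) <- list(geneNames, cellIds)
  cd <- S4Vectors::DataFrame(pseudotime = as.numeric(pseudotime),
                             selected = as.logical(selected),
                             row.names = cellIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr), colData = cd)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("ExpressionDataset", se)
}

#' Expression matrix of a dataset
#'
#' @param x an [ExpressionDataset-class].
#' @return The genes x cells numeric matrix.
#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "expr"))

#' Gene names
#'
#' @param x an object with genes.
#' @return character vector of gene identifiers.
#' @rdname geneNames
#' @export
setMethod("geneNames", "ExpressionDataset", function(x) rownames(x))

#' @rdname geneNames
#' @export
setMethod("geneNames", "DiscretizedSet", function(x) rownames(x@bins))

#' @rdname geneNames
#' @export
setMethod("geneNames", "TEMatrix", function(x) rownames(x@values))

#' Pseudotime of the cells
#'
#' @param x an [ExpressionDataset-class].
#' @param value numeric pseudotime per cell.
#' @return numeric vector, one value per cell (possibly `NA` if no
#'   trajectory has been attached).
#' @rdname pseudotime
#' @export
setMethod("pseudotime", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$pseudotime)

#' @rdname pseudotime
#' @export
setReplaceMethod("pseudotime", "ExpressionDataset", function(x, value) {
  if (length(value) != ncol(x))
    .stopLength(sprintf("pseudotime has %d values for %d cells",
                        length(value), ncol(x)))
  SummarizedExperiment::colData(x)$pseudotime <- as.numeric(value)
  validObject(x)
  x
})

#' Cell-selection flags
#'
#' @param x an [ExpressionDataset-class].
#' @param value logical flag per cell.
#' @return logical vector, one flag per cell.
#' @rdname selectedCells
#' @export
setMethod("selectedCells", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$selected)

#' @rdname selectedCells
#' @export
setReplaceMethod("selectedCells", "ExpressionDataset", function(x, value) {
  if (length(value) != ncol(x))
    .stopLength(sprintf("selection has %d flags for %d cells",
                        length(value), ncol(x)))
  SummarizedExperiment::colData(x)$selected <- as.logical(value)
  validObject(x)
  x
})

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells\n",
              nrow(object), ncol(object)))
  pt <- pseudotime(object)
  cat(sprintf("  pseudotime: %s | selected cells: %d\n",
              if (all(is.na(pt))) "absent" else "attached",
              sum(selectedCells(object))))
})
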