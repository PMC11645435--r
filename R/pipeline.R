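#' Run the full inference pipeline from files to artifacts
#'
#' Reads an expression matrix, pseudotime and optional cell-selection file,
#' preprocesses, computes the pairwise TE matrix, calls significant edges,
#' ranks hubs, and writes all artifacts under `outPrefix`:
#' `<prefix>.te_matrix.tsv`, `<prefix>.edges.tsv`, `<prefix>.edges.sif`,
#' `<prefix>.hubs.tsv` and `<prefix>.run_info.txt` (options, package
#' version, input digests). This is exactly what the command-line interface
#' runs; there is no CLI-only computation.
#'
#' @param exprPath expression matrix file (see [readExpression()]).
#' @param pseudotimePath pseudotime file (see [readTrajectory()]).
#' @param cellSelectPath optional cell-select file; `NULL` selects all
#'   cells.
#' @param orientation expression file orientation.
#' @param nBins,method,window preprocessing options, see
#'   [preprocessDataset()].
#' @param batchSize,nWorkers,backend,logBase engine options, see
#'   [computeTEMatrix()].
#' @param fdr Benjamini-Hochberg level for edge calling.
#' @param outPrefix path prefix for all written artifacts.
#' @return Invisibly, a list with the `te` [TEMatrix-class], `edges`
#'   [EdgeList-class], `hubs` data.frame and the written `paths`.
#' @export
runPipeline <- function(exprPath, pseudotimePath, cellSelectPath = NULL,
                        orientation = "genes_by_cells", nBins = "sqrt",
                        method = "equal_width", window = 1L,
                        batchSize = "auto", nWorkers = 1L, backend = "cpu",
                        logBase = 2, fdr = 0.01, outPrefix = "tegrn") {
  ds <- readExpression(exprPath, orientation)
  pseudotime(ds) <- readTrajectory(pseudotimePath, ncol(ds))
  selectedCells(ds) <- readCellSelect(cellSelectPath, ncol(ds))
  dset <- preprocessDataset(ds, nBins = nBins, method = method,
                            window = window)
  te <- computeTEMatrix(dset, batchSize = batchSize, nWorkers = nWorkers,
                        backend = backend, logBase = logBase)
  el <- edgesFromTE(te, fdrLevel = fdr)
  hubs <- hubRanking(el)
  paths <- list(te = paste0(outPrefix, ".te_matrix.tsv"),
                edgesTsv = paste0(outPrefix, ".edges.tsv"),
                edgesSif = paste0(outPrefix, ".edges.sif"),
                hubs = paste0(outPrefix, ".hubs.tsv"),
                runInfo = paste0(outPrefix, ".run_info.txt"))
  writeTEMatrix(te, paths$te)
  writeEdgeList(el, paths$edgesTsv, "tsv")
  writeEdgeList(el, paths$edgesSif, "sif")
  utils::write.table(hubs, paths$hubs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  inputs <- c(expr = exprPath, pseudotime = pseudotimePath,
              cellSelect = if (is.null(cellSelectPath)) NA_character_
              else cellSelectPath)
  digests <- vapply(inputs, function(p)
    if (is.na(p)) NA_character_ else unname(tools::md5sum(p)), character(1L))
  info <- c(
    sprintf("teGRN version: %s", as.character(utils::packageVersion("teGRN"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("option %s = %s",
            c("orientation", "nBins", "method", "window", "batchSize",
              "nWorkers", "backend", "logBase", "fdr"),
            c(orientation, as.character(nBins), method, window,
              as.character(batchSize), nWorkers, backend, logBase, fdr)),
    sprintf("input %s = %s (md5 %s)", names(inputs), inputs, digests))
  writeLines(info, paths$runInfo)
  invisible(list(te = te, edges = el, hubs = hubs, paths = paths))
}
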