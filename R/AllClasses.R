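#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExpressionDataset: genes x cells expression with pseudotime
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for a
#' genes x cells expression matrix together with the per-cell pseudotime and
#' cell-selection flags that the transfer-entropy engine needs. Rows are
#' genes, columns are cells. The pseudotime column of `colData` gives the
#' position of each cell along the trajectory (may be `NA` until a
#' trajectory file is attached); `selected` flags the cells that take part
#' in the analysis.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @seealso [ExpressionDataset()], [pseudotime()], [selectedCells()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character(0)
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  rn <- rownames(object)
  if (is.null(rn) || anyNA(rn))
    msg <- c(msg, "gene names (rownames) are required")
  else if (anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicate gene identifiers: %s",
                          paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "cell identifiers (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("pseudotime", "selected") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'pseudotime' and 'selected'")
  else {
    if (!is.numeric(cd$pseudotime))
      msg <- c(msg, "pseudotime must be numeric")
    if (!is.logical(cd$selected) || anyNA(cd$selected))
      msg <- c(msg, "selected must be logical without NA")
  }
  m <- SummarizedExperiment::assay(object, "expr")
  if (is.numeric(m) && any(is.finite(m) & m < 0))
    msg <- c(msg, "expression values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DiscretizedSeries: one gene's bin-index series in pseudotime order
#'
#' Holds the integer bin indices of a single gene's (smoothed) expression
#' values over the selected cells, ordered along pseudotime. Bin indices run
#' from 0 to `nBins - 1`.
#'
#' @slot bins integer vector of bin indices in `[0, nBins - 1]`.
#' @slot nBins number of bins.
#' @slot geneName gene identifier (may be empty).
#' @export
setClass("DiscretizedSeries",
         representation(bins = "integer", nBins = "integer",
                        geneName = "character"))

setValidity("DiscretizedSeries", function(object) {
  msg <- character(0)
  if (length(object@nBins) != 1L || object@nBins < 1L)
    msg <- c(msg, "nBins must be a single positive integer")
  if (length(object@bins) < 2L)
    msg <- c(msg, "series must contain at least 2 values to form a lagged triple")
  if (anyNA(object@bins) ||
      (length(object@bins) && (min(object@bins) < 0L ||
                               max(object@bins) >= object@nBins)))
    msg <- c(msg, "bin indices must lie in [0, nBins - 1]")
  if (length(msg)) msg else TRUE
})

#' DiscretizedSet: all genes' bin series over one shared cell ordering
#'
#' @slot bins integer matrix, genes x ordered cells; rownames are genes.
#' @slot nBins number of bins shared by all series.
#' @slot cellOrder original column indices of the selected cells, in
#'   pseudotime order.
#' @slot cellIds identifiers of the ordered cells.
#' @export
setClass("DiscretizedSet",
         representation(bins = "matrix", nBins = "integer",
                        cellOrder = "integer", cellIds = "character"))

setValidity("DiscretizedSet", function(object) {
  msg <- character(0)
  if (!is.integer(object@bins)) msg <- c(msg, "bins must be an integer matrix")
  if (is.null(rownames(object@bins))) msg <- c(msg, "bins must have gene rownames")
  if (ncol(object@bins) != length(object@cellOrder) ||
      ncol(object@bins) != length(object@cellIds))
    msg <- c(msg, "cellOrder/cellIds must match the number of columns")
  if (length(object@bins) &&
      (min(object@bins) < 0L || max(object@bins) >= object@nBins))
    msg <- c(msg, "bin indices must lie in [0, nBins - 1]")
  if (length(msg)) msg else TRUE
})

#' AlignedCounts: per-pattern joint-event counts for one ordered gene pair
#'
#' For a pair of discretized series (target X, putative regulator Y) the
#' lag-1 joint events are the triples (X_{t+1}, X_t, Y_t). Only the unique
#' triples actually observed are stored, lexicographically sorted, together
#' with four count vectors aligned so that position i in each refers to the
#' same triple pattern: the triple count itself and the counts of its
#' (X_{t+1}, X_t), (X_t, Y_t) and (X_t) sub-patterns. This is the sparse
#' representation the transfer-entropy estimator is evaluated on.
#'
#' @slot patterns integer matrix (m x 3) of unique observed triples, columns
#'   `xNext`, `xNow`, `yNow`, in strictly increasing lexicographic order.
#' @slot n3 count of each triple.
#' @slot n2xx count of each triple's (xNext, xNow) sub-pattern.
#' @slot n2xy count of each triple's (xNow, yNow) sub-pattern.
#' @slot n1x count of each triple's (xNow) sub-pattern.
#' @slot total number of lagged time steps, `l_t - 1`.
#' @export
setClass("AlignedCounts",
         representation(patterns = "matrix", n3 = "integer", n2xx = "integer",
                        n2xy = "integer", n1x = "integer", total = "integer"))

setValidity("AlignedCounts", function(object) {
  msg <- character(0)
  m <- nrow(object@patterns)
  if (ncol(object@patterns) != 3L) msg <- c(msg, "patterns must have 3 columns")
  lens <- c(length(object@n3), length(object@n2xx), length(object@n2xy),
            length(object@n1x))
  if (any(lens != m)) msg <- c(msg, "count vectors must align with patterns")
  if (m < 1L || m > object@total)
    msg <- c(msg, "number of patterns must lie in [1, total]")
  if (sum(object@n3) != object@total)
    msg <- c(msg, "sum(n3) must equal total (= l_t - 1)")
  if (any(object@n3 < 1L) || any(object@n2xx < object@n3) ||
      any(object@n2xy < object@n3) || any(object@n1x < object@n2xx) ||
      any(object@n1x < object@n2xy))
    msg <- c(msg, "count nesting 1 <= n3 <= n2xx,n2xy <= n1x violated")
  if (m > 1L) {
    p <- object@patterns
    key <- (p[, 1L] * (max(p) + 1)^2) + p[, 2L] * (max(p) + 1) + p[, 3L]
    if (any(diff(key) <= 0))
      msg <- c(msg, "patterns must be strictly increasing lexicographically")
  }
  if (length(msg)) msg else TRUE
})

#' DenseCountArray: the full b^3 joint-event histogram (testing oracle)
#'
#' The dense rank-3 count grid indexed `[xNext, xNow, yNow]` over all
#' `nBins^3` possible triples. It is never used on the production path (its
#' extreme sparsity is the problem the aligned representation solves); it
#' exists as an independent oracle for tests and for sparsity diagnostics.
#'
#' @slot counts integer array of dim `c(nBins, nBins, nBins)`.
#' @slot nBins number of bins.
#' @export
setClass("DenseCountArray",
         representation(counts = "array", nBins = "integer"))

setValidity("DenseCountArray", function(object) {
  msg <- character(0)
  if (!identical(dim(object@counts), rep(as.integer(object@nBins), 3L)))
    msg <- c(msg, "counts must be an nBins^3 cube")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TEMatrix: directed transfer-entropy matrix
#'
#' Square matrix of pairwise transfer entropies; entry (i, j) is the TE from
#' gene i (putative regulator, source) to gene j (target). The diagonal is
#' identically zero because self-TE vanishes. Values are in bits when
#' `logBase` is 2, nats when it is `exp(1)`.
#'
#' @slot values n x n numeric matrix with gene dimnames.
#' @slot logBase base of the logarithm used (2 or e).
#' @export
setClass("TEMatrix",
         representation(values = "matrix", logBase = "numeric"))

setValidity("TEMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column gene names must be present and identical")
  if (any(!is.finite(v))) msg <- c(msg, "all entries must be finite")
  if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be identically zero")
  if (any(v < 0)) msg <- c(msg, "transfer entropy cannot be negative")
  if (length(msg)) msg else TRUE
})

#' BatchPlan: contiguous partition of the ordered gene-pair sequence
#'
#' All n(n-1) ordered (source, target) pairs in row-major order, sliced into
#' contiguous batches of at most `batchSize` pairs; the last batch may be
#' short. Workers are handed batches, and the result matrix is assembled by
#' pair index so the partition never affects the output.
#'
#' @slot pairs integer matrix (nPairs x 2), columns `source`, `target`
#'   (1-based gene indices).
#' @slot batchSize maximum pairs per batch.
#' @slot starts,ends 1-based first/last pair row of each batch.
#' @export
setClass("BatchPlan",
         representation(pairs = "matrix", batchSize = "integer",
                        starts = "integer", ends = "integer"))

setValidity("BatchPlan", function(object) {
  msg <- character(0)
  if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have 2 columns")
  if (any(object@pairs[, 1L] == object@pairs[, 2L]))
    msg <- c(msg, "self-pairs are not allowed")
  if (length(object@starts) != length(object@ends))
    msg <- c(msg, "starts/ends must align")
  if (length(object@starts)) {
    cover <- unlist(mapply(seq.int, object@starts, object@ends,
                           SIMPLIFY = FALSE))
    if (!identical(cover, seq_len(nrow(object@pairs))))
      msg <- c(msg, "batches must tile the pair sequence exactly")
  }
  if (length(msg)) msg else TRUE
})

#' EdgeList: significant directed regulator-to-target edges
#'
#' @slot edges data.frame with columns `source`, `target`, `te`, `z`,
#'   `padj`, one row per retained edge.
#' @slot fdrLevel the Benjamini-Hochberg level the edges were filtered at.
#' @export
setClass("EdgeList",
         representation(edges = "data.frame", fdrLevel = "numeric"))

setValidity("EdgeList", function(object) {
  msg <- character(0)
  need <- c("source", "target", "te", "z", "padj")
  if (!all(need %in% colnames(object@edges)))
    msg <- c(msg, sprintf("edges must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    e <- object@edges
    if (any(e$source == e$target)) msg <- c(msg, "self-edges are not allowed")
    if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
      msg <- c(msg, "each ordered pair may appear at most once")
    if (nrow(e) && any(e$padj > object@fdrLevel))
      msg <- c(msg, "all retained adjusted p-values must be <= fdrLevel")
  }
  if (length(object@fdrLevel) != 1L || object@fdrLevel <= 0 ||
      object@fdrLevel >= 1)
    msg <- c(msg, "fdrLevel must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' ArrayBackend: array-computing backend satisfying the engine's contract
#'
#' A backend supplies the small set of array primitives the engine is built
#' from: `sort`, `uniqueWithCounts` (on a sorted vector), `repeatEach`,
#' `gather` (searchsorted-style lookup into a sorted table), elementwise
#' `log`, and `segmentSum`. The reference backend runs on the CPU with base
#' R; alternative backends register the same operation set and must agree
#' with the reference numerically.
#'
#' @slot name backend identifier.
#' @slot ops named list of the contract operations.
#' @export
setClass("ArrayBackend",
         representation(name = "character", ops = "list"))
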