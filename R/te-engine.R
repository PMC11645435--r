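# Transfer-entropy engine. TE from regulator Y to target X is
#   TE_{Y->X} = H(X_{t+1} | X_t) - H(X_{t+1} | X_t, Y_t)
#             = sum p(x', x, y) log[ p(x', x, y) p(x) / (p(x', x) p(x, y)) ]
# with the plug-in estimator p = count / total. The normalizing total
# cancels inside the logarithm, so over the aligned counts
#   TE = (1/total) * sum_i n3_i * log( n3_i * n1x_i / (n2xx_i * n2xy_i) ).
# Every count inside the logarithm is >= 1, so no zero-probability terms
# can arise on the aligned path.

.teFromCounts <- function(n3, n2xx, n2xy, n1x, total, logBase, logFun = log) {
  # grouped so that the constant-regulator case (n3 == n2xx, n1x == n2xy)
  # and the self-pair case cancel term by term, exactly in floating point
  te <- sum(n3 * ((logFun(n3) - logFun(n2xx)) +
                    (logFun(n1x) - logFun(n2xy)))) / (total * log(logBase))
  # plug-in TE is an expected KL divergence, hence >= 0; clamp float dust
  if (te < 0) te <- 0
  te
}

#' Transfer entropy of one gene pair from aligned counts
#'
#' Evaluates the plug-in transfer-entropy estimator over the aligned
#' observed-pattern counts. The value is the reduction in uncertainty about
#' X_{t+1} provided by Y_t beyond what X_t already provides; it is zero
#' exactly when X_{t+1} is conditionally independent of Y_t given X_t under
#' the empirical distribution, and never negative.
#'
#' @param counts an [AlignedCounts-class] for the pair (target X,
#'   regulator Y).
#' @param logBase logarithm base: 2 (default, bits) or `exp(1)` (nats).
#' @return a single non-negative finite number.
#' @export
transferEntropyPair <- function(counts, logBase = 2) {
  stopifnot(is(counts, "AlignedCounts"))
  if (!is.numeric(logBase) || length(logBase) != 1L || logBase <= 1)
    .stopUsage("logBase must be a number > 1")
  .teFromCounts(counts@n3, counts@n2xx, counts@n2xy, counts@n1x,
                counts@total, logBase)
}

#' Enumerate all ordered gene pairs
#'
#' All `n * (n - 1)` ordered (source, target) pairs with source != target,
#' in row-major order (sorted by source, then target); this is the nP2 pair
#' set of the all-against-all TE computation.
#'
#' @param nGenes number of genes, at least 2.
#' @return integer matrix with columns `source`, `target` (1-based).
#' @export
enumeratePairs <- function(nGenes) {
  if (!.isCount(nGenes) || nGenes < 2L)
    .stopUsage("nGenes must be an integer >= 2")
  n <- as.integer(nGenes)
  src <- rep(seq_len(n), each = n)
  tgt <- rep(seq_len(n), times = n)
  keep <- src != tgt
  cbind(source = src[keep], target = tgt[keep])
}

#' Partition the ordered pair sequence into contiguous batches
#'
#' @param nGenes number of genes.
#' @param batchSize maximum pairs per batch; the final batch may be short.
#' @return A [BatchPlan-class] with `ceiling(n(n-1)/batchSize)` batches.
#' @export
makeBatchPlan <- function(nGenes, batchSize) {
  if (!.isCount(batchSize) || batchSize < 1L)
    .stopUsage("batchSize must be a positive integer")
  pairs <- enumeratePairs(nGenes)
  batchSize <- as.integer(batchSize)
  starts <- as.integer(seq.int(1L, nrow(pairs), by = batchSize))
  ends <- as.integer(pmin(starts + batchSize - 1L, nrow(pairs)))
  new("BatchPlan", pairs = pairs, batchSize = batchSize,
      starts = starts, ends = ends)
}

#' Number of batches in a plan
#' @param plan a [BatchPlan-class].
#' @return integer batch count.
#' @export
nBatches <- function(plan) length(plan@starts)

setMethod("show", "BatchPlan", function(object) {
  cat(sprintf("BatchPlan: %d pairs in %d batch(es) of <= %d\n",
              nrow(object@pairs), length(object@starts), object@batchSize))
})

#' Compute transfer entropy for a batch of gene pairs
#'
#' Evaluates TE for each (source, target) pair in `pairs` against the bin
#' matrix, using only the backend's array primitives. For a pair (s, t),
#' the target series X is gene t and the regulator series Y is gene s.
#'
#' @param binMat integer matrix of bin indices, genes x ordered cells (see
#'   [binMatrix()]).
#' @param pairs integer matrix with columns source, target (1-based rows of
#'   `binMat`).
#' @param backend backend id or [ArrayBackend-class].
#' @param logBase logarithm base.
#' @param batchId optional identifier attached to error reports.
#' @return numeric vector of TE values, one per pair, in pair order.
#' @export
computeBatch <- function(binMat, pairs, backend = "cpu", logBase = 2,
                         batchId = NA_integer_) {
  ops <- getBackend(backend)@ops
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 1L) || any(pairs > nrow(binMat)))
    .stopBounds("pair index out of range for the bin matrix")
  out <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch({
      core <- .alignedCore(binMat[pairs[i, 2L], ], binMat[pairs[i, 1L], ],
                           ops)
      .teFromCounts(core$n3, core$n2xx, core$n2xy, core$n1x, core$total,
                    logBase, ops$log)
    }, error = function(e)
      .stopCompute(sprintf(
        "backend '%s' failed in batch %s on pair (%d -> %d): %s",
        getBackend(backend)@name, as.character(batchId),
        pairs[i, 1L], pairs[i, 2L], conditionMessage(e))))
    out[i] <- res
  }
  out
}

# Batch size heuristic: keep one batch's working set (a handful of
# double-precision scratch vectors per pair, each of length ~ l_t) under the
# memory budget.
.autoBatchSize <- function(lt, nPairs, memoryBudgetMB = 512) {
  perPair <- 8 * 12 * max(lt, 1L)
  max(1L, min(nPairs, as.integer(floor(memoryBudgetMB * 2^20 / perPair))))
}

#' Compute the full pairwise transfer-entropy matrix
#'
#' Runs the all-against-all TE computation over a preprocessed dataset:
#' enumerates all ordered gene pairs, partitions them into batches,
#' evaluates each batch through the array backend (optionally across
#' multiple worker processes), and assembles the result matrix keyed by
#' pair index. The output is bit-identical for any `nWorkers` and any
#' `batchSize`, because assembly order never depends on completion order.
#'
#' @param dset a [DiscretizedSet-class] from [preprocessDataset()], with at
#'   least 2 genes.
#' @param batchSize pairs per batch, or `"auto"` (default) to size batches
#'   so a batch's working set stays under `memoryBudgetMB`.
#' @param nWorkers number of worker processes (forked; >1 only on Unix).
#' @param backend backend id or [ArrayBackend-class].
#' @param logBase logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @param memoryBudgetMB memory budget used by `batchSize = "auto"`.
#' @param verbose emit per-batch progress messages with pair ranges.
#' @return A [TEMatrix-class]; entry (i, j) is TE from gene i to gene j.
#' @export
computeTEMatrix <- function(dset, batchSize = "auto", nWorkers = 1L,
                            backend = "cpu", logBase = 2,
                            memoryBudgetMB = 512, verbose = FALSE) {
  stopifnot(is(dset, "DiscretizedSet"))
  bins <- binMatrix(dset)
  n <- nrow(bins)
  if (n < 2L) .stopUsage("need at least 2 genes to compute pairwise TE")
  if (ncol(bins) < 2L)
    .stopInsufficient("need at least 2 ordered cells")
  if (!.isCount(nWorkers) || nWorkers < 1L)
    .stopUsage("nWorkers must be a positive integer")
  be <- getBackend(backend)
  nPairs <- n * (n - 1L)
  if (identical(batchSize, "auto"))
    batchSize <- .autoBatchSize(ncol(bins), nPairs, memoryBudgetMB)
  plan <- makeBatchPlan(n, batchSize)
  idx <- seq_len(nBatches(plan))
  worker <- function(b) {
    rows <- plan@starts[b]:plan@ends[b]
    if (verbose)
      message(sprintf("batch %d/%d: pairs %d-%d", b, nBatches(plan),
                      plan@starts[b], plan@ends[b]))
    computeBatch(bins, plan@pairs[rows, , drop = FALSE], be, logBase,
                 batchId = b)
  }
  results <- if (nWorkers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, worker, mc.cores = nWorkers,
                       mc.preschedule = TRUE)
  else lapply(idx, worker)
  failed <- vapply(results, function(r)
    inherits(r, c("try-error", "condition")), logical(1L))
  if (any(failed)) {
    msgs <- vapply(which(failed), function(b) {
      r <- results[[b]]
      sprintf("batch %d (pairs %d-%d): %s", b, plan@starts[b], plan@ends[b],
              if (inherits(r, "condition")) conditionMessage(r)
              else as.character(r))
    }, character(1L))
    .stopCompute(paste0("TE computation failed; no partial matrix is ",
                        "returned.\n", paste(msgs, collapse = "\n")))
  }
  values <- matrix(0, n, n, dimnames = list(rownames(bins), rownames(bins)))
  values[plan@pairs] <- unlist(results, use.names = FALSE)
  new("TEMatrix", values = values, logBase = logBase)
}

#' Transfer-entropy values
#'
#' @param x a [TEMatrix-class].
#' @return the n x n numeric matrix; entry (i, j) is TE from gene i
#'   (source) to gene j (target).
#' @rdname teValues
#' @export
setMethod("teValues", "TEMatrix", function(x) x@values)

setMethod("show", "TEMatrix", function(object) {
  v <- object@values
  off <- v[row(v) != col(v)]
  cat(sprintf(
    "TEMatrix: %d genes, log base %s\n  off-diagonal TE: min %.4g, median %.4g, max %.4g\n",
    nrow(v), format(object@logBase), min(off), stats::median(off), max(off)))
})
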