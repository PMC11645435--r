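# Joint-event counting. The estimator needs, for a gene pair (target X,
# regulator Y), the occurrence counts of the four lag-1 joint events
# (X_{t+1}, X_t, Y_t), (X_{t+1}, X_t), (X_t, Y_t) and (X_t). Two
# representations are provided: the dense b^3 histogram (oracle/diagnostic
# only) and the position-aligned counts over observed unique patterns that
# the production path uses.

.binsOf <- function(x) {
  if (is(x, "DiscretizedSeries")) x@bins
  else if (is.numeric(x)) as.integer(x)
  else .stopUsage("expected a DiscretizedSeries or an integer vector")
}

#' Enumerate lag-1 joint-event triples of a gene pair
#'
#' For discretized series of the target X (`bx`) and the regulator Y
#' (`by`), returns the `l_t - 1` triples (X_{t+1}, X_t, Y_t) in time order.
#'
#' @param bx,by discretized series ([DiscretizedSeries-class] or integer
#'   vectors) of equal length `l_t >= 2`.
#' @return integer matrix with `l_t - 1` rows and columns `xNext`, `xNow`,
#'   `yNow`.
#' @export
enumerateTriples <- function(bx, by) {
  bx <- .binsOf(bx); by <- .binsOf(by)
  if (length(bx) != length(by))
    .stopUsage(sprintf("series lengths differ: %d vs %d",
                       length(bx), length(by)))
  lt <- length(bx)
  if (lt < 2L)
    .stopInsufficient("need at least 2 time points to form one triple")
  cbind(xNext = bx[-1L], xNow = bx[-lt], yNow = by[-lt])
}

#' Build the dense joint-event count array
#'
#' The full `nBins^3` histogram `C[i, j, k]` counting the time steps t with
#' `(bx[t+1], bx[t], by[t]) == (i, j, k)` (0-based bin indices). Retained as
#' an independent testing oracle and for sparsity diagnostics; the
#' production path uses [alignedCounts()] because this cube is almost
#' entirely zeros on real data.
#'
#' @param bx,by discretized series of equal length.
#' @param nBins number of bins; all bin indices must be `< nBins`.
#' @return A [DenseCountArray-class].
#' @export
denseCountArray <- function(bx, by, nBins) {
  tr <- enumerateTriples(bx, by)
  if (!.isCount(nBins) || nBins < 1L) .stopUsage("nBins must be >= 1")
  nBins <- as.integer(nBins)
  if (max(tr) >= nBins)
    .stopBounds(sprintf("bin index %d out of range for nBins = %d",
                        max(tr), nBins))
  lin <- 1L + tr[, 1L] + nBins * tr[, 2L] + nBins * nBins * tr[, 3L]
  counts <- array(tabulate(lin, nbins = nBins^3L),
                  dim = c(nBins, nBins, nBins))
  new("DenseCountArray", counts = counts, nBins = nBins)
}

#' Fraction of zero cells in a dense count array
#'
#' @param x a [DenseCountArray-class].
#' @return the proportion of zero entries in the `nBins^3` cube.
#' @export
zeroFraction <- function(x) {
  stopifnot(is(x, "DenseCountArray"))
  mean(x@counts == 0L)
}

# Shared core used by alignedCounts() and the batch engine: everything is
# expressed through the backend's primitives. Bin pairs/triples are packed
# into scalar keys (base B = max bin + 1) so one sort orders patterns
# lexicographically; sub-pattern counts are aligned back onto the unique
# triples by searchsorted gather.
.alignedCore <- function(bx, by, ops) {
  lt <- length(bx)
  xn <- as.numeric(bx[-1L]); x <- as.numeric(bx[-lt]); y <- as.numeric(by[-lt])
  B <- max(xn, x, y) + 1
  u3 <- ops$uniqueWithCounts(ops$sort((xn * B + x) * B + y))
  uxx <- ops$uniqueWithCounts(ops$sort(xn * B + x))
  uxy <- ops$uniqueWithCounts(ops$sort(x * B + y))
  ux <- ops$uniqueWithCounts(ops$sort(x))
  k3 <- u3$values
  yk <- k3 %% B
  xk <- ((k3 - yk) / B) %% B
  xnk <- (k3 - yk - xk * B) / (B * B)
  list(
    B = B, total = lt - 1L,
    xNext = xnk, xNow = xk, yNow = yk,
    n3 = u3$counts,
    n2xx = uxx$counts[ops$gather(uxx$values, xnk * B + xk)],
    n2xy = uxy$counts[ops$gather(uxy$values, xk * B + yk)],
    n1x = ux$counts[ops$gather(ux$values, xk)]
  )
}

#' Build position-aligned count arrays over observed patterns
#'
#' Counts the four lag-1 joint events of a gene pair over only the unique
#' triple patterns actually observed in the series, sorted
#' lexicographically, with all four count vectors aligned per pattern. The
#' memory footprint is proportional to the number of observed patterns (at
#' most `l_t - 1`), not to `nBins^3`.
#'
#' @param bx,by discretized series (target X, regulator Y) of equal length
#'   `l_t >= 2`.
#' @param backend backend id or [ArrayBackend-class] used for the array
#'   primitives (default: reference CPU backend).
#' @return An [AlignedCounts-class].
#' @examples
#' ac <- alignedCounts(c(1, 0, 0, 1, 0), c(0, 0, 1, 0, 1))
#' transferEntropyPair(ac)  # 0.5 bits
#' @export
alignedCounts <- function(bx, by, backend = "cpu") {
  bx <- .binsOf(bx); by <- .binsOf(by)
  tr <- enumerateTriples(bx, by)  # validates lengths / l_t
  ops <- getBackend(backend)@ops
  core <- .alignedCore(bx, by, ops)
  patterns <- cbind(xNext = as.integer(core$xNext),
                    xNow = as.integer(core$xNow),
                    yNow = as.integer(core$yNow))
  new("AlignedCounts", patterns = patterns,
      n3 = as.integer(core$n3), n2xx = as.integer(core$n2xx),
      n2xy = as.integer(core$n2xy), n1x = as.integer(core$n1x),
      total = as.integer(core$total))
}

setMethod("show", "AlignedCounts", function(object) {
  cat(sprintf(
    "AlignedCounts: %d unique patterns over %d lagged steps\n",
    nrow(object@patterns), object@total))
})

setMethod("show", "DenseCountArray", function(object) {
  cat(sprintf("DenseCountArray: %d^3 cells, %.1f%% zero\n",
              object@nBins, 100 * mean(object@counts == 0L)))
})
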