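#' Order selected cells along pseudotime
#'
#' Returns the original column indices of the selected cells, sorted by
#' ascending pseudotime. Ties are broken by ascending original column index
#' (stable), so the ordering is identical across runs and worker counts.
#'
#' @param pseudotime numeric pseudotime per cell.
#' @param selected logical selection flag per cell (default: all selected).
#' @return integer vector of original cell indices in trajectory order.
#' @export
orderCells <- function(pseudotime, selected = rep(TRUE, length(pseudotime))) {
  if (length(selected) != length(pseudotime))
    .stopLength("pseudotime and selected must have equal length")
  idx <- which(selected)
  if (length(idx) < 2L)
    .stopInsufficient(sprintf("only %d selected cell(s); need at least 2",
                              length(idx)))
  pt <- pseudotime[idx]
  if (any(!is.finite(pt)))
    .stopValue("non-finite pseudotime among selected cells")
  idx[order(pt, method = "radix")]
}

#' Centered moving-average smoothing
#'
#' Smooths a series with a centered moving average of odd width `window`.
#' Near the series ends the window truncates to the available indices, so
#' the first and last points average over the available half-window.
#' `window = 1` is the identity.
#'
#' @param values numeric series.
#' @param window odd positive integer window width, at most the series
#'   length.
#' @return numeric series of the same length.
#' @examples
#' smoothSeries(c(0, 2, 4), 3)  # c(1, 2, 3)
#' @export
smoothSeries <- function(values, window) {
  n <- length(values)
  if (!.isCount(window) || window < 1L || window %% 2L == 0L)
    .stopUsage("window must be an odd positive integer")
  if (window > n)
    .stopUsage(sprintf("window (%d) exceeds series length (%d)", window, n))
  if (window == 1L) return(as.numeric(values))
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Discretize a continuous series into bin indices
#'
#' Maps a numeric series to integer bin indices in `[0, nBins - 1]`.
#'
#' `equal_width` partitions the observed range into `nBins` equal
#' intervals: value v maps to `floor((v - min) / (max - min) * nBins)`,
#' clipped to `nBins - 1` at the top, so a value exactly on an internal edge
#' falls into the upper bin. A constant series maps entirely to bin 0.
#'
#' `equal_frequency` places bin boundaries at the empirical quantiles
#' `i/nBins`, assigning by stable rank (ties split in order of appearance),
#' so bin occupancies differ by at most one plus tie-group effects.
#'
#' @param values finite numeric series, length >= 2.
#' @param nBins positive number of bins.
#' @param method `"equal_width"` (default) or `"equal_frequency"`.
#' @param geneName optional gene identifier carried on the result.
#' @return A [DiscretizedSeries-class].
#' @export
discretize <- function(values, nBins,
                       method = c("equal_width", "equal_frequency"),
                       geneName = "") {
  method <- match.arg(method)
  if (length(values) == 0L) .stopUsage("cannot discretize an empty series")
  if (length(values) < 2L)
    .stopInsufficient("series of length < 2 cannot form a lagged triple")
  if (!.isCount(nBins) || nBins < 1L) .stopUsage("nBins must be >= 1")
  if (any(!is.finite(values))) .stopValue("values must be finite")
  nBins <- as.integer(nBins)
  n <- length(values)
  if (method == "equal_width") {
    lo <- min(values); rng <- max(values) - lo
    bins <- if (rng == 0) rep(0L, n)
    else pmin(as.integer(floor((values - lo) / rng * nBins)), nBins - 1L)
  } else {
    ord <- order(values, method = "radix")  # stable: ties keep file order
    bins <- integer(n)
    bins[ord] <- as.integer(floor((seq_len(n) - 1L) * nBins / n))
  }
  new("DiscretizedSeries", bins = bins, nBins = nBins,
      geneName = as.character(geneName))
}

# Bin-count heuristics. "auto" is the fourth-root rule b = ceil(l_t^(1/4)),
# sized for the THREE-dimensional joint histogram the estimator fills:
# b^3 ~ l_t^(3/4) stays below the number of lagged steps, so joint cells
# keep usable occupancy. "sqrt" (the classical 1-D histogram rule) is kept
# as an option, but with b = sqrt(l_t) the b^3 grid far exceeds the sample
# count and the plug-in estimate is bias-saturated.
.resolveBins <- function(nBins, lt) {
  if (identical(nBins, "auto")) return(max(2L, as.integer(ceiling(lt^0.25))))
  if (identical(nBins, "sqrt")) return(as.integer(ceiling(sqrt(lt))))
  if (!.isCount(nBins) || nBins < 1L)
    .stopUsage("nBins must be a positive integer, \"auto\" or \"sqrt\"")
  as.integer(nBins)
}

#' Preprocess a dataset into discretized series
#'
#' Runs the full preprocessing chain for every gene: take the selected cells
#' in pseudotime order, optionally smooth with a centered moving average,
#' and discretize into bin indices. All genes share the same cell ordering
#' and series length.
#'
#' @param ds an [ExpressionDataset-class] with finite pseudotime on the
#'   selected cells.
#' @param nBins number of bins: a positive integer, `"auto"` (default) for
#'   the fourth-root rule `max(2, ceiling(l_t^(1/4)))` sized for the
#'   3-dimensional joint histogram the TE estimator fills, or `"sqrt"` for
#'   the classical 1-D histogram rule `ceiling(sqrt(l_t))` (`l_t` = number
#'   of selected cells).
#' @param method discretization method, see [discretize()].
#' @param window odd smoothing window width, see [smoothSeries()];
#'   `1` (default) disables smoothing.
#' @return A [DiscretizedSet-class].
#' @export
preprocessDataset <- function(ds, nBins = "auto",
                              method = c("equal_width", "equal_frequency"),
                              window = 1L) {
  stopifnot(is(ds, "ExpressionDataset"))
  method <- match.arg(method)
  sel <- selectedCells(ds)
  if (sum(sel) < 3L)
    .stopInsufficient(sprintf(
      "only %d selected cell(s); at least 3 are required", sum(sel)))
  ord <- orderCells(pseudotime(ds), sel)
  lt <- length(ord)
  nb <- .resolveBins(nBins, lt)
  m <- exprMatrix(ds)[, ord, drop = FALSE]
  bins <- matrix(0L, nrow = nrow(m), ncol = lt,
                 dimnames = list(rownames(m), NULL))
  for (g in seq_len(nrow(m))) {
    v <- smoothSeries(m[g, ], window)
    bins[g, ] <- discretize(v, nb, method)@bins
  }
  new("DiscretizedSet", bins = bins, nBins = nb,
      cellOrder = as.integer(ord), cellIds = colnames(m))
}

#' Number of bins of a discretized object
#'
#' @param x a discretized object.
#' @return the number of bins.
#' @rdname nBins
#' @export
setMethod("nBins", "DiscretizedSeries", function(x) x@nBins)

#' @rdname nBins
#' @export
setMethod("nBins", "DiscretizedSet", function(x) x@nBins)

#' Bin-index matrix of a discretized set
#'
#' @param x a [DiscretizedSet-class].
#' @return integer matrix, genes x ordered cells.
#' @rdname binMatrix
#' @export
setMethod("binMatrix", "DiscretizedSet", function(x) x@bins)

setMethod("show", "DiscretizedSet", function(object) {
  cat(sprintf("DiscretizedSet: %d genes x %d ordered cells, %d bins\n",
              nrow(object@bins), ncol(object@bins), object@nBins))
})

setMethod("show", "DiscretizedSeries", function(object) {
  cat(sprintf("DiscretizedSeries '%s': length %d, %d bins\n",
              object@geneName, length(object@bins), object@nBins))
})
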