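#' Call significant directed edges from a TE matrix
#'
#' Scores every off-diagonal TE value against the empirical distribution of
#' all off-diagonal TE values: each value is z-scored with the global mean
#' and standard deviation, converted to a one-tailed upper p-value, and the
#' `n(n-1)` p-values are adjusted jointly by Benjamini-Hochberg. Edges with
#' adjusted p at or below `fdrLevel` are retained. This global-background
#' z-test is this package's edge-calling convention; it is isolated here so
#' alternative significance procedures can be swapped in.
#'
#' @param te a [TEMatrix-class] with at least 2 genes.
#' @param fdrLevel Benjamini-Hochberg level in (0, 1); default 0.01.
#' @return An [EdgeList-class], rows sorted by descending TE (ties by
#'   source then target).
#' @export
edgesFromTE <- function(te, fdrLevel = 0.01) {
  stopifnot(is(te, "TEMatrix"))
  if (!is.numeric(fdrLevel) || length(fdrLevel) != 1L || fdrLevel <= 0 ||
      fdrLevel >= 1)
    .stopUsage("fdrLevel must lie strictly between 0 and 1")
  v <- teValues(te)
  off <- row(v) != col(v)
  scores <- v[off]
  if (length(scores) < 2L)
    .stopUsage("need at least 2 off-diagonal TE values")
  s <- stats::sd(scores)
  if (s == 0)
    .stopDegenerate(paste0(
      "all off-diagonal TE values are identical; the background ",
      "distribution is degenerate and no edges can be inferred"))
  z <- (scores - mean(scores)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  gn <- geneNames(te)
  src <- gn[row(v)[off]]
  tgt <- gn[col(v)[off]]
  keep <- padj <= fdrLevel
  e <- data.frame(source = src[keep], target = tgt[keep],
                  te = scores[keep], z = z[keep], padj = padj[keep],
                  stringsAsFactors = FALSE)
  e <- e[order(-e$te, e$source, e$target, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  new("EdgeList", edges = e, fdrLevel = fdrLevel)
}

#' Retained edges of an EdgeList
#'
#' @param x an [EdgeList-class].
#' @return data.frame with columns source, target, te, z, padj.
#' @rdname edges
#' @export
setMethod("edges", "EdgeList", function(x) x@edges)

#' Rank candidate hub regulators by outdegree
#'
#' Counts each gene's outgoing retained edges and ranks genes by descending
#' outdegree, ties broken lexicographically. Genes with no outgoing edges
#' are omitted. A high-outdegree gene is a candidate key regulator of the
#' trajectory.
#'
#' @param edgeList an [EdgeList-class].
#' @return data.frame with columns `gene`, `outdegree`, in rank order.
#' @examples
#' # edges A->B, A->C, B->C rank A (outdegree 2) above B (outdegree 1)
#' @export
hubRanking <- function(edgeList) {
  stopifnot(is(edgeList, "EdgeList"))
  e <- edges(edgeList)
  if (nrow(e) == 0L)
    return(data.frame(gene = character(0), outdegree = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(e$source)
  out <- data.frame(gene = names(tab), outdegree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$outdegree, out$gene, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "EdgeList", function(object) {
  cat(sprintf("EdgeList: %d edge(s) at BH level %g\n",
              nrow(object@edges), object@fdrLevel))
  if (nrow(object@edges))
    print(utils::head(object@edges, 5L))
})
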