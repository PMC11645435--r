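# Backend registry. A backend is a named list of array primitives; every
# engine computation is expressed through these six operations so that an
# accelerated implementation (GPU array library, compiled code) can be
# swapped in without touching the algorithm.

.backendRegistry <- new.env(parent = emptyenv())

.requiredOps <- c("sort", "uniqueWithCounts", "repeatEach", "gather",
                  "log", "segmentSum")

#' Register an array-computing backend
#'
#' A backend must provide all six contract operations as functions:
#' \describe{
#'   \item{sort(x)}{ascending sort of a numeric vector.}
#'   \item{uniqueWithCounts(xSorted)}{`list(values, counts)` of runs in an
#'     already-sorted vector.}
#'   \item{repeatEach(x, times)}{each element repeated `times` times.}
#'   \item{gather(table, queries)}{searchsorted-style lookup: for each query
#'     (guaranteed present) the index of its position in the sorted
#'     `table`.}
#'   \item{log(x)}{elementwise natural logarithm.}
#'   \item{segmentSum(values, ids, n)}{sum of `values` per integer segment
#'     id in `1..n`.}
#' }
#' A backend missing any operation is rejected at registration time
#' (capability error), never mid-run.
#'
#' @param name backend identifier.
#' @param ops named list of the contract operations.
#' @return The registered [ArrayBackend-class], invisibly.
#' @export
registerBackend <- function(name, ops) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stopUsage("backend name must be a non-empty string")
  missing <- setdiff(.requiredOps, names(ops))
  if (length(missing))
    .stopCapability(sprintf("backend '%s' lacks required operation(s): %s",
                            name, paste(missing, collapse = ", ")))
  notFun <- names(ops)[!vapply(ops, is.function, logical(1L))]
  if (length(notFun))
    .stopCapability(sprintf("backend '%s': not a function: %s", name,
                            paste(notFun, collapse = ", ")))
  be <- new("ArrayBackend", name = name, ops = ops)
  assign(name, be, envir = .backendRegistry)
  invisible(be)
}

#' Look up a registered backend
#'
#' @param backend a backend id string or an [ArrayBackend-class] object
#'   (returned unchanged).
#' @return An [ArrayBackend-class].
#' @export
getBackend <- function(backend = "cpu") {
  if (is(backend, "ArrayBackend")) return(backend)
  if (!exists(backend, envir = .backendRegistry))
    .stopCapability(sprintf(
      "unknown backend '%s' (registered: %s)", backend,
      paste(listBackends(), collapse = ", ")))
  get(backend, envir = .backendRegistry)
}

#' List registered backend names
#'
#' @return character vector of backend ids.
#' @export
listBackends <- function() sort(ls(.backendRegistry))

# Reference CPU backend on base R primitives.
.cpuBackendOps <- function() {
  list(
    sort = function(x) sort.int(x, method = "radix"),
    uniqueWithCounts = function(xSorted) {
      r <- rle(xSorted)
      list(values = r$values, counts = r$lengths)
    },
    repeatEach = function(x, times) rep.int(x, times),
    gather = function(table, queries) findInterval(queries, table),
    log = function(x) log(x),
    segmentSum = function(values, ids, n) {
      out <- numeric(n)
      agg <- rowsum(values, ids)
      out[as.integer(rownames(agg))] <- agg[, 1L]
      out
    }
  )
}

setMethod("show", "ArrayBackend", function(object) {
  cat(sprintf("ArrayBackend '%s' providing: %s\n", object@name,
              paste(names(object@ops), collapse = ", ")))
})
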