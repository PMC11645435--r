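# Synthetic-data generator. Emulates, at desk scale, the shape of a
# pseudotime-ordered scRNAseq experiment with known ground truth: planted
# regulator genes drive assigned target genes through lag-1 dynamics with an
# exogenous driver, the minimal process for which lag-1 transfer entropy is
# the matched statistic. Everything downstream can therefore be tested
# without external data.
#
# Process design. The regulator is a smooth MEAN-REVERTING walk (stationary
# AR(1)), not a pure random walk: an unbounded walk drifts into the
# saturated range of the tanh coupling map and the planted signal dies out.
# The target law
#   X[t+1] = coupling * tanh(Y[t]) + (1 - coupling) * phi * X[t] + eps
# reduces at coupling = 0 to exactly the same AR(1) family as the
# unregulated noise genes, giving a clean null.

.ar1Series <- function(n, phi, statSd) {
  innovSd <- statSd * sqrt(1 - phi^2)
  y <- numeric(n)
  y[1L] <- stats::rnorm(1L, 0, statSd)
  e <- stats::rnorm(n - 1L, 0, innovSd)
  for (t in seq_len(n - 1L)) y[t + 1L] <- phi * y[t] + e[t]
  y
}

.drivenSeries <- function(driver, coupling, phi, noiseSd) {
  n <- length(driver)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, noiseSd)
  eps <- stats::rnorm(n - 1L, 0, noiseSd)
  for (t in seq_len(n - 1L))
    x[t + 1L] <- coupling * tanh(driver[t]) + (1 - coupling) * phi * x[t] +
      eps[t]
  x
}

#' Generate one regulator-target series pair with known coupling
#'
#' The regulator Y is a smooth mean-reverting walk (stationary AR(1) with
#' memory `phi` and stationary standard deviation `statSd`). The target X
#' follows `X[t+1] = coupling * tanh(Y[t]) + (1 - coupling) * phi * X[t] +
#' noise`, so with `coupling > 0` the generative law makes Y_t informative
#' about X_{t+1} beyond X_t, and with `coupling = 0` X evolves
#' independently of Y by construction (an AR(1) of its own).
#'
#' @param lt series length (number of pseudotime points), at least 10.
#' @param coupling coupling strength in `[0, 1]`; default 0.8.
#' @param noiseSd standard deviation of the target's innovation noise;
#'   default 0.1.
#' @param seed RNG seed; the call sets the RNG state.
#' @param phi AR(1) memory of the regulator (and of the target's own
#'   recurrence); default 0.3.
#' @param statSd stationary standard deviation of the regulator; default
#'   0.8, which keeps the walk inside the responsive range of `tanh`.
#' @return `list(regulator =, target =)` numeric series of length `lt`.
#' @export
generateCoupledPair <- function(lt, coupling = 0.8, noiseSd = 0.1, seed = 1L,
                                phi = 0.3, statSd = 0.8) {
  if (!.isCount(lt) || lt < 10L) .stopUsage("lt must be an integer >= 10")
  if (!is.numeric(coupling) || length(coupling) != 1L || coupling < 0 ||
      coupling > 1)
    .stopUsage("coupling must lie in [0, 1]")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd <= 0)
    .stopUsage("noiseSd must be positive")
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi >= 1)
    .stopUsage("phi must lie in [0, 1)")
  set.seed(seed)
  y <- .ar1Series(lt, phi, statSd)
  x <- .drivenSeries(y, coupling, phi, noiseSd)
  list(regulator = y, target = x)
}

#' Generate a synthetic expression dataset with planted regulators
#'
#' Builds a genes x cells [ExpressionDataset-class] along a generated
#' pseudotime axis (sorted uniform draws; pseudotime is an input to this
#' workflow, not inferred). The first `nRegulators` genes are smooth
#' mean-reverting walks; each drives `targetsPerRegulator` target genes
#' through the coupled-pair dynamics (independent noise per target); the
#' remaining genes are independent draws of the same AR(1) null process.
#' Latent series are shifted per gene to their minimum so expression values
#' are non-negative. Gene roles are recorded in `rowData` (`role` in
#' regulator/target/noise, `drivenBy` naming the planted driver).
#'
#' @param nGenes total number of genes; default 10.
#' @param nCells number of cells; default 300.
#' @param nRegulators number of planted regulators; default 1.
#' @param targetsPerRegulator targets driven by each regulator; default 4.
#'   `nRegulators * targetsPerRegulator` must not exceed
#'   `nGenes - nRegulators`.
#' @param coupling coupling strength; default 0.8.
#' @param noiseSd target innovation noise; default 0.1.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @param phi AR(1) memory of regulators and noise genes; default 0.3.
#' @param statSd stationary standard deviation of regulator and noise
#'   series; default 0.8.
#' @return An [ExpressionDataset-class] with pseudotime attached and all
#'   cells selected.
#' @examples
#' ds <- generateDataset(seed = 7)
#' SummarizedExperiment::rowData(ds)
#' @export
generateDataset <- function(nGenes = 10L, nCells = 300L, nRegulators = 1L,
                            targetsPerRegulator = 4L, coupling = 0.8,
                            noiseSd = 0.1, seed = 1L, phi = 0.3,
                            statSd = 0.8) {
  for (v in list(nGenes, nCells, nRegulators, targetsPerRegulator))
    if (!.isCount(v) || v < 0L)
      .stopUsage("counts must be non-negative integers")
  if (nCells < 10L) .stopUsage("nCells must be at least 10")
  if (nRegulators * targetsPerRegulator > nGenes - nRegulators)
    .stopUsage(paste0("nRegulators * targetsPerRegulator must not exceed ",
                      "nGenes - nRegulators"))
  set.seed(seed)
  pt <- sort(stats::runif(nCells))
  nTargets <- nRegulators * targetsPerRegulator
  nNoise <- nGenes - nRegulators - nTargets
  raw <- matrix(0, nrow = nGenes, ncol = nCells)
  role <- character(nGenes)
  drivenBy <- rep(NA_character_, nGenes)
  geneNames <- c(sprintf("R%02d", seq_len(nRegulators)),
                 sprintf("T%02d", seq_len(nTargets)),
                 sprintf("N%02d", seq_len(nNoise)))
  for (r in seq_len(nRegulators)) {
    raw[r, ] <- .ar1Series(nCells, phi, statSd)
    role[r] <- "regulator"
  }
  row <- nRegulators
  for (r in seq_len(nRegulators)) {
    for (k in seq_len(targetsPerRegulator)) {
      row <- row + 1L
      raw[row, ] <- .drivenSeries(raw[r, ], coupling, phi, noiseSd)
      role[row] <- "target"
      drivenBy[row] <- geneNames[r]
    }
  }
  for (g in seq_len(nNoise)) {
    raw[row + g, ] <- .ar1Series(nCells, phi, statSd)
    role[row + g] <- "noise"
  }
  expr <- raw - apply(raw, 1L, min)  # per-gene shift to non-negative
  dimnames(expr) <- list(geneNames, sprintf("cell%04d", seq_len(nCells)))
  ExpressionDataset(
    expr, pseudotime = pt, selected = rep(TRUE, nCells),
    rowData = S4Vectors::DataFrame(role = role, drivenBy = drivenBy,
                                   row.names = geneNames))
}
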