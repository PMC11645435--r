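# Independent oracles for the event-counting and TE paths. These build the
# full dense joint histogram by explicit looping and evaluate the plug-in
# transfer entropy cell by cell; they share no code with the aligned
# production path.

oracleDenseCounts <- function(bx, by, nBins) {
  lt <- length(bx)
  counts <- array(0L, dim = c(nBins, nBins, nBins))
  for (t in seq_len(lt - 1L)) {
    i <- bx[t + 1L] + 1L; j <- bx[t] + 1L; k <- by[t] + 1L
    counts[i, j, k] <- counts[i, j, k] + 1L
  }
  counts
}

# Plug-in TE by direct evaluation over all b^3 cells of the dense
# histogram, skipping zero cells (0 * log(.) = 0 convention).
oracleTE <- function(bx, by, nBins, logBase = 2) {
  counts <- oracleDenseCounts(bx, by, nBins)
  total <- sum(counts)
  cXX <- apply(counts, c(1, 2), sum)   # (x_next, x_now)
  cXY <- apply(counts, c(2, 3), sum)   # (x_now, y_now)
  cX <- apply(counts, 2, sum)          # (x_now)
  te <- 0
  nb <- nBins
  for (i in seq_len(nb)) for (j in seq_len(nb)) for (k in seq_len(nb)) {
    c3 <- counts[i, j, k]
    if (c3 == 0L) next
    p3 <- c3 / total
    te <- te + p3 * log((p3 * (cX[j] / total)) /
                          ((cXX[i, j] / total) * (cXY[j, k] / total)),
                        base = logBase)
  }
  te
}

# Random bin series pair with the sampling scheme used by the seeded
# property suites: lengths 2..50, bins 2..8.
randomSeriesPair <- function() {
  nb <- sample(2:8, 1L)
  lt <- sample(2:50, 1L)
  list(bx = sample.int(nb, lt, replace = TRUE) - 1L,
       by = sample.int(nb, lt, replace = TRUE) - 1L,
       nBins = nb)
}

# Fixed length-14 pair over 5 bins whose 13 consecutive lag-1 triples are
# all distinct: the target cycles through the 5 bins while the regulator
# steps up every 5 positions, so each (x_next, x_now) recurrence carries a
# fresh y.
distinctTriplePair <- function() {
  list(bx = rep(0:4, length.out = 14L),
       by = (seq_len(14L) - 1L) %/% 5L)
}
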