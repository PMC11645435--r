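test_that("pairwise TE matches hand evaluation on the pinned examples", {
  # x_next copies y_now: exactly half a bit over 4 lagged steps
  ac <- alignedCounts(c(1L, 0L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L, 1L))
  expect_equal(transferEntropyPair(ac), 0.5)
  # every term's count ratio is 1: zero TE
  expect_equal(transferEntropyPair(
    alignedCounts(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L))), 0)
  # constant pair: single pattern, zero TE
  expect_equal(transferEntropyPair(alignedCounts(rep(2L, 5), rep(2L, 5))), 0)
})

test_that("log base only rescales the TE value", {
  ac <- alignedCounts(c(1L, 0L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L, 1L))
  expect_equal(transferEntropyPair(ac, logBase = exp(1)),
               0.5 * log(2))
  expect_error(transferEntropyPair(ac, logBase = 1),
               class = "tegrn_usage_error")
})

test_that("aligned-path TE equals the dense-histogram plug-in oracle", {
  set.seed(12)
  for (i in 1:300) {
    p <- randomSeriesPair()
    te <- transferEntropyPair(alignedCounts(p$bx, p$by))
    expect_true(abs(te - oracleTE(p$bx, p$by, p$nBins)) < 1e-12)
    expect_gte(te, 0)
  }
})

test_that("constant regulator carries zero transfer entropy", {
  set.seed(3)
  for (i in 1:20) {
    p <- randomSeriesPair()
    expect_equal(transferEntropyPair(
      alignedCounts(p$bx, rep(0L, length(p$bx)))), 0)
  }
})

test_that("ordered pair enumeration is the full nP2 set in row-major order", {
  expect_identical(unname(enumeratePairs(2)),
                   matrix(c(1L, 2L, 2L, 1L), ncol = 2, byrow = TRUE))
  p10 <- enumeratePairs(10)
  expect_identical(nrow(p10), 90L)
  expect_false(any(p10[, 1] == p10[, 2]))
  expect_false(is.unsorted(p10[, 1]))
  expect_error(enumeratePairs(1), class = "tegrn_usage_error")
})

test_that("batch plans tile the pair sequence contiguously", {
  plan <- makeBatchPlan(3, 4)
  expect_identical(nBatches(plan), 2L)
  expect_identical(plan@ends - plan@starts + 1L, c(4L, 2L))
  expect_identical(nBatches(makeBatchPlan(2, 100)), 1L)
  expect_identical(nBatches(makeBatchPlan(4, 1)), 12L)
  expect_error(makeBatchPlan(3, 0), class = "tegrn_usage_error")
})

test_that("computeBatch composes per-pair TE and respects pair order", {
  set.seed(8)
  bins <- matrix(sample(0:3, 30, replace = TRUE), nrow = 3,
                 dimnames = list(c("a", "b", "c"), NULL))
  pairs <- enumeratePairs(3)
  te <- computeBatch(bins, pairs)
  for (r in seq_len(nrow(pairs)))
    expect_equal(te[r], transferEntropyPair(
      alignedCounts(bins[pairs[r, 2], ], bins[pairs[r, 1], ])))
  perm <- sample(nrow(pairs))
  expect_identical(computeBatch(bins, pairs[perm, ]), te[perm])
})

test_that("the copy-dynamics pair surfaces as 0.5 bits in a batch", {
  bins <- rbind(x = c(1L, 0L, 0L, 1L, 0L), y = c(0L, 0L, 1L, 0L, 1L))
  te <- computeBatch(bins, cbind(2L, 1L))  # source y -> target x
  expect_equal(te, 0.5)
})

test_that("TE matrix orientation and diagonal follow the contract", {
  bx <- c(1L, 0L, 0L, 1L, 0L); by <- c(0L, 0L, 1L, 0L, 1L)
  dset <- new("DiscretizedSet",
              bins = rbind(X = bx, Y = by), nBins = 2L,
              cellOrder = 1:5, cellIds = paste0("c", 1:5))
  te <- computeTEMatrix(dset, nWorkers = 1)
  v <- teValues(te)
  expect_equal(v["Y", "X"], 0.5)  # source row, target column
  expect_equal(v["X", "Y"], oracleTE(by, bx, 2))
  expect_identical(diag(v), c(X = 0, Y = 0))
})

test_that("TE matrix is bit-identical across workers and batch sizes", {
  ds <- generateDataset(seed = 42)
  dset <- preprocessDataset(ds)
  ref <- teValues(computeTEMatrix(dset, batchSize = "auto", nWorkers = 1))
  for (w in c(2L, 4L))
    expect_identical(teValues(computeTEMatrix(dset, nWorkers = w)), ref)
  for (b in c(1L, 7L, 64L, 90L))
    expect_identical(teValues(computeTEMatrix(dset, batchSize = b)), ref)
  expect_true(all(ref >= 0))
  expect_identical(unname(diag(ref)), rep(0, 10))
})

test_that("backends are validated at registration, not mid-run", {
  ops <- teGRN:::.cpuBackendOps()
  expect_error(registerBackend("broken", ops[setdiff(names(ops),
                                                     "uniqueWithCounts")]),
               class = "tegrn_capability_error")
  expect_error(getBackend("no-such-backend"),
               class = "tegrn_capability_error")
  expect_true("cpu" %in% listBackends())
})

test_that("an independently implemented backend agrees with the reference", {
  # order() + tabulate-based primitives instead of sort.int/rle/findInterval
  alt <- list(
    sort = function(x) x[order(x)],
    uniqueWithCounts = function(xSorted) {
      u <- unique(xSorted)
      list(values = u, counts = as.integer(table(match(xSorted, u))))
    },
    repeatEach = function(x, times) rep(x, times = times),
    gather = function(table, queries) match(queries, table),
    log = base::log,
    segmentSum = function(values, ids, n)
      vapply(seq_len(n), function(i) sum(values[ids == i]), numeric(1))
  )
  registerBackend("alt", alt)
  set.seed(77)
  for (i in 1:100) {
    p <- randomSeriesPair()
    expect_equal(transferEntropyPair(alignedCounts(p$bx, p$by, "alt")),
                 transferEntropyPair(alignedCounts(p$bx, p$by, "cpu")),
                 tolerance = 1e-10)
  }
})
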