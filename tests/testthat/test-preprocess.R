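test_that("cells are ordered by pseudotime with stable tie-break", {
  expect_identical(orderCells(c(0.3, 0.1, 0.2)), c(2L, 3L, 1L))
  expect_identical(orderCells(c(0.1, 0.1)), c(1L, 2L))
  expect_identical(orderCells(c(0.5, 0.0, 0.2), c(TRUE, FALSE, TRUE)),
                   c(3L, 1L))
  expect_error(orderCells(c(0.1, 0.2), c(TRUE, FALSE)),
               class = "tegrn_insufficient_data_error")
  expect_error(orderCells(c(0.1, NA, 0.2)), class = "tegrn_value_error")
})

test_that("ordering is a permutation of the selected indices", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    pt <- rnorm(n)
    sel <- runif(n) < 0.8
    if (sum(sel) < 2) next
    ord <- orderCells(pt, sel)
    expect_identical(sort(ord), which(sel))
    expect_true(!is.unsorted(pt[ord]))
  }
})

test_that("moving-average smoothing matches hand arithmetic at the edges", {
  expect_identical(smoothSeries(c(0, 2, 4), 1), c(0, 2, 4))
  expect_identical(smoothSeries(c(0, 2, 4), 3), c(1, 2, 3))
  expect_identical(smoothSeries(rep(5, 4), 3), rep(5, 4))
  expect_error(smoothSeries(1:5, 2), class = "tegrn_usage_error")
  expect_error(smoothSeries(1:5, -1), class = "tegrn_usage_error")
  expect_error(smoothSeries(1:3, 5), class = "tegrn_usage_error")
})

test_that("smoothing preserves constants and never leaves the value range", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    v <- rnorm(n)
    w <- sample(seq(1, min(n, 11), by = 2), 1)
    s <- smoothSeries(v, w)
    expect_length(s, n)
    expect_true(all(s >= min(v) - 1e-12 & s <= max(v) + 1e-12))
  }
})

test_that("equal-width binning follows the floor formula with upper-edge rule", {
  expect_identical(discretize(c(0, 1, 2, 3, 4), 5)@bins, 0:4)
  expect_identical(discretize(c(7, 7, 7), 4)@bins, c(0L, 0L, 0L))
  # value exactly on the internal edge (5 of [0,10] with 2 bins) goes up
  expect_identical(discretize(c(10, 0, 5, 1), 2)@bins, c(1L, 0L, 1L, 0L))
  expect_error(discretize(numeric(0), 3), class = "tegrn_usage_error")
  expect_error(discretize(1:5, 0), class = "tegrn_usage_error")
  expect_error(discretize(c(1, Inf, 3), 2), class = "tegrn_value_error")
})

test_that("equal-width bins are invariant to positive affine rescaling", {
  set.seed(13)
  for (i in 1:25) {
    v <- rnorm(sample(5:50, 1))
    a <- sample(c(0.5, 2, 10), 1); b <- sample(c(-3, 0, 7), 1)
    nb <- sample(2:8, 1)
    expect_identical(discretize(a * v + b, nb)@bins, discretize(v, nb)@bins)
  }
})

test_that("equal-frequency bins balance occupancy with stable tie handling", {
  d <- discretize(c(5, 1, 4, 2, 3, 6), 3, method = "equal_frequency")
  expect_identical(as.integer(table(d@bins)), c(2L, 2L, 2L))
  expect_identical(d@bins, c(2L, 0L, 1L, 0L, 1L, 2L))
  # heavy ties: occupancies differ by at most the tie-group effects,
  # and every bin index stays in range
  dt <- discretize(c(1, 1, 1, 1, 2, 2), 3, method = "equal_frequency")
  expect_true(all(dt@bins >= 0L & dt@bins <= 2L))
  # ties split by order of appearance (stable rank)
  expect_identical(dt@bins[1:4], c(0L, 0L, 1L, 1L))
})

test_that("preprocessDataset composes ordering, smoothing and binning", {
  m <- matrix(c(10, 30, 50, 20, 40,
                3, 3, 3, 3, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("c", 1:5)))
  ds <- ExpressionDataset(m, pseudotime = c(0.1, 0.3, 0.5, 0.2, 0.4))
  dset <- preprocessDataset(ds, nBins = 5)
  # gA is 10..50 in pseudotime order: the uniform grid identity
  expect_identical(unname(binMatrix(dset)["gA", ]), 0:4)
  # constant gene maps to all-zero bins
  expect_identical(unname(binMatrix(dset)["gB", ]), rep(0L, 5))
  expect_identical(dset@cellOrder, c(1L, 4L, 2L, 5L, 3L))

  selectedCells(ds) <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_error(preprocessDataset(ds),
               class = "tegrn_insufficient_data_error")
})

test_that("default bin count follows the fourth-root rule", {
  m <- matrix(runif(2 * 300), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  ds <- ExpressionDataset(m, pseudotime = seq_len(300))
  expect_identical(nBins(preprocessDataset(ds)), 5L)      # ceil(300^(1/4))
  expect_identical(nBins(preprocessDataset(ds, "sqrt")), 18L)
  expect_identical(nBins(preprocessDataset(ds, 7)), 7L)
})
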