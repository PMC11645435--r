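writeLinesTo <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

test_that("expression matrices read back in either orientation", {
  p <- writeLinesTo(c("gene\tc1\tc2\tc3", "g1\t1\t2\t3", "g2\t4\t5\t6"),
                    "expr.tsv")
  ds <- readExpression(p)
  expect_identical(geneNames(ds), c("g1", "g2"))
  expect_identical(colnames(ds), c("c1", "c2", "c3"))
  expect_equal(unname(exprMatrix(ds)),
               matrix(1:6, nrow = 2, byrow = TRUE), ignore_attr = FALSE)
  expect_true(all(is.na(pseudotime(ds))))
  expect_true(all(selectedCells(ds)))

  # the transposed file with the other orientation gives the identical set
  pt <- writeLinesTo(c("cell,g1,g2", "c1,1,4", "c2,2,5", "c3,3,6"),
                     "expr_t.csv")
  dt <- readExpression(pt, orientation = "cells_by_genes")
  expect_identical(exprMatrix(dt), exprMatrix(ds))
})

test_that("expression reader rejects malformed input with precise errors", {
  dup <- writeLinesTo(c("gene\tc1\tc2", "g1\t1\t2", "g1\t3\t4"), "dup.tsv")
  expect_error(readExpression(dup), class = "tegrn_duplicate_error")

  bad <- writeLinesTo(c("gene\tc1\tc2", "g1\t1\tx", "g2\t3\t4"), "bad.tsv")
  err <- expect_error(readExpression(bad), class = "tegrn_parse_error")
  expect_match(conditionMessage(err), "c2")

  empty <- writeLinesTo(character(0), "empty.tsv")
  expect_error(readExpression(empty), class = "tegrn_format_error")

  mixed <- writeLinesTo(c("gene\tc1,c2", "g1\t1\t2"), "mixed.tsv")
  expect_error(readExpression(mixed), class = "tegrn_format_error")
})

test_that("round trip through write/read preserves random matrices", {
  set.seed(11)
  m <- matrix(round(rexp(30), 6), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(ExpressionDataset(m), tmp)
  expect_identical(exprMatrix(readExpression(tmp)), m)
})

test_that("trajectory files are positional and strictly numeric", {
  p <- writeLinesTo(c("0.1", "0.3", "0.2"), "pt.txt")
  expect_identical(readTrajectory(p, 3), c(0.1, 0.3, 0.2))

  short <- writeLinesTo(c("0.1", "0.3"), "pt2.txt")
  expect_error(readTrajectory(short, 3), class = "tegrn_length_error")

  bad <- writeLinesTo(c("0.1", "NA", "0.2"), "pt3.txt")
  err <- expect_error(readTrajectory(bad, 3), class = "tegrn_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("cell-select files parse 0/1 flags, defaulting to all selected", {
  p <- writeLinesTo(c("1", "0", "1"), "sel.txt")
  expect_identical(readCellSelect(p, 3), c(TRUE, FALSE, TRUE))
  expect_identical(readCellSelect(NULL, 4), rep(TRUE, 4))
  expect_identical(readCellSelect("no/such/file", 2), rep(TRUE, 2))

  bad <- writeLinesTo(c("1", "2", "1"), "sel2.txt")
  expect_error(readCellSelect(bad, 3), class = "tegrn_format_error")
})

test_that("TE matrices round-trip at full printed precision", {
  v <- matrix(c(0, 0.5, 0.19, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  te <- new("TEMatrix", values = v, logBase = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeTEMatrix(te, tmp)
  lines <- readLines(tmp)
  expect_length(lines, 3L)  # header plus one row per gene
  expect_identical(teValues(readTEMatrix(tmp)), v)

  # irrational values survive the 17-digit round trip exactly
  set.seed(5)
  w <- matrix(abs(rnorm(9)), 3); diag(w) <- 0
  dimnames(w) <- list(letters[1:3], letters[1:3])
  te2 <- new("TEMatrix", values = w, logBase = 2)
  writeTEMatrix(te2, tmp)
  expect_identical(teValues(readTEMatrix(tmp)), w)

  n1 <- new("TEMatrix",
            values = matrix(0, 1, 1, dimnames = list("g", "g")),
            logBase = 2)
  writeTEMatrix(n1, tmp)
  expect_identical(teValues(readTEMatrix(tmp)),
                   matrix(0, 1, 1, dimnames = list("g", "g")))
})

test_that("edge lists are written in score order with documented tie-break", {
  e <- data.frame(source = c("B", "A", "A"), target = c("C", "B", "C"),
                  te = c(0.5, 0.5, 0.9), z = c(1, 1, 2),
                  padj = c(0.01, 0.01, 0.001))
  el <- new("EdgeList", edges = e, fdrLevel = 0.05)
  tmp <- withr::local_tempfile()
  writeEdgeList(el, tmp, "tsv")
  lines <- readLines(tmp)
  expect_match(lines[1], "^A\tC\t0\\.9")
  # equal scores: (source, target) lexicographic
  expect_match(lines[2], "^A\tB\t0\\.5")
  expect_match(lines[3], "^B\tC\t0\\.5")

  writeEdgeList(el, tmp, "sif")
  expect_identical(readLines(tmp)[1], "A\tte\tC")

  emptyEl <- new("EdgeList", edges = e[0, ], fdrLevel = 0.05)
  writeEdgeList(emptyEl, tmp, "tsv")
  expect_identical(readLines(tmp), character(0))

  expect_error(writeEdgeList(el, tmp, "xml"), class = "tegrn_usage_error")
})

test_that("Matrix Market triplet input matches the delimited reader", {
  skip_if_not_installed("Matrix")
  set.seed(21)
  m <- matrix(rpois(12, 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "m.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "cells.txt"))
  ds <- readExpressionMM(file.path(dir, "m.mtx"),
                         file.path(dir, "genes.txt"),
                         file.path(dir, "cells.txt"))
  expect_equal(exprMatrix(ds), m, ignore_attr = FALSE)
})
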