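test_that("dense and sparse count dialects parse and round-trip identically", {
  Y <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
    dimnames = list(c("gA", "gB"), c("s1", "s2"))
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  writeCounts(Y, csv, "csv")
  expect_identical(readCounts(csv), Y)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  writeCounts(Y, mtx, "mtx")
  back <- readCounts(mtx,
    genes = paste0(tools::file_path_sans_ext(mtx), ".genes.txt"),
    spots = paste0(tools::file_path_sans_ext(mtx), ".spots.txt")
  )
  expect_identical(back, Y)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeCounts(Y, tsv, "tsv")
  expect_identical(readCounts(tsv), Y)
  # transpose flag accommodates spots-by-genes layouts
  expect_identical(t(readCounts(csv, transpose = TRUE)), t(t(Y)))
})

test_that("invalid count input is rejected with informative errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,-1,2", "g2,3,4"), csv)
  expect_error(readCounts(csv), "negative")
  writeLines(c("gene,s1,s2", "g1,1.5,2", "g2,3,4"), csv)
  expect_error(readCounts(csv), "non-integer")
  expect_error(readCounts("no/such/file.csv"), "not found")
  Ydup <- matrix(1L, 2, 2, dimnames = list(c("g", "g"), c("a", "b")))
  expect_error(asCountMatrix(Ydup), "duplicate")
  mtx <- withr::local_tempfile(fileext = ".mtx")
  writeCounts(matrix(1:4, 2, 2), mtx, "mtx")
  lab <- withr::local_tempfile()
  writeLines(c("only-one"), lab)
  expect_error(
    readCounts(mtx,
      genes = lab,
      spots = paste0(tools::file_path_sans_ext(mtx), ".spots.txt")
    ),
    "dimensions"
  )
})

test_that("counts can be supplied as a SummarizedExperiment", {
  Y <- tinyCounts(4, 3)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = Y))
  expect_identical(asCountMatrix(se), Y)
})

test_that("square-lattice adjacency has the textbook degree structure", {
  g <- expand.grid(x = 1:3, y = 1:3)
  E <- buildLatticeAdjacency(as.matrix(g), "square")
  deg <- Matrix::rowSums(E)
  expect_equal(sum(E) / 2, 12) # 2 * 3 * 2 grid edges
  expect_equal(deg[5], 4, ignore_attr = TRUE) # center
  expect_equal(deg[c(1, 3, 7, 9)], rep(2, 4), ignore_attr = TRUE) # corners
  expect_true(Matrix::isSymmetric(E))
  expect_true(all(Matrix::diag(E) == 0))

  # jitter below the tolerance must not change the edge set
  set.seed(1)
  gj <- as.matrix(g) + matrix(runif(18, -0.05, 0.05), 9, 2)
  Ej <- buildLatticeAdjacency(gj, "square")
  expect_equal(as.matrix(Ej != 0), as.matrix(E != 0), ignore_attr = TRUE)

  # 1 x 2 grid: the single possible edge
  E2 <- buildLatticeAdjacency(cbind(c(0, 1), c(0, 0)), "square")
  expect_equal(sum(E2) / 2, 1)
})

test_that("triangular-lattice adjacency yields six interior neighbours", {
  # hexagonal packing: odd rows offset by half a spacing
  rows <- 5
  cols <- 5
  coords <- do.call(rbind, lapply(seq_len(rows), function(r) {
    cbind(seq_len(cols) + ifelse(r %% 2 == 0, 0.5, 0), r * sqrt(3) / 2)
  }))
  E <- buildLatticeAdjacency(coords, "triangular")
  interior <- 13 # row 3, column 3
  expect_equal(Matrix::rowSums(E)[interior], 6, ignore_attr = TRUE)
  expect_true(Matrix::isSymmetric(E))
})

test_that("knn adjacency matches brute-force nearest neighbours", {
  coords <- cbind(c(0, 1, 2, 10), 0)
  E <- buildKnnAdjacency(coords, k = 1)
  expected <- rbind(c(1, 2), c(2, 3), c(3, 4))
  got <- Matrix::which(E != 0, arr.ind = TRUE)
  got <- got[got[, 1] < got[, 2], , drop = FALSE]
  expect_equal(unname(as.matrix(got)), expected, ignore_attr = TRUE)
  expect_true(all(Matrix::diag(E) == 0))
  expect_true(Matrix::isSymmetric(E))
  expect_error(buildKnnAdjacency(coords, k = 4), "smaller")
  expect_error(buildKnnAdjacency(coords, k = 0), "positive")
  # n = 2, k = 1: the single edge
  expect_equal(sum(buildKnnAdjacency(cbind(c(0, 3), c(0, 0)), 1)) / 2, 1)
})

test_that("adjacency edge lists round-trip through disk", {
  g <- expand.grid(x = 1:3, y = 1:2)
  rownames(g) <- paste0("sp", 1:6)
  E <- buildLatticeAdjacency(as.matrix(g), "square")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAdjacency(E, f)
  E2 <- readAdjacency(f, rownames(g))
  expect_equal(as.matrix(E2), as.matrix(E))
})

test_that("highly variable gene filter matches an independent recomputation", {
  Y <- tinyCounts(50, 20, lambda = 8, seed = 5)
  expect_identical(filterTopVariableGenes(Y, 50), Y) # m = p keeps all
  kept <- filterTopVariableGenes(Y, 10)
  # independent recomputation of the ranking statistic
  tot <- colSums(Y)
  norm <- log1p(t(t(Y) / tot) * median(tot))
  v <- apply(norm, 1, var)
  expected <- rownames(Y)[sort(order(-v)[1:10])]
  expect_identical(rownames(kept), expected)
  expect_error(filterTopVariableGenes(Y, 51), "exceeds")
  # constant gene always loses to a varying one
  Yc <- rbind(
    const = rep(5L, 6),
    vary = c(0L, 10L, 0L, 10L, 0L, 10L)
  )
  colnames(Yc) <- paste0("s", 1:6)
  expect_identical(rownames(filterTopVariableGenes(Yc, 1)), "vary")
})

test_that("dropEmpty removes zero-total rows and columns only", {
  Y <- tinyCounts(4, 4)
  Y[2, ] <- 0L
  Y[, 3] <- 0L
  expect_message(out <- dropEmpty(Y), "zero-total")
  expect_equal(dim(out), c(3, 3))
  expect_true(all(rowSums(out) > 0) && all(colSums(out) > 0))
})
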