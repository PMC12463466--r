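#' Validate and coerce a genes-by-spots count matrix
#'
#' Accepts an integer-valued matrix (genes as rows, spots as columns), a
#' data.frame, or a [SummarizedExperiment::SummarizedExperiment-class]
#' (its \code{counts} assay is used). Entries must be non-negative integers
#' and row/column identifiers unique; missing identifiers are filled in as
#' \code{gene1..genep} / \code{spot1..spotn}.
#'
#' @param x matrix, data.frame or SummarizedExperiment.
#' @return an integer matrix with unique dimnames.
#' @export
asCountMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    anames <- SummarizedExperiment::assayNames(x)
    nm <- if ("counts" %in% anames) "counts" else 1L
    x <- as.matrix(SummarizedExperiment::assay(x, nm))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("counts must be a matrix-like object")
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (!is.numeric(x)) stop("counts must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("count matrix must be non-empty")
  if (anyNA(x)) stop("count matrix contains missing values")
  if (any(x < 0)) stop("negative count detected")
  if (any(abs(x - round(x)) > 1e-8)) stop("non-integer count detected")
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("spot", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate spot identifiers")
  x
}

#' Read a count matrix from disk
#'
#' Two dialects are supported: a dense delimited table (genes as rows, spots
#' as columns, with a header row of spot identifiers and a first column of
#' gene identifiers), and MatrixMarket coordinate format paired with
#' one-column gene and spot label files (10x-style features/barcodes,
#' 1-based indices on disk).
#'
#' @param path path to the count file.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"tsv"},
#'   or \code{"mtx"}.
#' @param genes,spots label file paths, required for \code{"mtx"}.
#' @param transpose set \code{TRUE} for dense files laid out spots x genes.
#' @return an integer genes-by-spots matrix with dimnames.
#' @export
readCounts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                       genes = NULL, spots = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx", tsv = "tsv", txt = "tsv", "csv"
    )
  }
  if (format == "mtx") {
    if (is.null(genes) || is.null(spots)) {
      stop("matrix-market input requires gene and spot label files")
    }
    M <- as.matrix(Matrix::readMM(path))
    gid <- readLines(genes)
    sid <- readLines(spots)
    gid <- gid[nzchar(gid)]
    sid <- sid[nzchar(sid)]
    if (length(gid) != nrow(M) || length(sid) != ncol(M)) {
      stop("label files do not match matrix dimensions")
    }
    dimnames(M) <- list(gid, sid)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- read.csv(path, sep = sep, row.names = 1L, check.names = FALSE)
    M <- as.matrix(df)
  }
  if (transpose) M <- t(M)
  asCountMatrix(M)
}

#' Write a count matrix to disk
#'
#' Inverse of [readCounts()]: the dense dialect writes a delimited table
#' with gene identifiers in the first column; the MatrixMarket dialect
#' writes the sparse triplets plus one-column gene and spot label files.
#'
#' @param Y count matrix (see [asCountMatrix()]).
#' @param path output path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"mtx"}.
#' @param genes,spots label file paths for \code{"mtx"} (defaults alongside
#'   \code{path}).
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(Y, path, format = c("csv", "tsv", "mtx"),
                        genes = NULL, spots = NULL) {
  format <- match.arg(format)
  Y <- asCountMatrix(Y)
  if (format == "mtx") {
    if (is.null(genes)) genes <- paste0(tools::file_path_sans_ext(path), ".genes.txt")
    if (is.null(spots)) spots <- paste0(tools::file_path_sans_ext(path), ".spots.txt")
    Matrix::writeMM(Matrix::Matrix(Y, sparse = TRUE), path)
    writeLines(rownames(Y), genes)
    writeLines(colnames(Y), spots)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = rownames(Y), Y, check.names = FALSE)
    write.table(df, path,
      sep = sep, row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Read spot coordinates
#'
#' Expects a delimited file with columns \code{spot_id}, \code{x}, \code{y}.
#'
#' @param path file path.
#' @return an n x 2 numeric matrix with spot identifiers as rownames.
#' @export
readCoordinates <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns spot_id, x, y")
  }
  m <- as.matrix(df[, c("x", "y")])
  rownames(m) <- as.character(df$spot_id)
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite coordinates")
  m
}

.asCoords <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coordinates must be an n x 2 matrix")
  if (anyNA(coords) || any(!is.finite(coords))) stop("non-finite coordinates")
  storage.mode(coords) <- "double"
  coords
}

.edgesToAdjacency <- function(edges, n, ids = NULL) {
  if (length(edges)) {
    edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
    A <- Matrix::sparseMatrix(
      i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
      x = 1, dims = c(n, n)
    )
    A@x[] <- 1
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  }
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  A
}

#' Build a lattice adjacency graph over spots
#'
#' Spots on (approximately) regular grids, as produced by the ST and
#' 10x Visium platforms, are connected to their lattice neighbours: the 4
#' axis-aligned nearest neighbours on a square lattice, or the 6 spots at
#' the minimal centre-to-centre distance on a triangular (hexagonal-packing)
#' lattice. The unit spacing is inferred as the median nearest-neighbour
#' distance; two spots are neighbours when their distance is within
#' \code{tol} (relative) of the expected neighbour distance, which makes the
#' construction robust to small jitter in the coordinates.
#'
#' @param coords n x 2 coordinate matrix.
#' @param lattice \code{"square"} or \code{"triangular"}.
#' @param tol relative tolerance on the unit spacing (default 0.25).
#' @return a symmetric binary sparse adjacency matrix with zero diagonal.
#' @export
buildLatticeAdjacency <- function(coords, lattice = c("square", "triangular"),
                                  tol = 0.25) {
  lattice <- match.arg(lattice)
  coords <- .asCoords(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 spots")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nnd <- apply(D, 1L, min)
  unit <- median(nnd)
  if (!is.finite(unit) || unit <= 0) stop("degenerate coordinates")
  if (lattice == "square") {
    # axis-aligned unit steps only: distance ~ unit AND displacement along
    # a single axis (rules out diagonal neighbours at distance sqrt(2))
    keep <- which(D <= unit * (1 + tol), arr.ind = TRUE)
    keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]
    if (nrow(keep)) {
      dx <- abs(coords[keep[, 1], 1] - coords[keep[, 2], 1])
      dy <- abs(coords[keep[, 1], 2] - coords[keep[, 2], 2])
      ok <- (dx <= tol * unit) | (dy <= tol * unit)
      keep <- keep[ok, , drop = FALSE]
    }
  } else {
    keep <- which(D <= unit * (1 + tol), arr.ind = TRUE)
    keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]
  }
  .edgesToAdjacency(keep, n, rownames(coords))
}

#' Build a k-nearest-neighbour adjacency graph
#'
#' For irregular single-cell-resolution coordinates (e.g. STARmap), the
#' undirected union of each spot's \code{k} Euclidean nearest neighbours.
#' The default \code{k = 6} mirrors the interior degree of a triangular
#' lattice.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k number of nearest neighbours, \code{0 < k < n}.
#' @return a symmetric binary sparse adjacency matrix with zero diagonal.
#' @export
buildKnnAdjacency <- function(coords, k = 6L) {
  coords <- .asCoords(coords)
  n <- nrow(coords)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of spots")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nnidx <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nnidx))
  edges <- t(apply(edges, 1L, sort))
  .edgesToAdjacency(edges, n, rownames(coords))
}

#' Write / read an adjacency graph as a two-column edge list
#'
#' @param E adjacency matrix as returned by the builders.
#' @param path TSV path; columns \code{from}, \code{to} (spot identifiers
#'   when the matrix has dimnames, 1-based indices otherwise).
#' @return \code{writeAdjacency}: \code{path}, invisibly.
#' @export
writeAdjacency <- function(E, path) {
  idx <- Matrix::which(E != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  ids <- rownames(E)
  df <- if (!is.null(ids)) {
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]])
  } else {
    data.frame(from = idx[, 1], to = idx[, 2])
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAdjacency
#' @param spotIds identifier vector fixing node order (and count) when
#'   reading; indices are matched against it.
#' @return \code{readAdjacency}: the adjacency matrix.
#' @export
readAdjacency <- function(path, spotIds) {
  df <- read.csv(path, sep = "\t", check.names = FALSE)
  i <- match(as.character(df$from), spotIds)
  j <- match(as.character(df$to), spotIds)
  if (anyNA(i) || anyNA(j)) stop("edge list refers to unknown spot identifiers")
  .edgesToAdjacency(cbind(i, j), length(spotIds), spotIds)
}

#' Keep the most variable genes
#'
#' Ranks genes by the variance of \eqn{\log(1 + y_{ji} / T_i \cdot
#' \tilde T)} across spots, where \eqn{T_i} is the spot total and
#' \eqn{\tilde T} the median spot total (library-size normalisation to the
#' median depth before the log), and keeps the top \code{m} in their
#' original order.
#'
#' @param Y count matrix.
#' @param m number of genes to keep (\code{m <= p}).
#' @return the row-subset count matrix.
#' @export
filterTopVariableGenes <- function(Y, m) {
  Y <- asCountMatrix(Y)
  if (m > nrow(Y)) stop("m exceeds the number of genes")
  tot <- colSums(Y)
  if (any(tot == 0)) stop("spot with zero total; filter spots first")
  norm <- log1p(sweep(Y, 2L, tot, "/") * median(tot))
  v <- apply(norm, 1L, var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(m)])
  Y[keep, , drop = FALSE]
}

#' Drop zero-total spots and genes
#'
#' The plug-in scaling factors are undefined for all-zero spots or genes;
#' this helper removes them with a message rather than silently.
#'
#' @param Y count matrix.
#' @return the filtered count matrix.
#' @export
dropEmpty <- function(Y) {
  Y <- asCountMatrix(Y)
  es <- colSums(Y) == 0
  eg <- rowSums(Y) == 0
  if (any(es)) message("dropping ", sum(es), " zero-total spot(s)")
  if (any(eg)) message("dropping ", sum(eg), " zero-total gene(s)")
  Y[!eg, !es, drop = FALSE]
}

# adjacency matrix -> 0-based neighbour index list for the C++ sampler
.adjList <- function(E) {
  E <- Matrix::Matrix(E, sparse = TRUE)
  E <- methods::as(methods::as(E, "generalMatrix"), "CsparseMatrix")
  n <- ncol(E)
  lapply(seq_len(n), function(i) {
    rows <- E@i[seq.int(E@p[i] + 1L, length.out = E@p[i + 1L] - E@p[i])]
    as.integer(rows)
  })
}

.checkAdjacency <- function(E, n) {
  if (is.null(E)) stop("an adjacency graph (or coordinates) is required")
  if (!identical(dim(E), c(n, n))) {
    if (!(nrow(E) == n && ncol(E) == n)) stop("adjacency dimensions must be n x n")
  }
  if (any(Matrix::diag(E) != 0)) stop("adjacency must have zero diagonal")
  if (!Matrix::isSymmetric(E)) stop("adjacency must be symmetric")
  invisible(E)
}
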