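#' Construct a ContactMap from triplets or a matrix
#'
#' @param chrom Chromosome name.
#' @param binSize Bin width in bp.
#' @param mat A square (dense or sparse) matrix, or NULL when
#'   triplets are given.
#' @param i,j,x Optional COO triplets (1-based bin indices); entries
#'   are symmetrized (value placed at both (i,j) and (j,i)).
#' @param nBins Number of bins (required with triplets).
#' @param balanced,distNormalized State flags.
#' @param bias ICE bias vector (optional).
#' @return A [ContactMap-class].
#' @export
contactMap <- function(chrom, binSize = 10000, mat = NULL,
                       i = NULL, j = NULL, x = NULL, nBins = NULL,
                       balanced = FALSE, distNormalized = FALSE,
                       bias = numeric(0)) {
  if (is.null(mat)) {
    stopifnot(!is.null(i), !is.null(j), !is.null(x), !is.null(nBins))
    off <- i != j
    mat <- Matrix::sparseMatrix(i = c(i, j[off]), j = c(j, i[off]),
                                x = c(x, x[off]), dims = c(nBins, nBins))
  } else {
    mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
  }
  new("ContactMap", chrom = chrom, binSize = binSize, mat = mat,
      balanced = balanced, distNormalized = distNormalized, bias = bias)
}

#' Contact matrix of a ContactMap
#' @param map A `ContactMap`.
#' @export
contactMatrix <- function(map) map@mat

#' Read / write sparse COO contact triplets
#'
#' Text format: three tab-separated columns `bin_i`, `bin_j`, `value`
#' with 0-based bin indices, upper triangle (i <= j) sufficient.
#'
#' @param path Triplet file.
#' @param chrom Chromosome name.
#' @param binSize Bin width (bp).
#' @param nBins Number of bins; inferred from the largest index when
#'   omitted.
#' @export
readContactMap <- function(path, chrom, binSize = 10000, nBins = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("i", "j", "x"),
                          colClasses = c("integer", "integer", "numeric"))
  if (is.null(nBins)) nBins <- max(df$i, df$j) + 1L
  contactMap(chrom, binSize, i = df$i + 1L, j = df$j + 1L, x = df$x,
             nBins = nBins)
}

#' @rdname readContactMap
#' @param map A `ContactMap` to write.
#' @export
writeContactMap <- function(map, path) {
  tm <- methods::as(Matrix::triu(map@mat), "TsparseMatrix")
  df <- data.frame(i = tm@i, j = tm@j, x = tm@x)
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' ICE matrix balancing
#'
#' Iterative correction: repeatedly divides rows and columns by their
#' (mean-normalized) sums until the coefficient of variation of the
#' nonzero-row sums drops below `tol`. Zero rows are left untouched.
#'
#' @param map A raw-count [ContactMap-class].
#' @param tol Convergence tolerance on CV of nonzero-row sums.
#' @param maxIter Iteration cap.
#' @return List with `map` (balanced `ContactMap`) and `bias` (the
#'   accumulated per-bin multipliers; raw = bias_i * bias_j * balanced).
#' @export
iceNormalize <- function(map, tol = 1e-5, maxIter = 200) {
  m <- map@mat
  if (length(m@x) == 0L || all(m@x == 0)) stop("all-zero contact matrix")
  n <- nrow(m)
  bias <- rep(1, n)
  for (it in seq_len(maxIter)) {
    s <- Matrix::rowSums(m)
    nz <- s > 0
    mu <- mean(s[nz])
    cv <- stats::sd(s[nz]) / mu
    if (!is.finite(cv) || cv < tol) break
    d <- s / mu
    d[!nz] <- 1
    D <- Matrix::Diagonal(n, 1 / d)
    m <- D %*% m %*% D
    bias <- bias * d
  }
  out <- new("ContactMap", chrom = map@chrom, binSize = map@binSize,
             mat = methods::as(m, "CsparseMatrix"), balanced = TRUE,
             distNormalized = FALSE, bias = bias)
  list(map = out, bias = bias)
}

#' Diagonal-median distance normalization
#'
#' For every diagonal offset d, subtracts the median of all entries at
#' that offset (structural zeros included in the median, so sparse
#' storage does not bias it upward) and clamps negatives at zero.
#' Symmetry is preserved.
#'
#' @param map A balanced [ContactMap-class].
#' @return Distance-normalized `ContactMap`.
#' @export
distanceNormalize <- function(map) {
  n <- nrow(map@mat)
  tm <- methods::as(Matrix::triu(map@mat), "TsparseMatrix")
  i <- tm@i; j <- tm@j; x <- tm@x
  off <- j - i
  newX <- x
  for (d in unique(off)) {
    sel <- off == d
    med <- medianWithZeros(x[sel], n - d)
    newX[sel] <- pmax(0, x[sel] - med)
  }
  keep <- newX > 0
  contactMap(map@chrom, map@binSize, i = i[keep] + 1L, j = j[keep] + 1L,
             x = newX[keep], nBins = n, balanced = map@balanced,
             distNormalized = TRUE, bias = map@bias)
}

#' Top-k strongest-contact neighbor graph
#'
#' For each bin, selects its k strongest nonzero contacts (ties broken
#' toward the smaller partner bin index); the union over bins is taken
#' as an undirected edge set, so a bin chosen by many others can have
#' degree above k.
#'
#' @param map A distance-normalized [ContactMap-class].
#' @param k Neighbors per node (default 10).
#' @return Two-column integer matrix of undirected edges (1-based bin
#'   indices, smaller first).
#' @export
topkGraph <- function(map, k = 10) {
  if (k < 1) stop("k must be >= 1")
  tm <- methods::as(map@mat, "TsparseMatrix")
  i <- tm@i + 1L; j <- tm@j + 1L; x <- tm@x
  sel <- x > 0 & i != j
  i <- i[sel]; j <- j[sel]; x <- x[sel]
  if (!length(i)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("from", "to"))))
  # per source row i, order partners by decreasing value then partner index
  o <- order(i, -x, j)
  i <- i[o]; j <- j[o]
  rk <- stats::ave(seq_along(i), i, FUN = seq_along)
  keep <- rk <= k
  e <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
  e <- unique(e)
  colnames(e) <- c("from", "to")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Down-sample an interaction pair list
#'
#' Uniform without-replacement sample of exactly `n` pairs,
#' deterministic per seed.
#'
#' @param pairs data.frame with columns `chrom`, `bin_i`, `bin_j`
#'   (one row per valid interaction).
#' @param n Target number of pairs (<= nrow(pairs)).
#' @param seed RNG seed.
#' @export
downsamplePairs <- function(pairs, n, seed = 1) {
  if (n > nrow(pairs)) stop("cannot sample ", n, " from ", nrow(pairs),
                            " pairs")
  withSeed(seed, pairs[sample.int(nrow(pairs), n), , drop = FALSE])
}

#' Bin an intra-chromosomal pair list into a ContactMap
#' @param pairs data.frame `chrom`, `bin_i`, `bin_j` (1-based bins).
#' @param chrom Chromosome to keep.
#' @param nBins Number of bins.
#' @param binSize Bin width (bp).
#' @export
pairsToMap <- function(pairs, chrom, nBins, binSize = 10000) {
  p <- pairs[pairs$chrom == chrom, , drop = FALSE]
  lo <- pmin(p$bin_i, p$bin_j); hi <- pmax(p$bin_i, p$bin_j)
  key <- paste(lo, hi)
  cnt <- table(key)
  ij <- do.call(rbind, strsplit(names(cnt), " "))
  contactMap(chrom, binSize, i = as.integer(ij[, 1]),
             j = as.integer(ij[, 2]), x = as.numeric(cnt), nBins = nBins)
}

#' Down-sample, merge and balance multiple Hi-C datasets
#'
#' Each dataset's pair list is down-sampled to `nEach` interactions,
#' the samples are merged, binned at `binSize`, and the summed map is
#' ICE-balanced. A leave-one-out aggregate excludes a named dataset.
#'
#' @param pairLists Named list of pair data.frames (>= 2).
#' @param nEach Pairs to keep per dataset.
#' @param chrom Chromosome to aggregate.
#' @param nBins Number of bins.
#' @param binSize Bin width (bp).
#' @param seed RNG seed (per-dataset streams derived from it).
#' @param exclude Optional dataset name to leave out.
#' @return Balanced aggregate [ContactMap-class].
#' @export
aggregateMaps <- function(pairLists, nEach, chrom, nBins, binSize = 10000,
                          seed = 1, exclude = NULL) {
  if (!is.null(exclude)) pairLists <- pairLists[setdiff(names(pairLists), exclude)]
  if (length(pairLists) < 2L) stop("need at least 2 datasets to aggregate")
  merged <- do.call(rbind, lapply(seq_along(pairLists), function(idx) {
    downsamplePairs(pairLists[[idx]], nEach, seed = seed + idx)
  }))
  raw <- pairsToMap(merged, chrom, nBins, binSize)
  iceNormalize(raw)$map
}
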