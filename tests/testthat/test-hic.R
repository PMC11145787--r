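test_that("ICE leaves an already-balanced matrix proportional to itself", {
  m <- contactMap("chr1", 10000, mat = matrix(c(0, 2, 2, 0), 2))
  out <- iceNormalize(m)
  r <- Matrix::rowSums(contactMatrix(out$map))
  expect_equal(r[1], r[2])
  ratio <- as.matrix(contactMatrix(out$map)) / matrix(c(NA, 2, 2, NA), 2)
  expect_equal(ratio[1, 2], ratio[2, 1])
})

test_that("ICE equalizes row sums on the 3x3 hand case and matches the oracle", {
  raw <- matrix(c(0, 4, 1,
                  4, 0, 1,
                  1, 1, 0), 3, byrow = TRUE)
  m <- contactMap("chr1", 10000, mat = raw)
  out <- iceNormalize(m, tol = 1e-8)
  s <- Matrix::rowSums(contactMatrix(out$map))
  expect_lt(sd(s) / mean(s), 1e-8)
  oracle <- iceOracle(raw)
  got <- as.matrix(contactMatrix(out$map))
  expect_equal(got / mean(got[got > 0]), oracle / mean(oracle[oracle > 0]),
               tolerance = 1e-6)
})

test_that("ICE matches the brute-force fixed-point oracle on random sparse matrices", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(5:20, 1)
    m <- matrix(rpois(n * n, 3) * rbinom(n * n, 1, 0.6), n)
    m <- m + t(m); diag(m) <- 0
    if (any(rowSums(m) == 0)) m[1, 2] <- m[2, 1] <- m[1, 2] + 1
    out <- iceNormalize(contactMap("chr1", 1e4, mat = m), tol = 1e-10)
    oracle <- iceOracle(m)
    got <- as.matrix(contactMatrix(out$map))
    expect_equal(got / mean(got[got > 0]),
                 oracle / mean(oracle[oracle > 0]), tolerance = 1e-6)
  }
})

test_that("ICE rejects an all-zero matrix and skips zero rows", {
  expect_error(iceNormalize(contactMap("chr1", 1e4, mat = matrix(0, 3, 3))),
               "all-zero")
  m <- matrix(c(0, 3, 0, 3, 0, 0, 0, 0, 0), 3)
  out <- iceNormalize(contactMap("chr1", 1e4, mat = m))
  expect_equal(as.matrix(contactMatrix(out$map))[3, ], rep(0, 3))
})

test_that("distance normalization subtracts per-offset medians and clamps at zero", {
  # constant matrix: every offset has constant entries -> all zeros
  cm <- contactMap("chr1", 1e4, mat = matrix(5, 4, 4), balanced = TRUE)
  dn <- distanceNormalize(cm)
  expect_equal(length(contactMatrix(dn)@x), 0L)
  # offset-1 entries {4, 2}: median 3 -> {1, 0}
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 4
  m[2, 3] <- m[3, 2] <- 2
  dn2 <- distanceNormalize(contactMap("chr1", 1e4, mat = m, balanced = TRUE))
  got <- as.matrix(contactMatrix(dn2))
  expect_equal(got[1, 2], 1)
  expect_equal(got[2, 3], 0)
  expect_true(all(got >= 0))
  expect_equal(got, t(got))
})

test_that("structural zeros enter the diagonal medians", {
  # offset 1 has entries {6, 0, 0} (two structural zeros): median 0
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 6
  dn <- distanceNormalize(contactMap("chr1", 1e4, mat = m, balanced = TRUE))
  expect_equal(as.matrix(contactMatrix(dn))[1, 2], 6)
})

test_that("distance normalization commutes with diagonal translation", {
  set.seed(31)
  n <- 12
  base <- matrix(0, n, n)
  for (d in 1:4) for (i in 1:(n - d))
    base[i, i + d] <- base[i + d, i] <- rpois(1, 6 - d)
  dn <- as.matrix(contactMatrix(distanceNormalize(
    contactMap("chr1", 1e4, mat = base, balanced = TRUE))))
  # translate a block along the diagonal: entries at equal offset keep
  # their normalized value ordering under the same medians
  for (d in 1:3) {
    vals <- base[row(base) + d == col(base)]
    nvals <- dn[row(dn) + d == col(dn)]
    med <- median(vals)  # all entries at this offset are stored
    expect_equal(nvals, pmax(0, vals - med))
  }
})

test_that("top-k graph keeps the k strongest contacts per node", {
  m <- matrix(0, 6, 6)
  m[1, 2:6] <- m[2:6, 1] <- c(5, 4, 3, 2, 1)
  g <- topkGraph(contactMap("chr1", 1e4, mat = m, distNormalized = TRUE),
                 k = 3)
  # node 1 keeps 2,3,4; nodes 2..6 each keep their only contact (node 1)
  expect_true(all(c(2, 3, 4) %in% g[g[, 1] == 1, 2]))
  expect_equal(sum(g[, 1] == 1 | g[, 2] == 1), 5L)  # hub degree exceeds k
  expect_error(topkGraph(contactMap("chr1", 1e4, mat = m), k = 0), "k must")
})

test_that("nodes with fewer contacts than k keep what they have", {
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 3
  m[1, 3] <- m[3, 1] <- 1
  g <- topkGraph(contactMap("chr1", 1e4, mat = m), k = 10)
  expect_equal(nrow(g), 2L)
})

test_that("top-k ties break toward the smaller bin index", {
  m <- matrix(0, 6, 6)
  m[1, 2:5] <- c(7, 5, 5, 5)
  m[2:5, 6] <- 100          # nodes 2..5 prefer 6 and each other,
  m[2, 3] <- 50; m[4, 5] <- 50  # so they never pick node 1 at k = 2
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  g <- topkGraph(contactMap("chr1", 1e4, mat = m), k = 2)
  # node 1's second pick among tied {3,4,5} must be node 3
  inc1 <- g[g[, 1] == 1 | g[, 2] == 1, ]
  expect_setequal(setdiff(as.vector(inc1), 1), c(2, 3))
})

test_that("pair down-sampling is exact, seeded and distribution-preserving", {
  set.seed(17)
  pairs <- data.frame(chrom = "chr1",
                      bin_i = sample(1:50, 5000, TRUE),
                      bin_j = sample(1:50, 5000, TRUE))
  expect_equal(nrow(downsamplePairs(pairs, 5000, seed = 1)), 5000L)
  expect_setequal(rownames(downsamplePairs(pairs, 5000, seed = 1)),
                  rownames(pairs))
  d1 <- downsamplePairs(pairs, 800, seed = 1)
  expect_equal(nrow(d1), 800L)
  expect_identical(d1, downsamplePairs(pairs, 800, seed = 1))
  d2 <- downsamplePairs(pairs, 800, seed = 2)
  expect_false(identical(rownames(d1), rownames(d2)))
  ks <- suppressWarnings(stats::ks.test(abs(d1$bin_i - d1$bin_j),
                                        abs(d2$bin_i - d2$bin_j)))
  expect_gt(ks$p.value, 1e-4)
  expect_error(downsamplePairs(pairs, 1e6, seed = 1), "cannot sample")
})

test_that("aggregation down-samples, merges, conserves counts and balances", {
  set.seed(23)
  mk <- function(seed) {
    set.seed(seed)
    data.frame(chrom = "chr1", bin_i = sample(1:20, 3000, TRUE),
               bin_j = sample(1:20, 3000, TRUE))
  }
  pA <- mk(1); pB <- mk(2)
  # conservation before balancing
  merged <- rbind(downsamplePairs(pA, 1000, 2), downsamplePairs(pB, 1000, 3))
  raw <- pairsToMap(merged, "chr1", 20)
  tm <- Matrix::triu(contactMatrix(raw))
  expect_equal(sum(tm@x), 2000)
  agg <- aggregateMaps(list(A = pA, B = pB), 1000, "chr1", 20, seed = 5)
  expect_true(agg@balanced)
  # two identical datasets: aggregate proportional to either input
  aggSame <- aggregateMaps(list(A = pA, B = pA), 2999, "chr1", 20, seed = 5)
  one <- iceNormalize(pairsToMap(pA, "chr1", 20))$map
  m1 <- as.matrix(contactMatrix(aggSame)); m2 <- as.matrix(contactMatrix(one))
  expect_gt(cor(m1[upper.tri(m1)], m2[upper.tri(m2)]), 0.95)
  # leave-one-out differs from the full aggregate on discordant inputs
  aggLoo <- aggregateMaps(list(A = pA, B = pB, C = mk(9)), 1000, "chr1", 20,
                          seed = 5, exclude = "C")
  aggAll <- aggregateMaps(list(A = pA, B = pB, C = mk(9)), 1000, "chr1", 20,
                          seed = 5)
  expect_false(isTRUE(all.equal(contactMatrix(aggLoo), contactMatrix(aggAll))))
  expect_error(aggregateMaps(list(A = pA), 10, "chr1", 20), "at least 2")
})

test_that("COO text round trip preserves the sparse matrix", {
  set.seed(41)
  m <- matrix(rpois(64, 2), 8); m <- m + t(m)
  cm <- contactMap("chr2", 1e4, mat = m)
  path <- tempfile(fileext = ".coo")
  writeContactMap(cm, path)
  back <- readContactMap(path, "chr2", nBins = 8)
  expect_equal(as.matrix(contactMatrix(back)), as.matrix(contactMatrix(cm)))
})

test_that("contact maps validate symmetry and nonnegativity", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(contactMap("chr1", 1e4, mat = bad), "asymmetry")
  expect_error(contactMap("chr1", 1e4, mat = matrix(-1, 2, 2)), ">= 0")
})
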