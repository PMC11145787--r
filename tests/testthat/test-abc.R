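mkPeaks <- function(summits, scores, chrom = "chr1") {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(summits - 100, summits + 99),
    score = scores, signalValue = scores / 10, summit = summits)
}

test_that("candidate regions extend summits, merge overlaps and respect the blacklist", {
  peaks <- mkPeaks(c(1000, 5000, 9000), c(10, 20, 30))
  cand <- candidateRegions(peaks)
  expect_equal(length(cand), 3L)
  expect_true(all(GenomicRanges::width(cand) == 500))
  # summits 300 bp apart merge into one 800 bp region
  near <- mkPeaks(c(2000, 2300), c(5, 5))
  merged <- candidateRegions(near)
  expect_equal(length(merged), 1L)
  expect_equal(GenomicRanges::width(merged), 800L)
  # strongest-peak selection
  one <- candidateRegions(peaks, nStrongest = 1)
  expect_equal(length(one), 1L)
  expect_true(GenomicRanges::start(one) == 9000 - 250)
  # blacklist removal
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  expect_equal(length(candidateRegions(peaks, blacklist = bl)), 2L)
  noSummit <- peaks; noSummit$summit <- NULL
  expect_error(candidateRegions(noSummit), "summit")
})

test_that("element activity is the geometric mean of the two signals", {
  cand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  # constant tracks engineered to give RPKM 4 and 9
  acc <- constTrack(4, 1e5, depth = 1e9)    # RPKM = 4e3/(1 * 1e3) = 4
  act <- constTrack(9, 1e5, depth = 1e9)
  a <- elementActivity(cand, acc, act, eps = 1e-12)
  expect_equal(a, 6, tolerance = 1e-6)
  expect_equal(elementActivity(cand, act, acc, eps = 1e-12), a,
               tolerance = 1e-9)  # symmetric
  zero <- constTrack(0, 1e5, depth = 1e9)
  expect_equal(elementActivity(cand, zero, zero, eps = 0.1), 0.1,
               tolerance = 1e-9)
})

test_that("the power-law fit recovers a planted exponent", {
  n <- 400
  i <- rep(seq_len(n), each = 1)
  # exact contact d^-1 map
  tm <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- tm[, 2] - tm[, 1]
  m <- contactMap("chr1", 1e4, i = tm[, 1], j = tm[, 2], x = 1 / d,
                  nBins = n, balanced = TRUE)
  fit <- fitPowerlaw(m)
  expect_equal(fit$gamma, 1, tolerance = 0.01)
  # doubling every entry changes kappa, not gamma
  m2 <- contactMap("chr1", 1e4, i = tm[, 1], j = tm[, 2], x = 2 / d,
                   nBins = n, balanced = TRUE)
  fit2 <- fitPowerlaw(m2)
  expect_equal(fit2$gamma, fit$gamma, tolerance = 1e-9)
  expect_equal(fit2$kappa, 2 * fit$kappa, tolerance = 1e-6)
  # constant contacts: gamma 0
  mc <- contactMap("chr1", 1e4, i = tm[, 1], j = tm[, 2],
                   x = rep(3, nrow(tm)), nBins = n, balanced = TRUE)
  expect_equal(fitPowerlaw(mc)$gamma, 0, tolerance = 1e-9)
  tiny <- contactMap("chr1", 1e4, mat = matrix(c(0, 1, 1, 0), 2),
                     balanced = TRUE)
  expect_error(fitPowerlaw(tiny), "usable distances")
})

test_that("contact lookup imputes missing entries from the power law", {
  m <- contactMap("chr1", 1e4, i = 1L, j = 2L, x = 5, nBins = 300,
                  balanced = TRUE)
  fit <- list(gamma = 1, kappa = 1)
  # missing entry at 100 kb: C = 1/1e5 (imputed) + 1/1e6 (pseudocount)
  C <- geneElementContact(m, fit, elementMid = 105000, tss = 5000)
  expect_equal(C, 1e-5 + 1e-6, tolerance = 1e-12)
  # observed entry: observed + pseudocount
  Cobs <- geneElementContact(m, fit, elementMid = 15000, tss = 5000)
  expect_equal(Cobs, 5 + 1e-6, tolerance = 1e-9)
  # pure power-law component decreases monotonically with distance
  dists <- seq(25000, 2.5e6, by = 1e5)
  Cs <- geneElementContact(m, fit, elementMid = 5000 + dists, tss = 5000)
  expect_true(all(diff(Cs) < 0))
  # same-bin lookup uses the strongest nearby offset
  Csame <- geneElementContact(m, fit, elementMid = 6000, tss = 5000)
  expect_equal(Csame, 5 + 1e-6, tolerance = 1e-9)
})

test_that("ABC scores normalize to one per gene and threshold correctly", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, 105000),
                                  strand = "+", gene_id = "g1")
  cand <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(140000, 160000), width = 500))
  # equal contact by construction: symmetric distances from the TSS bin
  m <- contactMap("chr1", 1e4,
                  i = c(10L, 10L), j = c(15L, 17L), x = c(4, 4),
                  nBins = 50, balanced = TRUE)
  fit <- list(gamma = 1, kappa = 1)
  cand$activity <- c(2, 1)
  pred <- abcScores(cand, genes, list(chr1 = m), fit, allPutative = TRUE)
  expect_equal(sum(pred$abcScore), 1)
  expect_equal(pred$abcScore, c(2, 1) * pred$contact /
                 sum(c(2, 1) * pred$contact))
  # equal contacts -> scores 2/3 and 1/3
  expect_equal(pred$abcScore, c(2/3, 1/3), tolerance = 1e-6)
  # single element scores 1 regardless of magnitudes
  single <- abcScores(cand[1], genes, list(chr1 = m), fit,
                      allPutative = TRUE)
  expect_equal(single$abcScore, 1)
  # thresholding
  thr <- abcScores(cand, genes, list(chr1 = m), fit, threshold = 0.5)
  expect_equal(nrow(thr), 1L)
  expect_error(abcScores(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1, 10)), genes, list(chr1 = m), fit), "activity")
})

test_that("swapping the activity track changes scores only through activity", {
  s <- synthFixture()
  cand <- candidateRegions(s$tracks$peaks)[1:80]
  fits <- lapply(s$balanced, fitPowerlaw)
  cand$activity <- elementActivity(cand, s$tracks$atac, s$tracks$ip)
  p1 <- abcScores(cand, s$gen$genes[1:40], s$balanced, fits$chr1,
                  allPutative = TRUE)
  cand$activity <- elementActivity(cand, s$tracks$atac, s$tracks$input)
  p2 <- abcScores(cand, s$gen$genes[1:40], s$balanced, fits$chr1,
                  allPutative = TRUE)
  expect_equal(p1$contact, p2$contact)        # contact fixed
  expect_false(isTRUE(all.equal(p1$abcScore, p2$abcScore)))
})

test_that("region-set comparison distinguishes overlap from containment", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), c(10, 120)))
  expect_equal(unname(compareRegionSets(a, a)), c(0L, 2L, 0L))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(200, 300), c(210, 320)))
  expect_equal(unname(compareRegionSets(a, b)), c(2L, 0L, 2L))
  # region straddling a bin boundary: overlap yes, containment no
  bins <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 10001), c(10000, 20000)))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9996, 10020))
  expect_equal(unname(compareRegionSets(region, bins, "any_overlap")),
               c(0L, 1L, 0L))
  expect_equal(unname(compareRegionSets(region, bins, "contained_in_bins")),
               c(1L, 0L, 2L))
})

test_that("distance distributions measure target and closest TSS", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000, 20000), width = 5000), strand = "+",
    gene_id = c("gT", "gN"))
  pred <- data.frame(chrom = "chr1", start = 9751, end = 10250,
                     gene_id = "gT")
  dd <- distanceDistributions(pred, genes)
  expect_equal(dd$targetDist, 0)
  expect_equal(dd$closestDist, 0)
  # element nearer to a non-target gene
  pred2 <- data.frame(chrom = "chr1", start = 19000, end = 19499,
                      gene_id = "gT")
  dd2 <- distanceDistributions(pred2, genes)
  expect_gt(dd2$targetDist, dd2$closestDist)
  expect_true(all(dd2$closestDist <= dd2$targetDist))
})

test_that("planted enhancers score highest among non-promoter candidates at strong boost", {
  cfg <- synthConfig(seed = 19, loopBoost = 30, nGenes = 200)
  gen <- synthGenome(cfg)
  tracks <- synthTracks(cfg, gen)
  hic <- synthHic(cfg, gen)
  balanced <- lapply(hic$maps, function(m) iceNormalize(m)$map)
  fits <- lapply(balanced, fitPowerlaw)
  cand <- candidateRegions(tracks$peaks)
  cand$activity <- elementActivity(cand, tracks$atac, tracks$ip)
  pred <- abcScores(cand, gen$genes, balanced, fits, allPutative = TRUE)
  tss <- tssOf(gen$genes); names(tss) <- gen$genes$gene_id
  chrom <- as.character(GenomicRanges::seqnames(gen$genes))
  enh <- gen$enhancers
  hit <- 0; tot <- 0
  for (ei in seq_along(enh)) {
    gid <- enh$gene_id[ei]
    ch <- chrom[match(gid, gen$genes$gene_id)]
    mid <- (GenomicRanges::start(enh)[ei] + GenomicRanges::end(enh)[ei]) %/% 2
    p <- pred[pred$gene_id == gid, ]
    if (!nrow(p)) next
    pm <- (p$start + p$end) %/% 2
    tssCh <- tss[chrom == ch]
    nonProm <- vapply(pm, function(x) all(abs(x - tssCh) > 2500), logical(1))
    if (!any(nonProm)) next
    tot <- tot + 1
    best <- pm[nonProm][which.max(p$abcScore[nonProm])]
    if (abs(best - mid) <= 500) hit <- hit + 1
  }
  expect_gte(hit / tot, 0.9)
})
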