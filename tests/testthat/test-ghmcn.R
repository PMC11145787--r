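# Small hand-made inputs for graph construction.
miniGraphInputs <- function() {
  nBins <- 30
  m <- matrix(1, nBins, nBins); diag(m) <- 0
  map <- contactMap("chr1", 10000, mat = m, balanced = TRUE,
                    distNormalized = TRUE)
  ip <- constTrack(2, nBins * 10000, depth = 1e6)
  input <- constTrack(1, nBins * 10000, depth = 1e6)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(15000, 18000, 95000, 155000),
                     width = c(2000, 3000, 4000, 3000)),
    strand = "+", gene_id = c("gA", "gB", "gC", "gD"))
  tpm <- c(gA = 2, gB = 4, gC = 10, gD = 0.1)
  list(maps = list(chr1 = map), ip = ip, input = input, genes = genes,
       tpm = tpm)
}

test_that("nodes with several TSSs get the mean TPM, dichotomized at the gene median", {
  x <- miniGraphInputs()
  g <- buildGenomeGraph(x$maps, x$ip, x$input, x$genes, x$tpm, k = 3,
                        seed = 1)
  nodes <- graphNodes(g)
  # gA (TSS 15000) and gB (TSS 18000) share bin 2: mean TPM = 3
  expect_equal(nodes$meanTpm[2], 3)
  # gene-level median TPM = median(2,4,10,0.1) = 3 -> mean 3 is not > 3
  expect_equal(nodes$label[2], "Low")
  expect_equal(nodes$label[10], "High")  # gC, TPM 10
  expect_equal(nodes$label[16], "Low")   # gD, TPM 0.1
  # nodes without a TSS are unlabeled and fold-free
  expect_true(all(is.na(nodes$label[!nodes$mask])))
  expect_true(all(is.na(nodes$fold[!nodes$mask])))
  expect_equal(sum(nodes$mask), 3L)
})

test_that("masked nodes split 70/15/15 into folds", {
  mask <- c(rep(TRUE, 100), rep(FALSE, 50))
  fold <- hmcReg:::assignFolds(mask, seed = 4)
  expect_equal(sum(fold == "train", na.rm = TRUE), 70L)
  expect_equal(sum(fold == "val", na.rm = TRUE), 15L)
  expect_equal(sum(fold == "test", na.rm = TRUE), 15L)
  expect_true(all(is.na(fold[!mask])))
})

test_that("node features are log10(1 + RPKM) window signal", {
  x <- miniGraphInputs()
  g <- buildGenomeGraph(x$maps, x$ip, x$input, x$genes, x$tpm, seed = 1)
  nodes <- graphNodes(g)
  # constant coverage 2 over a 10 kb window at depth 1e6:
  # signal 20000 -> RPKM = 20000 / (10 * 1) = 2000
  expect_equal(nodes$ip[1], log10(1 + 2000))
  expect_equal(nodes$input[1], log10(1 + 1000))
})

test_that("the 1D nearest-bin graph connects 5 bins per side with end truncation", {
  e <- nearest1dGraph(c(chr1 = 40, chr2 = 20), k = 10)
  deg <- tabulate(c(e[, 1], e[, 2]), 60)
  expect_equal(deg[20], 10L)    # interior bin
  expect_equal(deg[1], 5L)      # first bin of chr1
  expect_equal(deg[41], 5L)     # first bin of chr2
  expect_equal(deg[40], 5L)     # last bin of chr1
  # no cross-chromosome edges
  expect_false(any(e[, 1] <= 40 & e[, 2] > 40))
})

test_that("GraphSAGE learns a self-feature threshold rule", {
  lg <- syntheticLoopGraph(nNodes = 1200, nGenes = 400, seed = 3)
  nodes <- graphNodes(lg$graph)
  # relabel by the node's own IP feature
  nodes$label[nodes$mask] <- ifelse(nodes$ip[nodes$mask] > 0, "High", "Low")
  g <- new("GenomeGraph", nodes = nodes, edges = graphEdges(lg$graph),
           binSize = 10000)
  model <- trainSage(g, sageConfig(epochs = 150, seed = 3))
  pr <- predictSage(model, g)
  te <- pr[pr$fold == "test", ]
  expect_gte(evaluate(te$score, te$label)$auc, 0.95)
})

test_that("loop-linked labels favor the true contact graph over the linear graph", {
  lg <- syntheticLoopGraph(nNodes = 2000, nGenes = 300, seed = 5)
  modelTrue <- trainSage(lg$graph, sageConfig(epochs = 150, seed = 5))
  prT <- predictSage(modelTrue, lg$graph)
  aucTrue <- evaluate(prT$score[prT$fold == "test"],
                      prT$label[prT$fold == "test"])$auc
  g1d <- setGraphEdges(lg$graph, lg$linearEdges)
  model1d <- trainSage(g1d, sageConfig(epochs = 150, seed = 5))
  pr1 <- predictSage(model1d, g1d)
  auc1d <- evaluate(pr1$score[pr1$fold == "test"],
                    pr1$label[pr1$fold == "test"])$auc
  expect_gte(aucTrue, auc1d)
  expect_gt(aucTrue, 0.6)   # the planted partner edge is actually used
})

test_that("label shuffling drives GraphSAGE AUC to chance", {
  lg <- syntheticLoopGraph(nNodes = 3000, nGenes = 1200, seed = 9)
  nodes <- graphNodes(lg$graph)
  set.seed(9)
  nodes$label[nodes$mask] <- sample(nodes$label[nodes$mask])
  g <- new("GenomeGraph", nodes = nodes, edges = graphEdges(lg$graph),
           binSize = 10000)
  model <- trainSage(g, sageConfig(epochs = 100, seed = 9))
  pr <- predictSage(model, g)
  heldOut <- pr[pr$fold %in% c("val", "test"), ]
  auc <- evaluate(heldOut$score, heldOut$label)$auc
  expect_true(abs(auc - 0.5) < 0.05)
})

test_that("prediction is deterministic, bounded and arity-checked", {
  sf <- sageFixture()
  p1 <- predictSage(sf$model, sf$graph)
  p2 <- predictSage(sf$model, sf$graph)
  expect_identical(p1, p2)
  expect_true(all(p1$score > 0 & p1$score < 1))
  bad <- sf$graph
  bad@nodes$input <- NULL
  expect_error({
    nodes <- graphNodes(sf$graph)
    X <- cbind(nodes$ip, nodes$input, nodes$ip)
    hmcReg:::sageForward(sf$model@weights, X,
                         hmcReg:::meanAggregator(graphEdges(sf$graph),
                                                 nrow(X)))
  })
})

test_that("masked-node scores depend only on the conv-depth receptive field", {
  lg <- syntheticLoopGraph(nNodes = 300, nGenes = 60, seed = 13)
  model <- trainSage(lg$graph, sageConfig(epochs = 30, seed = 13))
  nodes <- graphNodes(lg$graph)
  edges <- graphEdges(lg$graph)
  target <- which(nodes$mask)[1]
  # nodes within 2 hops of the target
  hop1 <- unique(c(edges[edges[, 1] == target, 2],
                   edges[edges[, 2] == target, 1]))
  hop2 <- unique(c(hop1, unlist(lapply(hop1, function(v)
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))))
  far <- setdiff(which(!nodes$mask), c(target, hop2))[1]
  nodes2 <- nodes
  nodes2$ip[far] <- nodes2$ip[far] + 50
  g2 <- new("GenomeGraph", nodes = nodes2, edges = edges, binSize = 10000)
  s1 <- predictSage(model, lg$graph)
  s2 <- predictSage(model, g2)
  expect_equal(s1$score[s1$node == target], s2$score[s2$node == target])
})

test_that("cross-application to a second graph needs no retraining", {
  lgA <- syntheticLoopGraph(nNodes = 800, nGenes = 200, seed = 15)
  lgB <- syntheticLoopGraph(nNodes = 800, nGenes = 200, seed = 16)
  nodesA <- graphNodes(lgA$graph)
  nodesA$label[nodesA$mask] <- ifelse(nodesA$ip[nodesA$mask] > 0,
                                      "High", "Low")
  gA <- new("GenomeGraph", nodes = nodesA, edges = graphEdges(lgA$graph),
            binSize = 10000)
  nodesB <- graphNodes(lgB$graph)
  nodesB$label[nodesB$mask] <- ifelse(nodesB$ip[nodesB$mask] > 0,
                                      "High", "Low")
  gB <- new("GenomeGraph", nodes = nodesB, edges = graphEdges(lgB$graph),
            binSize = 10000)
  model <- trainSage(gA, sageConfig(epochs = 150, seed = 15))
  prB <- predictSage(model, gB)
  expect_gte(evaluate(prB$score, prB$label)$auc, 0.9)
})
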