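# Shared synthetic fixtures, built once per test run. Everything is
# generated from fixed seeds so all tests are deterministic.

.fixtureCache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# The default study-condition genome: 4 chromosomes x 10 Mb, 400 genes,
# planted effect size d = 2, one planted enhancer per High gene with an
# 8x contact boost.
synthFixture <- function() cached("synth", function() {
  cfg <- synthConfig(seed = 7)
  gen <- synthGenome(cfg)
  tracks <- synthTracks(cfg, gen)
  hic <- synthHic(cfg, gen)
  balanced <- lapply(hic$maps, function(m) iceNormalize(m)$map)
  maps <- lapply(balanced, distanceNormalize)
  list(cfg = cfg, gen = gen, tracks = tracks, hic = hic,
       balanced = balanced, maps = maps)
})

# Labeled feature matrix on the default genome.
featureFixture <- function() cached("features", function() {
  s <- synthFixture()
  labelFeatureMatrix(featurizeSample(s$gen$genes, s$tracks$ip,
                                     s$tracks$input),
                     s$gen$tpm)
})

# Chromosome-hold-out MLP fit on the default genome.
fcdnnFixture <- function() cached("fcdnn", function() {
  trainFcdnn(featureFixture(), testChrom = "chr4", valChrom = "chr3",
             config = mlpConfig(seed = 7))
})

# Genome graph + trained GraphSAGE classifier on the default genome.
sageFixture <- function() cached("sage", function() {
  s <- synthFixture()
  graph <- buildGenomeGraph(s$maps, s$tracks$ip, s$tracks$input,
                            s$gen$genes, s$gen$tpm, k = 10, seed = 7)
  model <- trainSage(graph, sageConfig(epochs = 200, seed = 7))
  list(graph = graph, model = model)
})

# Map planted enhancers to (promoter node, enhancer node) pairs in the
# genome graph node indexing.
enhancerNodePairs <- function(s, graph) {
  nodes <- graphNodes(graph)
  bs <- 10000
  chroms <- names(s$maps)
  nPer <- vapply(s$maps, function(m) nrow(contactMatrix(m)), integer(1))
  offset <- stats::setNames(cumsum(c(0, nPer[-length(nPer)])), chroms)
  genes <- s$gen$genes
  tss <- tssOf(genes)
  enh <- s$gen$enhancers
  gi <- match(enh$gene_id, genes$gene_id)
  ch <- as.character(GenomicRanges::seqnames(genes))[gi]
  mid <- (GenomicRanges::start(enh) + GenomicRanges::end(enh)) %/% 2
  data.frame(gene_id = enh$gene_id,
             promNode = offset[ch] + floor((tss[gi] - 1) / bs) + 1,
             enhNode = offset[ch] + floor((mid - 1) / bs) + 1)
}

# A graph whose masked-node label is copied from a planted distal
# partner's IP feature: the partner edge exists only in the "true"
# edge set, so contact-graph convolutions can use it while the linear
# (nearest-bin) graph cannot.
syntheticLoopGraph <- function(nNodes = 2000, nGenes = 300, kBackground = 5,
                               seed = 1) {
  set.seed(seed)
  ip <- stats::rnorm(nNodes)
  input <- stats::rnorm(nNodes, sd = 0.3)
  geneNodes <- sort(sample(seq(51, nNodes - 50), nGenes))
  partner <- vapply(geneNodes, function(v) {
    repeat {
      p <- v + sample(c(-1, 1), 1) * sample(20:50, 1)
      if (p >= 1 && p <= nNodes && !(p %in% geneNodes)) return(p)
    }
  }, numeric(1))
  # partners carry a clearly bimodal IP signal; the gene label copies it
  ip[partner] <- sample(c(-2, 2), length(partner), TRUE) +
    stats::rnorm(length(partner), sd = 0.3)
  label <- ifelse(ip[partner] > 0, "High", "Low")
  # background edges: short-range random neighbors for every node
  bg <- do.call(rbind, lapply(seq_len(nNodes), function(v) {
    nb <- v + sample(setdiff(-15:15, 0), kBackground)
    nb <- nb[nb >= 1 & nb <= nNodes]
    if (length(nb)) cbind(pmin(v, nb), pmax(v, nb)) else NULL
  }))
  trueEdges <- unique(rbind(bg, cbind(pmin(geneNodes, partner),
                                      pmax(geneNodes, partner))))
  colnames(trueEdges) <- c("from", "to")
  nodes <- S4Vectors::DataFrame(
    chrom = "chr1", bin = seq_len(nNodes),
    start = (seq_len(nNodes) - 1L) * 10000 + 1L,
    ip = ip, input = input,
    label = NA_character_, mask = FALSE, fold = NA_character_)
  nodes$mask[geneNodes] <- TRUE
  nodes$label[geneNodes] <- label
  nodes$fold <- hmcReg:::assignFolds(nodes$mask, seed)
  graph <- new("GenomeGraph", nodes = nodes, edges = trueEdges,
               binSize = 10000)
  list(graph = graph, geneNodes = geneNodes, partner = partner,
       linearEdges = nearest1dGraph(c(chr1 = nNodes), k = 10))
}

# Hand-built SAGE model whose prediction is a monotone function of the
# neighbor-mean IP feature (used to unit-test the edge-mask explainer
# independently of training).
handSageModel <- function(scale = 4) {
  # positive conv bias keeps the rectifier in its active zone
  conv <- list(list(Wself = matrix(0, 2, 1),
                    Wneigh = matrix(c(scale, 0), 2, 1),
                    b = 2))
  head <- list(list(W = matrix(1, 1, 1), b = 0))
  cfg <- sageConfig(convLayers = 1, hidden = 1, headWidths = integer(0))
  cfg$inputWidth <- 2L
  new("SageClassifier", weights = list(conv = conv, head = head),
      config = cfg)
}

# Slow independent fixed-point oracle for ICE balancing: dense loops,
# no shared code with iceNormalize().
iceOracle <- function(m, iters = 5000) {
  m <- as.matrix(m)
  n <- nrow(m)
  for (it in seq_len(iters)) {
    s <- rowSums(m)
    nz <- s > 0
    if (!any(nz)) stop("all-zero matrix")
    target <- mean(s[nz])
    for (i in seq_len(n)) {
      if (!nz[i]) next
      f <- sqrt(s[i] / target)
      m[i, ] <- m[i, ] / f
      m[, i] <- m[, i] / f
    }
    s2 <- rowSums(m)
    if (stats::sd(s2[s2 > 0]) / mean(s2[s2 > 0]) < 1e-12) break
  }
  m
}

# Brute-force AUC: pairwise concordance over all (positive, negative)
# pairs, ties counted half.
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == "High"]
  neg <- scores[labels == "Low"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Constant-coverage track helper.
constTrack <- function(value, len, chrom = "chr1", depth = 1e6) {
  rl <- methods::as(stats::setNames(list(S4Vectors::Rle(value, len)), chrom),
                    "RleList")
  CoverageTrack(rl, totalMapped = depth)
}
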