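#' Build the genome graph of 10 kb windows
#'
#' Nodes are fixed-width windows tiling each chromosome present in
#' `maps`. Node features are `log10(1 + RPKM)` of the 5hmC IP and
#' input signal summed over the window. A node containing at least
#' one gene TSS is masked (usable for training); when several TSSs
#' fall in one window the mean TPM of those genes is taken and
#' dichotomized at the sample's gene-level median TPM. Masked nodes
#' are split 70/15/15 into train/validation/test folds at random
#' (seeded). Edges come from the per-chromosome top-k contact graph.
#'
#' @param maps Named list (by chromosome) of distance-normalized
#'   [ContactMap-class] objects.
#' @param ip,input [CoverageTrack-class] 5hmC IP and input signal.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param tpm Named TPM vector covering the genes.
#' @param k Neighbors per node for [topkGraph()].
#' @param seed Seed for the fold assignment.
#' @return A [GenomeGraph-class].
#' @export
buildGenomeGraph <- function(maps, ip, input, genes, tpm, k = 10, seed = 1) {
  chroms <- names(maps)
  binSize <- maps[[1]]@binSize
  nodeList <- list(); edgeList <- list(); offset <- 0L
  geneTpm <- tpm[genes$gene_id]
  medTpm <- stats::median(geneTpm)
  tssPos <- tssOf(genes)
  tssChrom <- as.character(seqnames(genes))
  for (ch in chroms) {
    nBins <- nrow(maps[[ch]]@mat)
    starts <- (seq_len(nBins) - 1L) * binSize + 1L
    win <- GRanges(ch, IRanges(starts, starts + binSize - 1L))
    ipS <- log10(1 + rpkm(regionSignal(ip, win), binSize, totalMapped(ip)))
    inS <- log10(1 + rpkm(regionSignal(input, win), binSize,
                          totalMapped(input)))
    sel <- tssChrom == ch
    bin <- floor((tssPos[sel] - 1L) / binSize) + 1L
    meanTpm <- rep(NA_real_, nBins)
    if (any(sel)) {
      agg <- tapply(geneTpm[sel], bin, mean)
      meanTpm[as.integer(names(agg))] <- agg
    }
    label <- ifelse(is.na(meanTpm), NA_character_,
                    ifelse(meanTpm > medTpm, "High", "Low"))
    nodeList[[ch]] <- DataFrame(chrom = ch, bin = seq_len(nBins),
                                start = starts, ip = ipS, input = inS,
                                label = label, mask = !is.na(meanTpm),
                                meanTpm = meanTpm)
    e <- topkGraph(maps[[ch]], k = k)
    if (nrow(e)) edgeList[[ch]] <- e + offset
    offset <- offset + nBins
  }
  nodes <- do.call(rbind, nodeList)
  if (!any(nodes$mask)) stop("no node contains a TSS; nothing to train on")
  nodes$fold <- assignFolds(nodes$mask, seed)
  edges <- do.call(rbind, edgeList)
  new("GenomeGraph", nodes = nodes, edges = edges, binSize = binSize)
}

# 70/15/15 random fold split over masked nodes.
assignFolds <- function(mask, seed) {
  fold <- rep(NA_character_, length(mask))
  idx <- which(mask)
  withSeed(seed, {
    idx <- sample(idx)
    n <- length(idx)
    nTrain <- round(0.70 * n)
    nVal <- round(0.15 * n)
    fold[idx[seq_len(nTrain)]] <- "train"
    fold[idx[nTrain + seq_len(nVal)]] <- "val"
    if (nTrain + nVal < n)
      fold[idx[(nTrain + nVal + 1L):n]] <- "test"
  })
  fold
}

#' Node table / edge accessors
#' @param graph A `GenomeGraph`.
#' @export
graphNodes <- function(graph) graph@nodes

#' @rdname graphNodes
#' @export
graphEdges <- function(graph) graph@edges

#' Replace the edge set of a genome graph
#'
#' Used to compare contact-derived graphs against baselines (e.g. the
#' linear-genome nearest-bin graph) on identical nodes.
#' @param graph A `GenomeGraph`.
#' @param edges Two-column integer edge matrix.
#' @export
setGraphEdges <- function(graph, edges) {
  new("GenomeGraph", nodes = graph@nodes, edges = edges,
      binSize = graph@binSize)
}

#' Linear-genome nearest-bin baseline graph
#'
#' Connects every bin to its k nearest bins along the chromosome
#' (k/2 on each side, fewer at chromosome ends), ignoring any contact
#' map. Node indexing matches [buildGenomeGraph()]'s ordering of the
#' same chromosomes.
#'
#' @param nBinsPerChrom Named integer vector: bins per chromosome, in
#'   node order.
#' @param k Total neighbors per interior bin (default 10: 5 per side).
#' @return Two-column integer edge matrix (undirected, global node
#'   indices).
#' @export
nearest1dGraph <- function(nBinsPerChrom, k = 10) {
  half <- k %/% 2
  edges <- list(); offset <- 0L
  for (nb in nBinsPerChrom) {
    for (d in seq_len(half)) {
      if (nb > d) {
        i <- seq_len(nb - d)
        edges[[length(edges) + 1L]] <- cbind(i + offset, i + d + offset)
      }
    }
    offset <- offset + nb
  }
  e <- do.call(rbind, edges)
  colnames(e) <- c("from", "to")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
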