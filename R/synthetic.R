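#' Configuration for the synthetic genome generator
#'
#' The generator plants every statistical structure the pipeline
#' assumes: non-overlapping genes with a bimodal TPM distribution
#' whose median split recovers the planted High/Low assignment,
#' 5hmC IP/input tracks whose gene-body enrichment follows the
#' planted label (dip at the TSS, enrichment maximal just downstream
#' of the TSS, shoulder past the TTS), ATAC-like peaks at promoters
#' and planted enhancers, and distance-decaying symmetric contact
#' maps with planted enhancer-promoter loops.
#'
#' @param nChroms Number of chromosomes.
#' @param chromLength Chromosome length in bp.
#' @param nGenes Total gene count (split evenly across chromosomes).
#' @param lengthRange Gene length range (log-uniform), bp.
#' @param highFraction Fraction of genes planted High.
#' @param effectSize Planted log2 IP/input enrichment at the
#'   gene-body plateau of High genes.
#' @param enhancerProb Probability a High gene gets a planted distal
#'   enhancer.
#' @param enhancerDist Distance range of planted enhancers from the
#'   TSS, bp.
#' @param loopBoost Contact multiplier at planted enhancer-promoter
#'   bin pairs.
#' @param decay Power-law exponent of background contact decay.
#' @param hicScale Expected contact count at adjacent bins.
#' @param inputRate Poisson mean of the input coverage per step.
#' @param stepSize Coverage step size, bp.
#' @param binSize Hi-C bin size, bp.
#' @param seed Master seed.
#' @export
synthConfig <- function(nChroms = 4, chromLength = 1e7, nGenes = 400,
                        lengthRange = c(1500, 1e5), highFraction = 0.5,
                        effectSize = 2, enhancerProb = 1,
                        enhancerDist = c(5e4, 5e5), loopBoost = 8,
                        decay = 1, hicScale = 30, inputRate = 5,
                        stepSize = 100, binSize = 10000, seed = 1) {
  list(nChroms = nChroms, chromLength = chromLength, nGenes = nGenes,
       lengthRange = lengthRange, highFraction = highFraction,
       effectSize = effectSize, enhancerProb = enhancerProb,
       enhancerDist = enhancerDist, loopBoost = loopBoost, decay = decay,
       hicScale = hicScale, inputRate = inputRate, stepSize = stepSize,
       binSize = binSize, seed = seed)
}

#' Generate the synthetic gene set, labels and expression table
#'
#' Genes are placed without overlap (with a 60 kb margin at the
#' chromosome ends so flanks and planted enhancers stay inside).
#' TPMs are drawn from two well-separated log-normal components so
#' the median split recovers the planted labels exactly; planted
#' enhancers are intergenic.
#'
#' @param config From [synthConfig()].
#' @return List: `genes` (`GRanges` with `gene_id`), `tpm` (named),
#'   `labels` (named, planted), `enhancers` (`GRanges` with
#'   `gene_id`), `chromLengths` (named).
#' @export
synthGenome <- function(config = synthConfig()) {
  withSeed(config$seed, {
    margin <- 6e4
    perChrom <- rep(config$nGenes %/% config$nChroms, config$nChroms)
    extra <- config$nGenes %% config$nChroms
    if (extra) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
    chroms <- paste0("chr", seq_len(config$nChroms))
    geneList <- list()
    sinfo <- GenomeInfoDb::Seqinfo(chroms,
                                   rep(config$chromLength, config$nChroms))
    for (ci in seq_along(chroms)) {
      nG <- perChrom[ci]
      lens <- round(exp(stats::runif(nG, log(config$lengthRange[1]),
                                     log(config$lengthRange[2]))))
      avail <- config$chromLength - 2 * margin - sum(lens)
      if (avail < nG + 1)
        stop("genes cannot be placed; reduce nGenes or gene lengths")
      u <- stats::runif(nG + 1)
      gaps <- floor(avail * u / sum(u))
      starts <- margin + cumsum(gaps[seq_len(nG)]) +
        c(0, cumsum(lens))[seq_len(nG)] + 1
      geneList[[ci]] <- GRanges(chroms[ci],
        IRanges(starts, width = lens),
        strand = sample(c("+", "-"), nG, replace = TRUE),
        seqinfo = sinfo)
    }
    genes <- do.call(c, geneList)
    genes$gene_id <- sprintf("g%04d", seq_along(genes))
    n <- length(genes)
    nHigh <- round(config$highFraction * n)
    labels <- rep("Low", n)
    labels[sample.int(n, nHigh)] <- "High"
    tpm <- numeric(n)
    repeat {
      tpm[labels == "Low"] <- exp(stats::rnorm(sum(labels == "Low"), 0, 0.4))
      tpm[labels == "High"] <- 200 * exp(stats::rnorm(nHigh, 0, 0.4))
      if (nHigh == 0 || nHigh == n ||
          max(tpm[labels == "Low"]) < min(tpm[labels == "High"])) break
    }
    names(tpm) <- names(labels) <- genes$gene_id
    # plant intergenic enhancers for High genes
    enh <- list()
    tss <- tssOf(genes)
    for (g in which(labels == "High")) {
      if (stats::runif(1) > config$enhancerProb) next
      for (try in 1:50) {
        d <- round(stats::runif(1, config$enhancerDist[1],
                                config$enhancerDist[2]))
        pos <- tss[g] + sample(c(-1, 1), 1) * d
        if (pos < 2000 || pos > config$chromLength - 2000) next
        cand <- GRanges(seqnames(genes)[g], IRanges(pos - 500, pos + 499),
                        seqinfo = sinfo)
        if (!any(countOverlaps(cand, genes, ignore.strand = TRUE)))
          { enh[[length(enh) + 1L]] <- `mcols<-`(cand,
              value = DataFrame(gene_id = genes$gene_id[g])); break }
      }
    }
    enhancers <- if (length(enh)) do.call(c, enh) else
      GRanges(gene_id = character(0))
    chromLengths <- stats::setNames(rep(config$chromLength,
                                        config$nChroms), chroms)
    list(genes = genes, tpm = tpm, labels = labels, enhancers = enhancers,
         chromLengths = chromLengths)
  })
}

# Enrichment profile over the gene body: 0 at the TSS (the planted
# TSS dip), peaking at 1 within the first ~5% of the span so the
# strongest planted signal sits just downstream of the TSS, then a
# lower plateau through the rest of the body.
bodyProfile <- function(u) {
  ramp <- pmin(u / 0.015, 1)
  peak <- exp(-((u - 0.03)^2) / (2 * 0.025^2))
  ramp * pmax(peak, 0.55)
}

#' Generate synthetic 5hmC IP/input tracks and ATAC-like peaks
#'
#' Input coverage is Poisson background; IP adds the planted
#' gene-body enrichment (factor `2^effectSize` at the plateau) for
#' High genes and at planted enhancers. Peaks (with summits) are
#' produced at every promoter and every planted enhancer, plus an
#' ATAC-like accessibility track with signal at the same sites.
#'
#' @param config From [synthConfig()].
#' @param genome From [synthGenome()].
#' @return List of [CoverageTrack-class] `ip`, `input`, `atac` and
#'   `peaks` (`GRanges` with score/summit).
#' @export
synthTracks <- function(config = synthConfig(), genome) {
  withSeed(config$seed + 1L, {
    step <- config$stepSize
    nSteps <- ceiling(config$chromLength / step)
    fold <- 2^config$effectSize
    genes <- genome$genes
    ipCov <- list(); inCov <- list(); atCov <- list()
    for (ch in names(genome$chromLengths)) {
      lambdaMult <- rep(1, nSteps)
      atacMult <- rep(1, nSteps)
      onCh <- which(as.character(seqnames(genes)) == ch)
      for (g in onCh) {
        s <- start(genes)[g]; e <- end(genes)[g]
        stepIdx <- (floor((s - 1) / step) + 1L):(floor((e - 1) / step) + 1L)
        midPos <- (stepIdx - 0.5) * step
        u <- if (as.character(strand(genes)[g]) == "-")
          (e - midPos) / (e - s) else (midPos - s) / (e - s)
        u <- pmin(pmax(u, 0), 1)
        if (genome$labels[genes$gene_id[g]] == "High")
          lambdaMult[stepIdx] <- lambdaMult[stepIdx] +
            (fold - 1) * bodyProfile(u)
        # accessibility at the promoter for every gene
        t0 <- tssOf(genes[g])
        pIdx <- (floor((t0 - 300) / step) + 1L):(floor((t0 + 300) / step) + 1L)
        atacMult[pIdx] <- atacMult[pIdx] + 8
      }
      if (length(genome$enhancers)) {
        eCh <- which(as.character(seqnames(genome$enhancers)) == ch)
        for (ei in eCh) {
          # enhancers are strong focal 5hmC sites: ~2 kb at several-fold
          # enrichment, so they remain visible at 10 kb window resolution
          mid <- (start(genome$enhancers)[ei] + end(genome$enhancers)[ei]) %/% 2
          idx <- (floor((mid - 1000) / step) + 1L):(floor((mid + 1000) / step) + 1L)
          lambdaMult[idx] <- lambdaMult[idx] + 4 * (fold - 1)
          atacMult[idx] <- atacMult[idx] + 5
        }
      }
      inVals <- stats::rpois(nSteps, config$inputRate)
      ipVals <- stats::rpois(nSteps, config$inputRate * lambdaMult)
      atVals <- stats::rpois(nSteps, config$inputRate * atacMult)
      ipCov[[ch]] <- S4Vectors::Rle(ipVals, rep(step, nSteps))
      inCov[[ch]] <- S4Vectors::Rle(inVals, rep(step, nSteps))
      atCov[[ch]] <- S4Vectors::Rle(atVals, rep(step, nSteps))
    }
    mk <- function(lst) {
      rl <- methods::as(lst, "RleList")
      CoverageTrack(rl, totalMapped = sum(vapply(lst, function(r)
        sum(as.numeric(runValue(r)) * runLength(r)) / 100, numeric(1))))
    }
    # peaks: promoter of every gene + every planted enhancer
    t0 <- tssOf(genes)
    promPeaks <- GRanges(seqnames(genes), IRanges(t0 - 200, t0 + 199),
                         score = round(stats::runif(length(genes), 200, 1000)),
                         signalValue = stats::runif(length(genes), 5, 20),
                         summit = t0)
    promPeaks$name <- paste0("prom_", genes$gene_id)
    peaks <- promPeaks
    if (length(genome$enhancers)) {
      mid <- (start(genome$enhancers) + end(genome$enhancers)) %/% 2
      enhPeaks <- GRanges(seqnames(genome$enhancers),
                          IRanges(mid - 200, mid + 199),
                          score = round(stats::runif(length(mid), 50, 500)),
                          signalValue = stats::runif(length(mid), 2, 10),
                          summit = mid)
      enhPeaks$name <- paste0("enh_", genome$enhancers$gene_id)
      suppressWarnings(peaks <- c(peaks, enhPeaks))
    }
    list(ip = mk(ipCov), input = mk(inCov), atac = mk(atCov), peaks = peaks)
  })
}

#' Generate synthetic Hi-C contact maps with planted loops
#'
#' Expected contact decays as `hicScale * d^(-decay)` with distance d
#' (in bins); planted enhancer-promoter bin pairs are boosted by
#' `loopBoost`. Counts are Poisson-sampled and symmetric.
#'
#' @param config From [synthConfig()].
#' @param genome From [synthGenome()].
#' @return List: `maps` (named list of raw-count
#'   [ContactMap-class]), `pairs` (data.frame `chrom`, `bin_i`,
#'   `bin_j`, one row per interaction).
#' @export
synthHic <- function(config = synthConfig(), genome) {
  withSeed(config$seed + 2L, {
    bs <- config$binSize
    nBins <- ceiling(config$chromLength / bs)
    genes <- genome$genes
    tss <- tssOf(genes)
    maps <- list(); pairParts <- list()
    for (ch in names(genome$chromLengths)) {
      ii <- rep(seq_len(nBins), times = nBins - seq_len(nBins) + 1L)
      jj <- unlist(lapply(seq_len(nBins), function(i) i:nBins))
      d <- jj - ii
      ev <- config$hicScale * pmax(d, 1)^(-config$decay)
      ev[d == 0] <- config$hicScale * 2
      if (length(genome$enhancers)) {
        eCh <- which(as.character(seqnames(genome$enhancers)) == ch)
        for (ei in eCh) {
          g <- match(genome$enhancers$gene_id[ei], genes$gene_id)
          pb <- floor((tss[g] - 1) / bs) + 1L
          mid <- (start(genome$enhancers)[ei] + end(genome$enhancers)[ei]) %/% 2
          eb <- floor((mid - 1) / bs) + 1L
          sel <- (ii == min(pb, eb) & jj == max(pb, eb))
          ev[sel] <- ev[sel] * config$loopBoost
        }
      }
      x <- stats::rpois(length(ev), ev)
      nz <- x > 0
      maps[[ch]] <- contactMap(ch, bs, i = ii[nz], j = jj[nz], x = x[nz],
                               nBins = nBins)
      pairParts[[ch]] <- data.frame(
        chrom = ch,
        bin_i = rep(ii[nz], x[nz]),
        bin_j = rep(jj[nz], x[nz]))
    }
    list(maps = maps, pairs = do.call(rbind, pairParts))
  })
}

#' Write a synthetic dataset in standard formats
#'
#' Emits the same formats the real pipeline reads: BED6 gene models,
#' bedGraph IP/input/ATAC coverage, narrowPeak peaks, per-chromosome
#' COO contact triplets, and a TSV expression table.
#'
#' @param genome,tracks,hic Outputs of the three generators.
#' @param dir Output directory (created if needed).
#' @export
writeSyntheticData <- function(genome, tracks, hic, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGeneModels(genome$genes, file.path(dir, "genes.bed"))
  for (nm in c("ip", "input", "atac")) {
    gr <- methods::as(tracks[[nm]]@coverage, "GRanges")
    rtracklayer::export(gr[gr$score > 0],
                        file.path(dir, paste0(nm, ".bedGraph")),
                        format = "bedGraph")
  }
  writeNarrowPeak(tracks$peaks, file.path(dir, "peaks.narrowPeak"))
  for (ch in names(hic$maps))
    writeContactMap(hic$maps[[ch]], file.path(dir, paste0("hic_", ch, ".coo")))
  expr <- data.frame(gene_id = names(genome$tpm), TPM = unname(genome$tpm))
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
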