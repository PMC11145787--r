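#' Candidate enhancer regions from peak summits
#'
#' Keeps the `nStrongest` peaks by score, extends each summit by
#' +/- `extend` bp, merges overlapping extensions and removes regions
#' overlapping the blacklist.
#'
#' @param peaks `GRanges` with `score` and absolute `summit` positions
#'   (as from [readNarrowPeak()]).
#' @param extend Summit extension in bp (default 250, i.e. 500 bp
#'   elements).
#' @param nStrongest Number of strongest peaks retained (default
#'   150000).
#' @param blacklist Optional `GRanges` of excluded regions.
#' @return `GRanges` of merged candidate regions.
#' @export
candidateRegions <- function(peaks, extend = 250, nStrongest = 150000,
                             blacklist = NULL) {
  if (is.null(peaks$summit)) stop("peaks must carry summit positions")
  if (length(peaks) > nStrongest) {
    o <- order(peaks$score, decreasing = TRUE)
    peaks <- peaks[o[seq_len(nStrongest)]]
  }
  ext <- GRanges(seqnames(peaks),
                 IRanges(peaks$summit - extend, peaks$summit + extend - 1L))
  merged <- reduce(ext, ignore.strand = TRUE)
  if (!is.null(blacklist)) merged <- excludeBlacklist(merged, blacklist)
  merged
}

#' Element activity: geometric mean of accessibility and activity signal
#'
#' `A = sqrt((RPKM_access + eps) * (RPKM_activity + eps))`, with the
#' activity track being 5hmC enrichment or H3K27ac.
#'
#' @param candidates `GRanges` of candidate elements.
#' @param accessibility,activity [CoverageTrack-class] signals.
#' @param eps RPKM pseudocount (default 0.1).
#' @return Numeric activity per candidate.
#' @export
elementActivity <- function(candidates, accessibility, activity, eps = 0.1) {
  acc <- rpkm(regionSignal(accessibility, candidates), width(candidates),
              totalMapped(accessibility))
  act <- rpkm(regionSignal(activity, candidates), width(candidates),
              totalMapped(activity))
  sqrt((acc + eps) * (act + eps))
}

#' Fit the contact-vs-distance power law
#'
#' Least-squares line on (log distance, log mean contact) over
#' `dRange`; returns the decay exponent gamma (negated slope) and the
#' scale kappa such that expected contact ~ kappa * d^(-gamma).
#'
#' @param map A balanced [ContactMap-class].
#' @param dRange Distance range in bp used for the fit.
#' @return List with `gamma`, `kappa`, `dRange`.
#' @export
fitPowerlaw <- function(map, dRange = c(2e4, 2e6)) {
  n <- nrow(map@mat)
  tm <- methods::as(Matrix::triu(map@mat), "TsparseMatrix")
  off <- tm@j - tm@i
  offs <- seq(max(1, floor(dRange[1] / map@binSize)),
              min(n - 1, floor(dRange[2] / map@binSize)))
  usable <- offs[offs %in% seq_len(n - 1)]
  meanC <- vapply(usable, function(d) {
    sum(tm@x[off == d]) / (n - d)   # structural zeros included in the mean
  }, numeric(1))
  keep <- meanC > 0
  if (sum(keep) < 3) stop("fewer than 3 usable distances for power-law fit")
  ld <- log(usable[keep] * map@binSize)
  lc <- log(meanC[keep])
  fit <- stats::lm.fit(cbind(1, ld), lc)
  gamma <- -fit$coefficients[2]
  kappa <- exp(fit$coefficients[1])
  list(gamma = unname(gamma), kappa = unname(kappa), dRange = dRange)
}

#' Element-gene contact score
#'
#' Observed balanced contact between the element bin and the TSS bin
#' plus a power-law pseudocount `kappa * max(d, 1 Mb)^(-gamma)`;
#' missing observed entries are imputed by `kappa * d^(-gamma)`.
#' Same-bin lookups (offset 0) use the maximum observed contact among
#' offsets 1-2 for that bin, since the balanced diagonal is
#' ill-defined.
#'
#' @param map Balanced [ContactMap-class] for the gene's chromosome.
#' @param fit A [fitPowerlaw()] result.
#' @param elementMid Element midpoint positions (bp, 1-based).
#' @param tss Gene TSS position (bp, 1-based).
#' @return Numeric contact per element.
#' @export
geneElementContact <- function(map, fit, elementMid, tss) {
  bs <- map@binSize
  n <- nrow(map@mat)
  eBin <- pmin(pmax(floor((elementMid - 1) / bs) + 1L, 1L), n)
  tBin <- min(max(floor((tss - 1) / bs) + 1L, 1L), n)
  m <- map@mat
  obs <- numeric(length(eBin))
  same <- eBin == tBin
  if (any(same)) {
    neigh <- c(if (tBin > 1) m[tBin, tBin - 1L], if (tBin < n) m[tBin, tBin + 1L],
               if (tBin > 2) m[tBin, tBin - 2L], if (tBin < n - 1) m[tBin, tBin + 2L])
    obs[same] <- if (length(neigh)) max(neigh) else 0
  }
  if (any(!same)) obs[!same] <- m[cbind(eBin[!same], tBin)]
  d <- pmax(abs(eBin - tBin), 1) * bs
  powerObs <- fit$kappa * d^(-fit$gamma)
  pseudo <- fit$kappa * pmax(d, 1e6)^(-fit$gamma)
  ifelse(obs > 0, obs + pseudo, powerObs + pseudo)
}

#' Activity-by-Contact scores
#'
#' For every gene, scores each candidate element within `maxDist` of
#' its TSS as `S(e, g) = A_e * C_eg / sum_e' A_e' * C_e'g` (the sum
#' over all candidates in range), so per-gene scores sum to 1 before
#' thresholding. With `allPutative = TRUE` the unthresholded list is
#' returned, otherwise pairs with `S >= threshold` are kept.
#'
#' @param candidates `GRanges` of candidate elements with an
#'   `activity` metadata column (from [elementActivity()]).
#' @param genes `GRanges` gene models with `gene_id`.
#' @param maps Named list (by chromosome) of balanced
#'   [ContactMap-class] objects.
#' @param fits Named list of [fitPowerlaw()] results per chromosome
#'   (or a single fit reused for all).
#' @param threshold Minimum ABC score kept (default 0.02).
#' @param maxDist Candidate window around the TSS (default 5 Mb).
#' @param allPutative Return unthresholded scores.
#' @return data.frame: chrom, start, end, gene_id, activity, contact,
#'   abcScore.
#' @export
abcScores <- function(candidates, genes, maps, fits, threshold = 0.02,
                      maxDist = 5e6, allPutative = FALSE) {
  if (is.null(candidates$activity))
    stop("candidates need an 'activity' column; run elementActivity()")
  singleFit <- !is.null(fits$gamma)
  out <- list()
  mid <- (start(candidates) + end(candidates)) %/% 2
  candChrom <- as.character(seqnames(candidates))
  for (g in seq_along(genes)) {
    ch <- as.character(seqnames(genes)[g])
    if (!ch %in% names(maps)) next
    tss <- tssOf(genes[g])
    sel <- which(candChrom == ch & abs(mid - tss) <= maxDist)
    if (!length(sel)) {
      message("no candidate in range for gene ", genes$gene_id[g])
      next
    }
    fit <- if (singleFit) fits else fits[[ch]]
    C <- geneElementContact(maps[[ch]], fit, mid[sel], tss)
    A <- candidates$activity[sel]
    s <- A * C / sum(A * C)
    keep <- if (allPutative) seq_along(s) else which(s >= threshold)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start(candidates)[sel[keep]],
        end = end(candidates)[sel[keep]], gene_id = genes$gene_id[g],
        activity = A[keep], contact = C[keep], abcScore = s[keep])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      activity = numeric(0), contact = numeric(0),
                      abcScore = numeric(0)))
  do.call(rbind, out)
}

#' Compare two region sets
#'
#' `any_overlap`: a region of either set sharing >= 1 bp with the
#' other counts as shared. `contained_in_bins`: a region of `setA`
#' counts as shared only when fully inside a region (bin) of `setB`.
#'
#' @param setA,setB `GRanges` interval sets.
#' @param mode "any_overlap" or "contained_in_bins".
#' @return Named counts `a_only`, `shared`, `b_only` (shared is
#'   counted in units of `setA` regions; `b_only` counts `setB`
#'   regions not overlapping/containing any `setA` region).
#' @export
compareRegionSets <- function(setA, setB,
                              mode = c("any_overlap", "contained_in_bins")) {
  mode <- match.arg(mode)
  type <- if (mode == "any_overlap") "any" else "within"
  hits <- findOverlaps(setA, setB, type = type, ignore.strand = TRUE)
  aShared <- seq_along(setA) %in% queryHits(hits)
  bHit <- seq_along(setB) %in% subjectHits(hits)
  c(a_only = sum(!aShared), shared = sum(aShared), b_only = sum(!bHit))
}

#' Distances from predicted elements to TSSs
#'
#' Per prediction: distance from the element midpoint to its target
#' gene's TSS, and to the closest TSS of any gene.
#'
#' @param predictions data.frame from [abcScores()].
#' @param genes `GRanges` gene models with `gene_id`.
#' @return data.frame with `targetDist` and `closestDist`.
#' @export
distanceDistributions <- function(predictions, genes) {
  tss <- tssOf(genes)
  chrom <- as.character(seqnames(genes))
  mid <- (predictions$start + predictions$end) %/% 2
  targetIdx <- match(predictions$gene_id, genes$gene_id)
  targetDist <- abs(mid - tss[targetIdx])
  closestDist <- vapply(seq_len(nrow(predictions)), function(i) {
    onChrom <- chrom == predictions$chrom[i]
    min(abs(mid[i] - tss[onChrom]))
  }, numeric(1))
  data.frame(targetDist = targetDist, closestDist = closestDist)
}
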