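#' RPKM normalization
#'
#' Reads per kilobase per million mapped reads:
#' `count / ((width/1000) * (depth/1e6))`.
#'
#' @param count Read count (or summed signal) per interval.
#' @param width Interval width in bp (> 0).
#' @param depth Library depth in mapped reads (> 0).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, width, depth) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(depth <= 0)) stop("depth must be positive")
  count / ((width / 1000) * (depth / 1e6))
}

#' The 230-bin per-gene layout
#'
#' For one gene, returns the ordered bin intervals used for 5hmC
#' featurization, always in transcription (5' to 3') order:
#' 15 x 100 bp upstream-of-TSS flank bins, 100 x 100 bp promoter bins
#' spanning TSS +/- 5 kb, 100 variable-width gene-body bins tiling
#' TSS..TTS exactly (widths differ by at most 1 bp), and 15 x 100 bp
#' downstream-of-TTS flank bins. Minus-strand genes have their bins
#' mirrored in genomic space so bin index always increases 5' to 3'.
#'
#' @param gene A length-1 `GRanges` gene model (width > 1000).
#' @param promoterFlank Promoter half-window around the TSS (bp).
#' @param promoterBins Number of fixed promoter bins.
#' @param flankWidth TSS-upstream / TTS-downstream flank span (bp).
#' @param flankBins Number of bins per flank.
#' @param bodyBins Number of variable-width gene-body bins.
#' @return `GRanges` of `flankBins + promoterBins + bodyBins +
#'   flankBins` intervals with a `role` metadata column.
#' @export
makeFeatureBins <- function(gene, promoterFlank = 5000, promoterBins = 100,
                            flankWidth = 1500, flankBins = 15,
                            bodyBins = 100) {
  if (length(gene) != 1L) stop("makeFeatureBins expects a single gene")
  L <- width(gene)
  if (L <= 1000) stop("gene must be longer than 1 kb")
  binW <- flankWidth / flankBins
  pw <- 2 * promoterFlank / promoterBins
  # offsets are 0-based distances downstream of the TSS base
  up <- cbind(-flankWidth + binW * (seq_len(flankBins) - 1),
              -flankWidth + binW * seq_len(flankBins))
  prom <- cbind(-promoterFlank + pw * (seq_len(promoterBins) - 1),
                -promoterFlank + pw * seq_len(promoterBins))
  edges <- floor((0:bodyBins) * L / bodyBins)
  body <- cbind(edges[-length(edges)], edges[-1])
  down <- cbind(L + binW * (seq_len(flankBins) - 1), L + binW * seq_len(flankBins))
  off <- rbind(up, prom, body, down)
  role <- rep(c("upstream_flank", "promoter", "gene_body", "tts_flank"),
              c(flankBins, promoterBins, bodyBins, flankBins))
  t0 <- tssOf(gene)
  minus <- as.character(strand(gene)) == "-"
  if (minus) {
    gstart <- t0 - off[, 2] + 1
    gend <- t0 - off[, 1]
  } else {
    gstart <- t0 + off[, 1]
    gend <- t0 + off[, 2] - 1
  }
  GRanges(rep(as.character(seqnames(gene)), nrow(off)),
          IRanges(gstart, gend), strand = as.character(strand(gene)),
          role = role, bin = seq_len(nrow(off)))
}

# All genes' bins in one GRanges with a gene index column.
allFeatureBins <- function(genes, ...) {
  lst <- lapply(seq_along(genes), function(i) {
    b <- makeFeatureBins(genes[i], ...)
    b$geneIdx <- i
    b
  })
  suppressWarnings(do.call(c, lst))
}

#' Build the per-gene 5hmC enrichment feature matrix for one sample
#'
#' Per bin, the feature is `log2((RPKM_ip + 0.5) / (RPKM_input + 0.5))`
#' (IP enrichment over matched input, both normalized for sequencing
#' depth and bin size). If the input track is all zero the features
#' fall back to `log2(RPKM_ip + 0.5)` with a warning. Standardization
#' is a separate step ([standardizeFeatures()]) so its statistics can
#' be frozen on training genes only.
#'
#' @param genes Gene models (`GRanges` with `gene_id`), all > 1 kb.
#' @param ip,input [CoverageTrack-class] IP and matched input signal.
#' @param pseudocount Added to both RPKM values before the log ratio.
#' @param ... Bin-layout parameters passed to [makeFeatureBins()].
#' @return An unlabeled, unstandardized [FeatureMatrix-class].
#' @export
featurizeSample <- function(genes, ip, input, pseudocount = 0.5, ...) {
  if (any(width(genes) <= 1000)) stop("all genes must be longer than 1 kb")
  bins <- allFeatureBins(genes, ...)
  nBins <- length(bins) / length(genes)
  ipR <- rpkm(regionSignal(ip, bins), width(bins), totalMapped(ip))
  inputZero <- all(vapply(input@coverage,
                          function(r) length(r) == 0 || max(r) == 0,
                          logical(1)))
  if (inputZero) {
    warning("input track is all zero; using log2(RPKM_ip + pseudocount)")
    feat <- log2(ipR + pseudocount)
  } else {
    inR <- rpkm(regionSignal(input, bins), width(bins), totalMapped(input))
    feat <- log2((ipR + pseudocount) / (inR + pseudocount))
  }
  m <- matrix(feat, nrow = nBins, ncol = length(genes))
  colnames(m) <- genes$gene_id
  roles <- bins$role[seq_len(nBins)]
  se <- SummarizedExperiment(
    assays = list(enrichment = m),
    rowData = DataFrame(role = roles, bin = seq_len(nBins)),
    colData = DataFrame(gene_id = genes$gene_id,
                        chrom = as.character(seqnames(genes)),
                        strand = as.character(strand(genes)),
                        tss = tssOf(genes), tts = ttsOf(genes),
                        row.names = genes$gene_id))
  new("FeatureMatrix", se)
}

#' Genes x bins feature values
#' @param x A `FeatureMatrix`.
#' @return Numeric matrix, genes in rows, bins in columns.
#' @export
featureValues <- function(x) t(assay(x, "enrichment"))

#' Bin roles of a FeatureMatrix
#' @param x A `FeatureMatrix`.
#' @export
binRoles <- function(x) rowData(x)$role

#' High/Low labels of a FeatureMatrix
#' @param x A `FeatureMatrix`.
#' @export
geneLabels <- function(x) {
  if (!"label" %in% colnames(colData(x))) return(rep(NA_character_, ncol(x)))
  as.character(colData(x)$label)
}

#' Label genes High/Low at the sample median TPM
#'
#' A gene is High iff its TPM is strictly above the median TPM over
#' the supplied genes; ties at the median are Low.
#'
#' @param tpm Named numeric vector of TPM values (>= 0).
#' @return Character vector of "High"/"Low", same names.
#' @export
labelGenes <- function(tpm) {
  if (length(tpm) < 2) stop("need at least 2 genes to split at the median")
  med <- stats::median(tpm)
  out <- ifelse(tpm > med, "High", "Low")
  names(out) <- names(tpm)
  out
}

#' Attach expression labels (and TPM) to a FeatureMatrix
#'
#' @param x A `FeatureMatrix`.
#' @param tpm Named TPM vector covering every gene in `x`.
#' @return Labeled `FeatureMatrix`.
#' @export
labelFeatureMatrix <- function(x, tpm) {
  missing <- setdiff(colnames(x), names(tpm))
  if (length(missing))
    stop("genes missing from expression table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  tpm <- tpm[colnames(x)]
  colData(x)$tpm <- unname(tpm)
  colData(x)$label <- unname(labelGenes(tpm))
  validObject(x)
  x
}

#' Per-bin z-score standardization frozen on training genes
#'
#' Computes per-bin mean and sd over the `train` genes only and
#' applies them to every gene, storing the statistics in
#' `metadata(x)$scaling` so validation/test genes are transformed with
#' frozen training statistics.
#'
#' @param x A `FeatureMatrix`.
#' @param train Logical or integer index of training genes (columns).
#' @return Standardized `FeatureMatrix`.
#' @export
standardizeFeatures <- function(x, train = seq_len(ncol(x))) {
  m <- assay(x, "enrichment")
  tm <- m[, train, drop = FALSE]
  center <- rowMeans(tm)
  scale <- apply(tm, 1, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  assay(x, "enrichment") <- (m - center) / scale
  metadata(x)$scaling <- list(center = center, scale = scale)
  x
}

#' Apply previously frozen standardization statistics
#' @param x An unstandardized `FeatureMatrix`.
#' @param scaling A list with `center` and `scale` (from
#'   `metadata(std)$scaling`).
#' @export
applyStandardization <- function(x, scaling) {
  m <- assay(x, "enrichment")
  if (length(scaling$center) != nrow(m)) stop("scaling length mismatch")
  assay(x, "enrichment") <- (m - scaling$center) / scaling$scale
  metadata(x)$scaling <- scaling
  x
}

#' Drop promoter-surrounding bins from the feature set
#'
#' Removes the listed bins so downstream models see only the
#' remaining features. The default removes every fixed-size bin (the
#' two 15-bin flanks and the 100 promoter bins, 130 bins total),
#' leaving the 100 gene-body bins.
#'
#' @param x A `FeatureMatrix`.
#' @param binIndices 1-based bin indices to remove; default all bins
#'   whose role is not `gene_body`.
#' @return `FeatureMatrix` with fewer rows.
#' @export
maskPromoterBins <- function(x, binIndices = NULL) {
  if (is.null(binIndices))
    binIndices <- which(binRoles(x) != "gene_body")
  if (length(binIndices) == 0L) return(x)
  if (any(binIndices < 1L | binIndices > nrow(x)))
    stop("bin index out of range 1..", nrow(x))
  keep <- setdiff(seq_len(nrow(x)), binIndices)
  if (length(keep) == 0L) stop("cannot mask every bin: no features left")
  x[keep, ]
}

#' Write a FeatureMatrix as TSV plus a sidecar layout JSON
#'
#' @param x A `FeatureMatrix`.
#' @param path TSV output (gene_id, one column per bin, label).
#' @export
writeFeatureMatrix <- function(x, path) {
  fv <- featureValues(x)
  cd <- colData(x)
  df <- data.frame(gene_id = colnames(x), chrom = cd$chrom,
                   strand = cd$strand, tss = cd$tss, tts = cd$tts,
                   fv, check.names = FALSE)
  colnames(df)[-(1:5)] <- paste0("bin", seq_len(ncol(fv)))
  df$label <- geneLabels(x)
  if (!is.null(cd$tpm)) df$tpm <- cd$tpm
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(roles = binRoles(x), scaling = metadata(x)$scaling)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a FeatureMatrix written by [writeFeatureMatrix()]
#' @param path TSV path (the sidecar `<path>.json` must sit next to it).
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  binCols <- grep("^bin[0-9]+$", colnames(df), value = TRUE)
  m <- t(as.matrix(df[, binCols]))
  colnames(m) <- df$gene_id
  rownames(m) <- NULL
  cd <- DataFrame(gene_id = df$gene_id, chrom = df$chrom,
                  strand = df$strand, tss = df$tss, tts = df$tts,
                  row.names = df$gene_id)
  if ("label" %in% colnames(df) && !all(is.na(df$label)))
    cd$label <- df$label
  if ("tpm" %in% colnames(df)) cd$tpm <- df$tpm
  se <- SummarizedExperiment(
    assays = list(enrichment = m),
    rowData = DataFrame(role = side$roles, bin = seq_along(side$roles)),
    colData = cd)
  out <- new("FeatureMatrix", se)
  if (!is.null(side$scaling) && length(side$scaling))
    metadata(out)$scaling <- side$scaling
  out
}
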