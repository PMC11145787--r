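#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData colData<-
#' @importFrom Matrix Matrix sparseMatrix t rowSums colSums
NULL

#' Coverage track with library depth
#'
#' A per-base read-coverage signal stored as a run-length encoded list
#' (one `Rle` per chromosome) together with the library depth used for
#' RPKM normalization.
#'
#' @slot coverage An [IRanges::RleList] of nonnegative per-base values.
#' @slot totalMapped Library depth (mapped reads) used as the RPKM
#'   denominator; must be a single positive number.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(coverage = "RleList", totalMapped = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- NULL
  if (length(object@totalMapped) != 1L || !is.finite(object@totalMapped) ||
      object@totalMapped <= 0)
    msg <- c(msg, "totalMapped must be a single positive number")
  if (length(object@coverage) > 0) {
    mins <- vapply(object@coverage,
                   function(r) if (length(r)) min(r) else 0, numeric(1))
    if (any(mins < 0)) msg <- c(msg, "coverage values must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-gene binned 5hmC feature matrix
#'
#' Wraps a [SummarizedExperiment::SummarizedExperiment] holding one
#' `"enrichment"` assay of bins (rows) by genes (columns). Row metadata
#' records each bin's role in the layout (upstream flank, promoter,
#' gene body, downstream flank); column metadata carries the gene
#' identity and, when labeled, the High/Low expression state and TPM.
#' Standardization statistics (per-bin center/scale frozen on the
#' training genes) live in `metadata(x)$scaling`.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (!"enrichment" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'enrichment' is required")
  if (!"role" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'role' is required")
  if (anyNA(assay(object, "enrichment")))
    msg <- c(msg, "feature values must not contain missing values")
  if ("label" %in% colnames(colData(object))) {
    lab <- colData(object)$label
    if (!all(lab[!is.na(lab)] %in% c("High", "Low")))
      msg <- c(msg, "labels must be 'High' or 'Low'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Sparse symmetric Hi-C contact map at fixed resolution
#'
#' @slot chrom Chromosome name.
#' @slot binSize Bin width in bp (default 10,000 elsewhere).
#' @slot mat Sparse symmetric nonnegative matrix of contact values.
#' @slot balanced Whether ICE balancing has been applied.
#' @slot distNormalized Whether diagonal-median distance normalization
#'   has been applied.
#' @slot bias ICE bias vector (length = number of bins) or empty.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(chrom = "character", binSize = "numeric",
                 mat = "Matrix", balanced = "logical",
                 distNormalized = "logical", bias = "numeric"))

setValidity("ContactMap", function(object) {
  msg <- NULL
  m <- object@mat
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (length(m@x) && min(m@x) < -1e-12) msg <- c(msg, "values must be >= 0")
  asym <- max(abs(m - Matrix::t(m)))
  if (asym > 1e-8) msg <- c(msg, sprintf("matrix asymmetry %.3g > 1e-8", asym))
  if (length(object@bias) && length(object@bias) != nrow(m))
    msg <- c(msg, "bias length must match bin count")
  if (is.null(msg)) TRUE else msg
})

#' Genome graph of 10 kb windows for graph-convolutional training
#'
#' Nodes are fixed-width windows tiling each chromosome, carrying
#' normalized 5hmC IP and input signal. Edges come from the top-k
#' contact graph. Nodes containing at least one gene TSS are "masked"
#' (labeled usable) and split 70/15/15 into train/validation/test.
#'
#' @slot nodes A [S4Vectors::DataFrame] with columns `chrom`, `bin`,
#'   `start`, `ip`, `input`, `label`, `mask`, `fold`.
#' @slot edges Two-column integer matrix of undirected edges (1-based
#'   node indices, smaller index first).
#' @slot binSize Window width in bp.
#' @exportClass GenomeGraph
setClass("GenomeGraph",
  representation(nodes = "DataFrame", edges = "matrix", binSize = "numeric"))

setValidity("GenomeGraph", function(object) {
  msg <- NULL
  need <- c("chrom", "bin", "start", "ip", "input", "label", "mask", "fold")
  if (!all(need %in% colnames(object@nodes)))
    msg <- c(msg, paste("nodes must have columns:", paste(need, collapse = ", ")))
  e <- object@edges
  if (length(e)) {
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else {
      if (max(e) > nrow(object@nodes) || min(e) < 1L)
        msg <- c(msg, "edge endpoints out of node range")
      if (any(e[, 1] == e[, 2])) msg <- c(msg, "self loops are not allowed")
    }
  }
  if (is.null(msg)) {
    nd <- object@nodes
    if (any(!is.na(nd$label) & !nd$mask))
      msg <- c(msg, "only masked nodes may carry labels")
  }
  if (is.null(msg)) TRUE else msg
})

#' Fully connected neural classifier (sigmoid output)
#'
#' Weights of a rectifier multilayer perceptron trained with Adam on
#' binary cross-entropy; scores are interpreted as P(High).
#'
#' @slot weights List with per-layer `W` (in x out) and `b`.
#' @slot config Training configuration (layer widths, learning rate,
#'   dropout, epochs, minibatch size, seed).
#' @exportClass MLPClassifier
setClass("MLPClassifier", representation(weights = "list", config = "list"))

#' GraphSAGE node classifier
#'
#' Mean-aggregator graph convolutions (concatenated self and
#' neighbor-mean, affine map, rectifier) followed by a dropout MLP
#' head, trained on masked nodes only.
#'
#' @slot weights List of conv-layer and head-layer weights.
#' @slot config Training configuration.
#' @exportClass SageClassifier
setClass("SageClassifier", representation(weights = "list", config = "list"))

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack across", length(object@coverage), "chromosome(s);",
      "totalMapped =", format(object@totalMapped, big.mark = ","), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  lab <- if ("label" %in% colnames(colData(object)))
    sum(!is.na(colData(object)$label)) else 0L
  cat("FeatureMatrix:", nrow(object), "bins x", ncol(object), "genes (",
      lab, "labeled );",
      if (is.null(metadata(object)$scaling)) "unstandardized" else "standardized",
      "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap %s: %d bins @ %g bp, %d nonzero; balanced=%s, distNormalized=%s\n",
      object@chrom, nrow(object@mat), object@binSize,
      length(object@mat@x), object@balanced, object@distNormalized))
})

setMethod("show", "GenomeGraph", function(object) {
  cat(sprintf("GenomeGraph: %d nodes (%d masked), %d undirected edges, binSize=%g\n",
      nrow(object@nodes), sum(object@nodes$mask), nrow(object@edges),
      object@binSize))
})

setMethod("show", "MLPClassifier", function(object) {
  widths <- vapply(object@weights, function(l) ncol(l$W), integer(1))
  cat("MLPClassifier with layer widths:", paste(widths, collapse = " -> "), "\n")
})

setMethod("show", "SageClassifier", function(object) {
  cat("SageClassifier:", object@config$convLayers, "conv layer(s), hidden",
      object@config$hidden, "\n")
})
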