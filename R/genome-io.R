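#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- start<- end<- strand<- reduce findOverlaps countOverlaps
#'   resize coverage
#' @importFrom IRanges IRanges Views viewSums RleList subsetByOverlaps
#' @importFrom S4Vectors Rle queryHits subjectHits runValue runLength
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- keepSeqlevels
NULL

#' Load gene models from GTF or BED
#'
#' Reads a gene annotation (GTF/GFF or BED6/BED12) and returns a
#' gene-level [GenomicRanges::GRanges] with a `gene_id` metadata
#' column. Genes spanning multiple transcripts are collapsed to their
#' gene-level span (minimum start to maximum end). Genes whose length
#' is not strictly greater than `minLength` are dropped, mirroring the
#' usual exclusion of sub-kilobase genes from gene-body binning.
#'
#' @param path Annotation file; format chosen by extension
#'   (`.gtf`/`.gff`/`.gff3` vs `.bed`/`.narrowPeak`).
#' @param minLength Minimum gene length in bp (exclusive; default 1000).
#' @return `GRanges` with unique `gene_id`, strand recorded.
#' @export
loadGeneModels <- function(path, minLength = 1000) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  isGtf <- grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE)
  gr <- tryCatch({
    if (isGtf) rtracklayer::import(path, format = "gtf")
    else rtracklayer::import(path, format = "bed")
  }, error = function(e) stop("failed to parse ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (isGtf) {
    if (!"gene_id" %in% colnames(mcols(gr)))
      stop("GTF lacks gene_id attribute")
    # gene-level span per gene_id (collapse transcripts/exons)
    gid <- mcols(gr)$gene_id
    first <- !duplicated(gid)
    ids <- gid[first]
    starts <- tapply(start(gr), gid, min)[ids]
    ends <- tapply(end(gr), gid, max)[ids]
    genes <- GRanges(as.character(seqnames(gr))[first],
                     IRanges(as.integer(starts), as.integer(ends)),
                     strand = as.character(strand(gr))[first],
                     gene_id = ids)
  } else {
    if (!"name" %in% colnames(mcols(gr)))
      stop("BED lacks a name column for gene_id")
    genes <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                     strand = strand(gr), gene_id = mcols(gr)$name)
  }
  names(genes) <- NULL
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  genes[width(genes) > minLength]
}

#' Write gene models to BED6
#' @param genes A `GRanges` with `gene_id`.
#' @param path Output path.
#' @export
writeGeneModels <- function(genes, path) {
  out <- genes
  mcols(out) <- NULL
  out$name <- genes$gene_id
  out$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Transcription start / termination sites
#'
#' TSS is the 5' end of the gene (start on `+`, end on `-`); TTS the
#' 3' end. Positions are 1-based genomic coordinates.
#' @param genes `GRanges` of gene models.
#' @return Integer vector of positions.
#' @export
tssOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' @rdname tssOf
#' @export
ttsOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

#' Construct a CoverageTrack
#'
#' @param coverage An `RleList` of per-base values, or a `GRanges` with
#'   a `score` column (interval values are expanded to per-base
#'   coverage weighted by score, the bedGraph convention).
#' @param totalMapped Library depth in reads. If missing and a GRanges
#'   is given, defaults to the summed score-weighted bases / 50 (a
#'   50 bp read-length proxy); pass the real depth when known.
#' @param seqlens Optional named chromosome lengths (bp) used to pad
#'   the coverage to full chromosome length.
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(coverage, totalMapped = NULL, seqlens = NULL) {
  if (is(coverage, "GRanges")) {
    gr <- coverage
    if (!is.null(seqlens)) seqlengths(gr)[names(seqlens)] <- seqlens
    w <- if ("score" %in% colnames(mcols(gr))) gr$score else rep(1, length(gr))
    if (is.null(totalMapped))
      totalMapped <- max(1, sum(as.numeric(w) * width(gr)) / 50)
    coverage <- coverage(gr, weight = w)
  }
  if (is.null(totalMapped))
    stop("totalMapped is required when coverage is given as an RleList")
  new("CoverageTrack", coverage = coverage, totalMapped = totalMapped)
}

#' Read a bedGraph file into a CoverageTrack
#' @param path bedGraph path.
#' @param totalMapped Library depth in reads (optional, see
#'   [CoverageTrack()]).
#' @export
readBedGraph <- function(path, totalMapped = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  CoverageTrack(gr, totalMapped = totalMapped)
}

#' Library depth of a track
#' @param track A `CoverageTrack`.
#' @export
totalMapped <- function(track) track@totalMapped

#' Summed per-base signal over intervals
#'
#' Sums coverage value x overlapped bases for each query interval.
#' Intervals extending past the covered region are clipped and the
#' missing portion contributes 0.
#'
#' @param track A [CoverageTrack-class].
#' @param intervals A `GRanges` of query intervals.
#' @return Numeric vector of summed signal, one per interval.
#' @export
regionSignal <- function(track, intervals) {
  chroms <- as.character(seqnames(intervals))
  unknown <- setdiff(unique(chroms), names(track@coverage))
  if (length(unknown))
    stop("unknown chromosome(s) in track: ", paste(unknown, collapse = ", "))
  out <- numeric(length(intervals))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    rle <- track@coverage[[ch]]
    n <- length(rle)
    s <- pmax(start(intervals)[idx], 1L)
    e <- pmin(end(intervals)[idx], n)
    ok <- s <= e & n > 0L
    if (any(ok)) {
      v <- Views(rle, start = s[ok], end = e[ok])
      out[idx[ok]] <- viewSums(v)
    }
  }
  out
}

#' Remove intervals overlapping a blacklist
#'
#' Any interval with at least 1 bp of overlap with a blacklist region
#' is dropped entirely; intervals merely touching a blacklist region
#' end-to-end are kept.
#'
#' @param intervals,blacklist `GRanges` interval sets.
#' @return Filtered `GRanges`.
#' @export
excludeBlacklist <- function(intervals, blacklist) {
  if (length(blacklist) == 0L) return(intervals)
  hits <- countOverlaps(intervals, blacklist, minoverlap = 1L,
                        ignore.strand = TRUE)
  intervals[hits == 0L]
}

#' Read narrowPeak peak calls
#'
#' Returns peaks as `GRanges` with `score`, `signalValue` and an
#' absolute `summit` position (peak start + 10th-column offset).
#'
#' @param path narrowPeak file.
#' @export
readNarrowPeak <- function(path) {
  cols <- c("character", "integer", "integer", "character", "numeric",
            "character", "numeric", "numeric", "numeric", "integer")
  df <- utils::read.table(path, sep = "\t", colClasses = cols,
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "signalValue", "pValue", "qValue", "peak"))
  if (any(df$peak < 0 | df$peak >= df$end - df$start))
    stop("summit offset outside its peak interval")
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                score = df$score, signalValue = df$signalValue,
                summit = df$start + df$peak + 1L, name = df$name)
  gr
}

#' Write peaks as narrowPeak
#' @param peaks `GRanges` with `score`, `signalValue`, `summit`.
#' @param path Output path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = if (!is.null(peaks$name)) peaks$name
                          else paste0("peak_", seq_along(peaks)),
                   score = peaks$score, strand = ".",
                   signalValue = peaks$signalValue, pValue = -1, qValue = -1,
                   peak = peaks$summit - start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene expression table (gene_id, TPM columns)
#'
#' @param path TSV with a `gene_id` column and one numeric TPM column
#'   per sample.
#' @return data.frame with rownames = gene_id.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(df)) stop("expression table needs gene_id")
  rownames(df) <- df$gene_id
  df$gene_id <- NULL
  if (any(as.matrix(df) < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  df
}
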