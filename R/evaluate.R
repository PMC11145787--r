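#' Ranking and threshold metrics for High/Low prediction
#'
#' AUC is the mid-rank (Mann-Whitney) statistic, equal to the
#' probability that a random High gene outranks a random Low gene
#' (ties counted half). AUPR uses step interpolation of the
#' precision-recall curve. F1 and accuracy are computed at the score
#' threshold with High as the positive class.
#'
#' @param scores Numeric scores, higher = more likely High.
#' @param labels "High"/"Low" (or logical/0-1 with TRUE/1 = High).
#' @param threshold Score cutoff for the hard metrics.
#' @return List with `auc`, `aupr`, `f1`, `accuracy`, `n`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  y <- normalizeLabels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  aupr <- auprStep(scores, y)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  acc <- mean(pred == y)
  list(auc = auc, aupr = aupr, f1 = f1, accuracy = acc, n = length(y))
}

normalizeLabels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("High", "Low"))
    if (length(bad)) stop("labels must be High/Low, got: ",
                          paste(bad, collapse = ", "))
    labels == "High"
  } else as.logical(labels)
}

# Step-interpolated average precision: sum over recall increments of
# the precision at that point, walking scores in decreasing order.
auprStep <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  # evaluate at distinct-score boundaries so ties are handled as a block
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Fit an off-the-shelf baseline classifier
#'
#' Logistic regression (`stats::glm`), random forest
#' (`randomForest::randomForest`) or a support vector machine
#' (`e1071::svm`), each at package defaults, on the feature matrix.
#' Returns an object with a `predictScores(model, features)` score per
#' gene (probability of High for logistic/forest, decision value for
#' the SVM).
#'
#' @param kind One of "logistic", "random_forest", "svm".
#' @param features Genes x bins numeric matrix.
#' @param labels "High"/"Low" per gene.
#' @param seed RNG seed (random forest is stochastic).
#' @return A classifier object of class `hmcBaseline`.
#' @export
fitBaseline <- function(kind = c("logistic", "random_forest", "svm"),
                        features, labels, seed = 1) {
  kind <- match.arg(kind)
  y <- normalizeLabels(labels)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  fit <- withSeed(seed, switch(kind,
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, features), y, family = stats::binomial())),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("randomForest package required")
      randomForest::randomForest(features, factor(y, c(FALSE, TRUE)))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("e1071 package required")
      e1071::svm(features, factor(y, c(FALSE, TRUE)))
    }))
  structure(list(kind = kind, fit = fit), class = "hmcBaseline")
}

#' Scores from a fitted baseline
#' @param model An `hmcBaseline` object.
#' @param features Genes x bins matrix.
#' @return Numeric score per gene (higher = more likely High).
#' @export
predictScores <- function(model, features) {
  switch(model$kind,
    logistic = as.numeric(sigmoid(cbind(1, features) %*% model$fit$coefficients)),
    random_forest = as.numeric(
      stats::predict(model$fit, features, type = "prob")[, "TRUE"]),
    svm = {
      dv <- attr(stats::predict(model$fit, features, decision.values = TRUE),
                 "decision.values")
      # decision values are signed toward the first class in the
      # colname ("A/B": positive = A); orient so higher means High
      if (startsWith(colnames(dv)[1], "TRUE")) as.numeric(dv)
      else -as.numeric(dv)
    })
}

#' Majority-vote memorization baseline
#'
#' Predicts, for each gene, the label held by a strict majority of
#' the training samples (the held-out sample is excluded from the
#' vote). An exact tie predicts High (fixed convention).
#'
#' @param labelTable Gene x sample matrix/data.frame of "High"/"Low".
#' @param heldOut Column name or index of the held-out sample.
#' @param genes Genes to predict (default all rows); a gene absent
#'   from the table is an error.
#' @return Named character vector of predicted labels.
#' @export
majorityVotePredict <- function(labelTable, heldOut, genes = rownames(labelTable)) {
  labelTable <- as.matrix(labelTable)
  if (ncol(labelTable) < 2L) stop("need at least 2 samples")
  missing <- setdiff(genes, rownames(labelTable))
  if (length(missing)) stop("gene absent from label table: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (is.character(heldOut)) heldOut <- match(heldOut, colnames(labelTable))
  train <- labelTable[genes, -heldOut, drop = FALSE]
  nHigh <- rowSums(train == "High")
  out <- ifelse(nHigh >= ncol(train) / 2, "High", "Low")
  names(out) <- genes
  out
}

#' Accuracy per expression quartile
#'
#' Ranks test genes by TPM, splits them into four groups (Q4 = top
#' 25%; remainders go to the lower quartiles) and reports the
#' prediction accuracy within each.
#'
#' @param predicted,observed "High"/"Low" vectors.
#' @param tpm TPM per gene (same order).
#' @return Numeric length-4 vector `Q1`..`Q4`.
#' @export
quartileAccuracy <- function(predicted, observed, tpm) {
  n <- length(tpm)
  if (n < 4L) stop("need at least 4 genes")
  o <- order(tpm)
  base <- n %/% 4L; extra <- n %% 4L
  sizes <- rep(base, 4L) + c(extra >= 1, extra >= 2, extra >= 3, 0)
  grp <- rep(1:4, sizes)
  acc <- vapply(1:4, function(q) {
    idx <- o[grp == q]
    mean(predicted[idx] == observed[idx])
  }, numeric(1))
  names(acc) <- paste0("Q", 1:4)
  acc
}

#' Genes with variable expression state across samples
#'
#' Selects genes whose minority (underrepresented) label covers at
#' least `minMinorFraction` of the samples; with `minMinorFraction`
#' near 0 this returns every gene with any label variation.
#'
#' @param labelTable Gene x sample matrix of "High"/"Low".
#' @param minMinorFraction Minimum minority-label fraction (default 1/3).
#' @return Character vector of gene ids.
#' @export
variableGeneSubset <- function(labelTable, minMinorFraction = 1/3) {
  labelTable <- as.matrix(labelTable)
  nHigh <- rowSums(labelTable == "High")
  minor <- pmin(nHigh, ncol(labelTable) - nHigh) / ncol(labelTable)
  rownames(labelTable)[minor >= minMinorFraction & minor > 0]
}

#' CpG dinucleotide density in a gene promoter
#'
#' Counts "CG" dinucleotides in the promoter window (TSS +/- `flank`,
#' clipped at chromosome ends) divided by the window length.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or object
#'   subsettable by chromosome) of chromosome sequences.
#' @param gene Length-1 `GRanges` gene model.
#' @param flank Half-window around the TSS in bp (default 1000).
#' @return CpG density in [0, 0.5].
#' @export
promoterCpgContent <- function(genome, gene, flank = 1000) {
  ch <- as.character(seqnames(gene))
  if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
  seq <- genome[[ch]]
  t0 <- tssOf(gene)
  s <- max(1L, t0 - flank)
  e <- min(length(seq), t0 + flank)
  win <- Biostrings::subseq(seq, s, e)
  Biostrings::countPattern("CG", win) / length(win)
}
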