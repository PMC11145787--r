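#' Configuration for the fully connected expression classifier
#'
#' Defaults follow the tuned architecture: hidden layers of 200, 100
#' and 50 rectifier units feeding a single sigmoid output, learning
#' rate 1e-4, hidden dropout 0.15, minibatch 128, 40 epochs for a
#' single-sample model (use 60 for a combined multi-sample model).
#'
#' @param hidden Hidden layer widths.
#' @param lr Adam learning rate.
#' @param dropout Dropout probability in hidden layers, in [0, 1).
#' @param epochs Training epochs (final-epoch weights are kept).
#' @param minibatch Minibatch size.
#' @param seed Seed covering weight init, dropout masks and shuffling.
#' @return A config list.
#' @export
mlpConfig <- function(hidden = c(200, 100, 50), lr = 1e-4, dropout = 0.15,
                      epochs = 40, minibatch = 128, seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1, minibatch >= 1)
  list(hidden = hidden, lr = lr, dropout = dropout, epochs = epochs,
       minibatch = minibatch, seed = seed)
}

mlpInit <- function(inputWidth, hidden) {
  widths <- c(inputWidth, hidden, 1L)
  lapply(seq_len(length(widths) - 1L), function(i) {
    fanIn <- widths[i]
    list(W = matrix(stats::rnorm(fanIn * widths[i + 1L], 0,
                                 sqrt(2 / fanIn)),
                    fanIn, widths[i + 1L]),
         b = numeric(widths[i + 1L]))
  })
}

mlpForward <- function(weights, X, dropout = 0, training = FALSE) {
  L <- length(weights)
  acts <- vector("list", L + 1L); acts[[1L]] <- X
  masks <- vector("list", L)
  H <- X
  for (i in seq_len(L)) {
    Z <- sweep(H %*% weights[[i]]$W, 2, weights[[i]]$b, `+`)
    if (i < L) {
      H <- relu(Z)
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                    nrow(H), ncol(H))
        H <- H * m
        masks[[i]] <- m
      }
    } else {
      H <- Z  # logits
    }
    acts[[i + 1L]] <- H
  }
  list(logits = H, acts = acts, masks = masks)
}

#' Train the rectifier MLP expression classifier
#'
#' Binary cross-entropy on a sigmoid output, optimized with Adam;
#' deterministic given the config seed (weight initialization, dropout
#' masks and minibatch shuffling all draw from it).
#'
#' @param features Genes x bins numeric matrix (standardized).
#' @param labels "High"/"Low" per gene.
#' @param config From [mlpConfig()].
#' @return An [MLPClassifier-class].
#' @export
trainMLP <- function(features, labels, config = mlpConfig()) {
  X <- as.matrix(features)
  y <- as.numeric(normalizeLabels(labels))
  if (nrow(X) == 0L) stop("empty training fold")
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  withSeed(config$seed, {
    weights <- mlpInit(ncol(X), config$hidden)
    L <- length(weights)
    mState <- lapply(weights, function(w)
      list(W = 0 * w$W, b = 0 * w$b))
    vState <- mState
    t <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    curve <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      lossSum <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$minibatch))) {
        Xb <- X[bs, , drop = FALSE]; yb <- y[bs]
        fw <- mlpForward(weights, Xb, config$dropout, training = TRUE)
        p <- sigmoid(fw$logits)
        loss <- -mean(yb * log(pmax(p, 1e-12)) +
                      (1 - yb) * log(pmax(1 - p, 1e-12)))
        if (!is.finite(loss))
          stop("NaN/Inf loss at epoch ", ep, "; inspect feature scaling")
        lossSum <- lossSum + loss * length(bs)
        # backprop
        grads <- vector("list", L)
        delta <- (p - yb) / length(bs)      # dL/dlogit
        for (i in L:1) {
          H <- fw$acts[[i]]
          grads[[i]] <- list(W = crossprod(H, delta),
                             b = colSums(delta))
          if (i > 1L) {
            delta <- delta %*% t(weights[[i]]$W)
            if (!is.null(fw$masks[[i - 1L]])) delta <- delta * fw$masks[[i - 1L]]
            delta <- delta * (fw$acts[[i]] > 0)
          }
        }
        t <- t + 1L
        for (i in seq_len(L)) {
          for (nm in c("W", "b")) {
            g <- grads[[i]][[nm]]
            mState[[i]][[nm]] <- b1 * mState[[i]][[nm]] + (1 - b1) * g
            vState[[i]][[nm]] <- b2 * vState[[i]][[nm]] + (1 - b2) * g^2
            mh <- mState[[i]][[nm]] / (1 - b1^t)
            vh <- vState[[i]][[nm]] / (1 - b2^t)
            weights[[i]][[nm]] <- weights[[i]][[nm]] -
              config$lr * mh / (sqrt(vh) + eps)
          }
        }
      }
      curve[ep] <- lossSum / n
    }
    cfg <- config
    cfg$inputWidth <- ncol(X)
    cfg$trainingCurve <- curve
    new("MLPClassifier", weights = weights, config = cfg)
  })
}

#' Scores from a trained MLP classifier
#' @param model An `MLPClassifier`.
#' @param features Genes x bins matrix with the model's input width.
#' @return P(High) per gene, strictly inside (0, 1).
#' @export
predictMLP <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != model@config$inputWidth)
    stop("feature width ", ncol(X), " does not match model input ",
         model@config$inputWidth)
  as.numeric(sigmoid(mlpForward(model@weights, X)$logits))
}

# Pre-sigmoid logits (used by the attribution module).
mlpLogits <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != model@config$inputWidth) stop("feature width mismatch")
  as.numeric(mlpForward(model@weights, X)$logits)
}

#' Chromosome hold-out split schedule
#'
#' Builds the leave-one-chromosome-out schedule: one entry per
#' chromosome as the test chromosome, paired with a randomly drawn
#' validation chromosome such that no chromosome appears twice in
#' either role and test differs from validation within every entry
#' (a seeded derangement).
#'
#' @param chromosomes Character vector (e.g. the 19 mouse autosomes).
#' @param seed RNG seed.
#' @return data.frame with columns `test`, `val`.
#' @export
makeSplitSchedule <- function(chromosomes, seed = 1) {
  n <- length(chromosomes)
  if (n < 2L) stop("need at least 2 chromosomes")
  withSeed(seed, {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    data.frame(test = chromosomes, val = chromosomes[p],
               stringsAsFactors = FALSE)
  })
}

#' Assign genes to train/val/test folds by held-out chromosome
#' @param x A `FeatureMatrix`.
#' @param testChrom,valChrom Held-out chromosome names.
#' @return List of integer indices `train`, `val`, `test`.
#' @export
chromosomeFolds <- function(x, testChrom = "chr4", valChrom = "chr5") {
  ch <- colData(x)$chrom
  if (!any(ch == testChrom)) stop("no genes on test chromosome ", testChrom)
  list(train = which(!ch %in% c(testChrom, valChrom)),
       val = which(ch == valChrom),
       test = which(ch == testChrom))
}

#' Train an expression classifier with chromosome hold-out
#'
#' Accepts one labeled [FeatureMatrix-class] or a list of them (one
#' per sample, the "combined" setting). For every sample the same
#' test and validation chromosomes are withheld, each sample is
#' standardized on its own training genes, and training genes from
#' all samples are concatenated.
#'
#' @param fms A labeled `FeatureMatrix` or list of them.
#' @param testChrom,valChrom Held-out chromosomes (defaults chr4/chr5).
#' @param config From [mlpConfig()].
#' @return List with the `MLPClassifier` (`model`), the fold indices
#'   and standardized matrices per sample, and `testChrom`/`valChrom`.
#' @export
trainFcdnn <- function(fms, testChrom = "chr4", valChrom = "chr5",
                       config = mlpConfig()) {
  if (is(fms, "FeatureMatrix")) fms <- list(fms)
  samples <- lapply(fms, function(fm) {
    folds <- chromosomeFolds(fm, testChrom, valChrom)
    if (length(folds$train) == 0L) stop("empty training fold")
    if (is.null(metadata(fm)$scaling))
      fm <- standardizeFeatures(fm, folds$train)
    list(features = featureValues(fm), labels = geneLabels(fm),
         tpm = colData(fm)$tpm, folds = folds)
  })
  X <- do.call(rbind, lapply(samples, function(s)
    s$features[s$folds$train, , drop = FALSE]))
  y <- unlist(lapply(samples, function(s) s$labels[s$folds$train]))
  model <- trainMLP(X, y, config)
  list(model = model, samples = samples,
       testChrom = testChrom, valChrom = valChrom)
}

#' Evaluate a chromosome-hold-out fit on its test fold
#'
#' Concatenates test-chromosome genes across samples (optionally a
#' subset of held-out samples, the leave-samples-out protocol) and
#' computes ranking metrics.
#'
#' @param fit Result of [trainFcdnn()].
#' @param which Integer indices of the samples to evaluate (default
#'   all).
#' @param fold Which fold to score ("test" or "val").
#' @return [evaluate()] report plus the raw `scores` and `labels`.
#' @export
evaluateFcdnn <- function(fit, which = seq_along(fit$samples), fold = "test") {
  scores <- numeric(0); labels <- character(0); tpms <- numeric(0)
  for (s in fit$samples[which]) {
    idx <- s$folds[[fold]]
    scores <- c(scores, predictMLP(fit$model, s$features[idx, , drop = FALSE]))
    labels <- c(labels, s$labels[idx])
    tpms <- c(tpms, if (!is.null(s$tpm)) s$tpm[idx] else rep(NA_real_, length(idx)))
  }
  rep <- evaluate(scores, labels)
  rep$scores <- scores; rep$labels <- labels; rep$tpm <- tpms
  rep
}
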