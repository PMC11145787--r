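#' Configuration for the GraphSAGE node classifier
#'
#' Mean-aggregator graph convolutions (self and neighbor-mean
#' features concatenated into an affine map, rectifier activation)
#' followed by a three-layer multilayer-perceptron head with 50%
#' dropout in its hidden layers.
#'
#' @param convLayers Number of graph convolutions (default 2).
#' @param hidden Convolution output width (default 128).
#' @param headWidths Hidden widths of the MLP head (output is 1).
#' @param dropout Head dropout probability.
#' @param epochs Full-batch Adam epochs.
#' @param lr Learning rate.
#' @param seed RNG seed (init, dropout, fold-invariant).
#' @export
sageConfig <- function(convLayers = 2, hidden = 128, headWidths = c(64, 32),
                       dropout = 0.5, epochs = 200, lr = 1e-3, seed = 1) {
  stopifnot(convLayers >= 1, dropout >= 0, dropout < 1)
  list(convLayers = convLayers, hidden = hidden, headWidths = headWidths,
       dropout = dropout, epochs = epochs, lr = lr, seed = seed)
}

# Row-normalized (mean) aggregation operator from an undirected edge
# matrix: A[v, u] = 1/deg(v) for each neighbor u of v.
meanAggregator <- function(edges, n) {
  if (!length(edges)) return(Matrix::sparseMatrix(i = integer(0),
    j = integer(0), x = numeric(0), dims = c(n, n)))
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  deg <- tabulate(i, n)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
}

sageInit <- function(inWidth, config) {
  widths <- c(inWidth, rep(config$hidden, config$convLayers))
  conv <- lapply(seq_len(config$convLayers), function(l) {
    fi <- widths[l]
    list(Wself = matrix(stats::rnorm(fi * widths[l + 1], 0, sqrt(2 / fi)),
                        fi, widths[l + 1]),
         Wneigh = matrix(stats::rnorm(fi * widths[l + 1], 0, sqrt(2 / fi)),
                         fi, widths[l + 1]),
         b = numeric(widths[l + 1]))
  })
  hw <- c(config$hidden, config$headWidths, 1L)
  head <- lapply(seq_len(length(hw) - 1L), function(l) {
    list(W = matrix(stats::rnorm(hw[l] * hw[l + 1], 0, sqrt(2 / hw[l])),
                    hw[l], hw[l + 1]),
         b = numeric(hw[l + 1]))
  })
  list(conv = conv, head = head)
}

# Forward pass over all nodes; A is the mean-aggregation operator.
sageForward <- function(weights, X, A, dropout = 0, training = FALSE) {
  H <- X
  convActs <- list(H)
  aggs <- list()
  for (l in seq_along(weights$conv)) {
    w <- weights$conv[[l]]
    agg <- as.matrix(A %*% H)
    Z <- sweep(H %*% w$Wself + agg %*% w$Wneigh, 2, w$b, `+`)
    H <- relu(Z)
    aggs[[l]] <- agg
    convActs[[l + 1L]] <- H
  }
  headActs <- list(H)
  masks <- list()
  nHead <- length(weights$head)
  for (l in seq_len(nHead)) {
    w <- weights$head[[l]]
    Z <- sweep(headActs[[l]] %*% w$W, 2, w$b, `+`)
    if (l < nHead) {
      Hh <- relu(Z)
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(Hh), 1, 1 - dropout) / (1 - dropout),
                    nrow(Hh), ncol(Hh))
        Hh <- Hh * m
        masks[[l]] <- m
      }
      headActs[[l + 1L]] <- Hh
    } else headActs[[l + 1L]] <- Z
  }
  list(logits = as.numeric(headActs[[nHead + 1L]]),
       convActs = convActs, aggs = aggs, headActs = headActs, masks = masks)
}

#' Train the GraphSAGE expression-state classifier
#'
#' Full-batch Adam on binary cross-entropy restricted to train-fold
#' masked nodes. Deterministic given the config seed.
#'
#' @param graph A [GenomeGraph-class].
#' @param config From [sageConfig()].
#' @return A [SageClassifier-class].
#' @export
trainSage <- function(graph, config = sageConfig()) {
  nodes <- graph@nodes
  X <- cbind(nodes$ip, nodes$input)
  n <- nrow(X)
  A <- meanAggregator(graph@edges, n)
  trainIdx <- which(!is.na(nodes$fold) & nodes$fold == "train")
  if (!length(trainIdx)) stop("empty training fold")
  y <- nodes$label[trainIdx] == "High"
  if (length(unique(y)) < 2L) stop("training fold must contain both classes")
  y <- as.numeric(y)
  withSeed(config$seed, {
    weights <- sageInit(ncol(X), config)
    opt <- adamInitTree(weights)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    for (ep in seq_len(config$epochs)) {
      fw <- sageForward(weights, X, A, config$dropout, training = TRUE)
      p <- sigmoid(fw$logits[trainIdx])
      loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
      if (!is.finite(loss)) stop("NaN/Inf loss at epoch ", ep)
      grads <- sageBackward(weights, fw, A, trainIdx, p - y)
      t <- t + 1L
      upd <- adamStepTree(weights, grads, opt, config$lr, b1, b2, eps, t)
      weights <- upd$weights; opt <- upd$opt
    }
    cfg <- config
    cfg$inputWidth <- ncol(X)
    new("SageClassifier", weights = weights, config = cfg)
  })
}

# dLogit: d(loss)/d(logit) on the loss nodes (already averaged).
sageBackward <- function(weights, fw, A, lossIdx, residual) {
  n <- nrow(fw$convActs[[1]])
  nHead <- length(weights$head)
  dLogit <- numeric(n)
  dLogit[lossIdx] <- residual / length(lossIdx)
  grads <- list(conv = vector("list", length(weights$conv)),
                head = vector("list", nHead))
  delta <- matrix(dLogit, n, 1)
  for (l in nHead:1) {
    Hin <- fw$headActs[[l]]
    grads$head[[l]] <- list(W = crossprod(Hin, delta), b = colSums(delta))
    delta <- delta %*% t(weights$head[[l]]$W)
    if (l > 1L) {
      if (length(fw$masks) >= l - 1L && !is.null(fw$masks[[l - 1L]]))
        delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * (fw$headActs[[l]] > 0)
    }
  }
  # delta is now dL/d(top conv output)
  for (l in length(weights$conv):1) {
    delta <- delta * (fw$convActs[[l + 1L]] > 0)
    Hin <- fw$convActs[[l]]
    agg <- fw$aggs[[l]]
    grads$conv[[l]] <- list(Wself = crossprod(Hin, delta),
                            Wneigh = crossprod(agg, delta),
                            b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(weights$conv[[l]]$Wself) +
        as.matrix(Matrix::t(A) %*% (delta %*% t(weights$conv[[l]]$Wneigh)))
    }
  }
  grads
}

# Adam state/step over an arbitrarily nested list of numeric arrays.
adamInitTree <- function(w) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(w), v = zero(w))
}

adamStepTree <- function(w, g, opt, lr, b1, b2, eps, t) {
  step <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- Map(step, w, g, m, v)
      list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- step(w, g, opt$m, opt$v)
  list(weights = out$w, opt = list(m = out$m, v = out$v))
}

#' Scores from a trained GraphSAGE classifier
#'
#' Applies the trained aggregation function to a (possibly different)
#' genome graph with the same node-feature arity — this is also how a
#' model trained on one cell type is applied to another — and returns
#' P(High) for all masked nodes.
#'
#' @param model A [SageClassifier-class].
#' @param graph A [GenomeGraph-class].
#' @return data.frame with node index, fold, label and score for each
#'   masked node.
#' @export
predictSage <- function(model, graph) {
  nodes <- graph@nodes
  X <- cbind(nodes$ip, nodes$input)
  if (ncol(X) != model@config$inputWidth)
    stop("node feature arity mismatch")
  A <- meanAggregator(graph@edges, nrow(X))
  fw <- sageForward(model@weights, X, A, training = FALSE)
  idx <- which(nodes$mask)
  data.frame(node = idx, fold = nodes$fold[idx], label = nodes$label[idx],
             score = sigmoid(fw$logits[idx]))
}
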