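#' Edge-mask explanation of a GraphSAGE prediction
#'
#' Learns a sigmoid-parameterized soft mask over the edges of the
#' target node's k-hop subgraph, minimizing the cross-entropy of the
#' model's own prediction under the masked graph plus a sparsity
#' (L1) and an entropy regularizer on the mask — the edge-mask
#' objective popularized by GNNExplainer. Edges with high learned
#' mask values are the interactions most responsible for the node's
#' predicted label.
#'
#' During optimization the neighbor aggregation becomes a weighted
#' mean with the mask values as weights; gradients with respect to
#' the mask logits are computed analytically through the
#' convolutions.
#'
#' @param model A trained [SageClassifier-class].
#' @param graph The [GenomeGraph-class] the prediction was made on.
#' @param node Target node index (must be masked).
#' @param epochs Mask-optimization epochs (default 200).
#' @param kHop Subgraph radius (default 1).
#' @param alpha L1 (edge-size) regularizer weight.
#' @param beta Mask-entropy regularizer weight.
#' @param lr Adam learning rate for the mask logits.
#' @param seed Seed for the mask initialization.
#' @return List of class `edgeImportance`: `node`, `edges` (subgraph
#'   edge matrix in global indices), `mask` (values in (0,1)),
#'   `lossCurve`, and `prediction` (the explained label).
#' @export
explainNode <- function(model, graph, node, epochs = 200, kHop = 1,
                        alpha = 0.005, beta = 1.0, lr = 0.05, seed = 1) {
  nodes <- graph@nodes
  if (!nodes$mask[node]) stop("node ", node, " is not a masked (gene) node")
  edges <- graph@edges
  # k-hop node set by breadth-first expansion
  nodeSet <- node
  frontier <- node
  for (h in seq_len(kHop)) {
    inc <- edges[, 1] %in% frontier | edges[, 2] %in% frontier
    frontier <- setdiff(unique(c(edges[inc, 1], edges[inc, 2])), nodeSet)
    nodeSet <- c(nodeSet, frontier)
    if (!length(frontier)) break
  }
  sub <- edges[edges[, 1] %in% nodeSet & edges[, 2] %in% nodeSet, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("node ", node, " is isolated; empty importance")
    return(structure(list(node = node,
                          edges = matrix(integer(0), 0, 2),
                          mask = numeric(0), lossCurve = numeric(0),
                          prediction = NA_character_),
                     class = "edgeImportance"))
  }
  # model's own prediction on the full graph is the explained target
  full <- predictSage(model, graph)
  yHat <- as.numeric(full$score[match(node, full$node)] >= 0.5)

  nodeSet <- sort(nodeSet)
  local <- match(c(sub[, 1], sub[, 2]), nodeSet)
  eLocal <- matrix(local, ncol = 2)
  X <- cbind(nodes$ip, nodes$input)[nodeSet, , drop = FALSE]
  target <- match(node, nodeSet)
  nE <- nrow(sub)
  # directed edge list: each undirected edge in both directions
  src <- c(eLocal[, 1], eLocal[, 2])
  dst <- c(eLocal[, 2], eLocal[, 1])
  eid <- rep(seq_len(nE), 2)

  withSeed(seed, {
    theta <- stats::rnorm(nE, 0, 0.1)
    mAd <- numeric(nE); vAd <- numeric(nE)
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    curve <- numeric(epochs)
    for (t in seq_len(epochs)) {
      w <- sigmoid(theta)
      fb <- maskedForwardBackward(model@weights, X, src, dst, eid, w,
                                  target, yHat)
      ent <- -mean(w * log(w) + (1 - w) * log(1 - w))
      curve[t] <- fb$loss + alpha * sum(w) + beta * ent
      dEnt <- -(log(w) - log(1 - w)) / nE    # d entropy / d w
      gW <- fb$gradMask + alpha + beta * dEnt
      gTheta <- gW * w * (1 - w)
      mAd <- b1 * mAd + (1 - b1) * gTheta
      vAd <- b2 * vAd + (1 - b2) * gTheta^2
      theta <- theta - lr * (mAd / (1 - b1^t)) / (sqrt(vAd / (1 - b2^t)) + epsA)
    }
    structure(list(node = node, edges = sub, mask = sigmoid(theta),
                   lossCurve = curve,
                   prediction = if (yHat == 1) "High" else "Low"),
              class = "edgeImportance")
  })
}

# Forward with mask-weighted mean aggregation and analytic gradient of
# the target-node BCE w.r.t. the per-edge mask weights.
maskedForwardBackward <- function(weights, X, src, dst, eid, w, target, y) {
  n <- nrow(X)
  wDir <- w[eid]
  C <- length(weights$conv)
  H <- X
  Hs <- list(H); aggs <- list(); sws <- list(); Zs <- list()
  for (l in seq_len(C)) {
    cw <- weights$conv[[l]]
    swTab <- rowsum(wDir, dst)
    swFull <- numeric(n)
    swFull[as.integer(rownames(swTab))] <- as.numeric(swTab)
    num <- rowsum(H[src, , drop = FALSE] * wDir, dst)
    agg <- matrix(0, n, ncol(H))
    agg[as.integer(rownames(num)), ] <- as.matrix(num)
    nzw <- swFull > 0
    agg[nzw, ] <- agg[nzw, , drop = FALSE] / swFull[nzw]
    Z <- sweep(H %*% cw$Wself + agg %*% cw$Wneigh, 2, cw$b, `+`)
    H <- relu(Z)
    Hs[[l + 1L]] <- H; aggs[[l]] <- agg; sws[[l]] <- swFull; Zs[[l]] <- Z
  }
  # head forward on the target node only
  nHead <- length(weights$head)
  hActs <- list(H[target, , drop = FALSE])
  for (l in seq_len(nHead)) {
    hw <- weights$head[[l]]
    Z <- sweep(hActs[[l]] %*% hw$W, 2, hw$b, `+`)
    hActs[[l + 1L]] <- if (l < nHead) relu(Z) else Z
  }
  logitT <- as.numeric(hActs[[nHead + 1L]])
  p <- sigmoid(logitT)
  loss <- -(y * log(max(p, 1e-12)) + (1 - y) * log(max(1 - p, 1e-12)))
  # backward: head
  delta <- matrix(p - y, 1, 1)
  for (l in nHead:1) {
    delta <- delta %*% t(weights$head[[l]]$W)
    if (l > 1L) delta <- delta * (hActs[[l]] > 0)
  }
  G <- matrix(0, n, ncol(H))
  G[target, ] <- delta
  gradMask <- numeric(length(w))
  for (l in C:1) {
    dZ <- G * (Zs[[l]] > 0)
    cw <- weights$conv[[l]]
    dAgg <- dZ %*% t(cw$Wneigh)
    Hprev <- Hs[[l]]
    sw <- sws[[l]]
    # per directed edge e=(u -> v): d agg_v / d w_e = (h_u - agg_v)/sw_v
    ok <- sw[dst] > 0
    if (any(ok)) {
      diffs <- Hprev[src[ok], , drop = FALSE] - aggs[[l]][dst[ok], , drop = FALSE]
      contrib <- rowSums(dAgg[dst[ok], , drop = FALSE] * diffs) / sw[dst[ok]]
      gTab <- rowsum(contrib, eid[ok])
      gm <- numeric(length(w))
      gm[as.integer(rownames(gTab))] <- as.numeric(gTab)
      gradMask <- gradMask + gm
    }
    # propagate to previous layer activations
    Gprev <- dZ %*% t(cw$Wself)
    scl <- ifelse(sw[dst] > 0, wDir / sw[dst], 0)
    back <- rowsum(dAgg[dst, , drop = FALSE] * scl, src)
    Gprev[as.integer(rownames(back)), ] <-
      Gprev[as.integer(rownames(back)), , drop = FALSE] + as.matrix(back)
    G <- Gprev
  }
  list(loss = loss, gradMask = gradMask, p = p)
}

#' @export
print.edgeImportance <- function(x, ...) {
  cat("edgeImportance for node", x$node, "(predicted", x$prediction,
      "):", nrow(x$edges), "subgraph edges\n")
  invisible(x)
}

#' Top-ranked interacting windows for an explained node
#'
#' Ranks edges incident to the target node by descending mask value
#' and reports the partner windows as genomic intervals.
#'
#' @param importance An `edgeImportance` from [explainNode()].
#' @param graph The [GenomeGraph-class] used for the explanation.
#' @param n Number of windows to report (default 10).
#' @return data.frame with rank, partner node, chrom, window start and
#'   end (1-based inclusive), and mask value.
#' @export
topInteractions <- function(importance, graph, n = 10) {
  if (n < 1) stop("n must be >= 1")
  e <- importance$edges
  inc <- e[, 1] == importance$node | e[, 2] == importance$node
  partner <- ifelse(e[inc, 1] == importance$node, e[inc, 2], e[inc, 1])
  mask <- importance$mask[inc]
  o <- order(-mask, partner)
  take <- utils::head(o, n)
  nodes <- graph@nodes
  data.frame(rank = seq_along(take), node = partner[take],
             chrom = nodes$chrom[partner[take]],
             start = nodes$start[partner[take]],
             end = nodes$start[partner[take]] + graph@binSize - 1L,
             mask = mask[take])
}
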