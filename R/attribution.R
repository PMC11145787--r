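#' Find a neutral constant reference input
#'
#' Searches constants within the observed feature range for the
#' constant input vector whose predicted probability is closest to
#' 0.5, so the network is decoded from a non-saturated state. A grid
#' scan locates the best bracket and bisection refines it where the
#' response crosses 0.5.
#'
#' @param model An [MLPClassifier-class].
#' @param featureRange Length-2 numeric: min and max observed feature
#'   values.
#' @param gridPoints Number of grid points for the initial scan.
#' @param tol Probability tolerance for bisection refinement.
#' @return List with `reference` (the constant), `p` (achieved output
#'   probability, guaranteed inside (0.05, 0.95)).
#' @export
findNeutralReference <- function(model, featureRange, gridPoints = 201,
                                 tol = 1e-4) {
  stopifnot(length(featureRange) == 2, featureRange[1] <= featureRange[2])
  d <- model@config$inputWidth
  pOf <- function(c) predictMLP(model, matrix(c, 1, d))
  grid <- seq(featureRange[1], featureRange[2], length.out = gridPoints)
  ps <- vapply(grid, pOf, numeric(1))
  best <- which.min(abs(ps - 0.5))
  cBest <- grid[best]; pBest <- ps[best]
  # refine by bisection if a sign change brackets 0.5
  cross <- which(diff(sign(ps - 0.5)) != 0)
  if (length(cross)) {
    lo <- grid[cross[1]]; hi <- grid[cross[1] + 1L]
    plo <- ps[cross[1]]
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      pm <- pOf(mid)
      if (abs(pm - 0.5) < abs(pBest - 0.5)) { cBest <- mid; pBest <- pm }
      if (abs(pm - 0.5) < tol) break
      if (sign(pm - 0.5) == sign(plo - 0.5)) { lo <- mid; plo <- pm }
      else hi <- mid
    }
  }
  if (pBest <= 0.05 || pBest >= 0.95)
    stop("no constant input gives a non-saturated output (closest p = ",
         signif(pBest, 3),
         "); consider a per-bin mean reference over sampled genes instead")
  list(reference = cBest, p = pBest)
}

#' DeepLift (Rescale) per-bin contribution scores
#'
#' Chains Rescale-rule multipliers layer by layer from the pre-sigmoid
#' logit down to the input bins: each rectifier unit gets the finite
#' difference `(relu(z) - relu(z_ref)) / (z - z_ref)` as its
#' multiplier, so the per-bin contributions satisfy
#' summation-to-delta exactly:
#' `sum(scores) = logit(x) - logit(reference)`.
#'
#' @param model An [MLPClassifier-class] (rectifier hiddens).
#' @param inputs Genes x bins matrix to decode.
#' @param reference A constant (broadcast across bins) or a full
#'   reference vector of the model's input width.
#' @return Genes x bins matrix of contributions.
#' @export
deepliftScores <- function(model, inputs, reference) {
  X <- as.matrix(inputs)
  d <- model@config$inputWidth
  if (ncol(X) != d) stop("feature width mismatch")
  ref <- if (length(reference) == 1L) rep(reference, d) else as.numeric(reference)
  if (length(ref) != d) stop("reference length must be 1 or the input width")
  W <- model@weights
  L <- length(W)
  # reference pre-activations per layer
  zRef <- vector("list", L)
  h <- matrix(ref, 1, d)
  for (i in seq_len(L)) {
    z <- sweep(h %*% W[[i]]$W, 2, W[[i]]$b, `+`)
    zRef[[i]] <- as.numeric(z)
    h <- if (i < L) relu(z) else z
  }
  scores <- matrix(0, nrow(X), d, dimnames = dimnames(X))
  for (g in seq_len(nrow(X))) {
    # forward pass for this gene, keeping pre-activations
    zs <- vector("list", L)
    h <- X[g, , drop = FALSE]
    for (i in seq_len(L)) {
      z <- sweep(h %*% W[[i]]$W, 2, W[[i]]$b, `+`)
      zs[[i]] <- as.numeric(z)
      h <- if (i < L) relu(z) else z
    }
    # rescale multipliers per hidden unit
    rs <- lapply(seq_len(L - 1L), function(i) {
      dz <- zs[[i]] - zRef[[i]]
      r <- ifelse(abs(dz) > 1e-12,
                  (relu(zs[[i]]) - relu(zRef[[i]])) / dz,
                  as.numeric(zs[[i]] > 0))
      r
    })
    # backward vector product down to the input layer
    v <- as.numeric(W[[L]]$W)            # logit is linear in last hidden
    for (i in (L - 1L):1) {
      v <- rs[[i]] * v
      v <- as.numeric(W[[i]]$W %*% v)
    }
    scores[g, ] <- v * (X[g, ] - ref)
  }
  scores
}

#' Summarize contribution scores per bin and label group
#'
#' Decodes are summarized separately for observed-High and
#' observed-Low genes as per-bin mean and standard deviation.
#'
#' @param scores Genes x bins contribution matrix.
#' @param labels Observed "High"/"Low" per gene.
#' @return List with elements `High` and `Low`, each a data.frame of
#'   `bin`, `mean`, `sd`.
#' @export
summarizeContributions <- function(scores, labels) {
  y <- normalizeLabels(labels)
  out <- list()
  for (grp in c("High", "Low")) {
    idx <- if (grp == "High") which(y) else which(!y)
    if (length(idx) == 0L) stop("empty label group: ", grp)
    s <- scores[idx, , drop = FALSE]
    out[[grp]] <- data.frame(bin = seq_len(ncol(s)),
                             mean = colMeans(s),
                             sd = apply(s, 2, stats::sd))
  }
  out
}
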