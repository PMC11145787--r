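sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

logit <- function(p) log(p / (1 - p))

#' Run code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package
#' operations never perturb the session stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Median of `vals` padded with (nTotal - length(vals)) implicit zeros,
# without materializing the zeros.
medianWithZeros <- function(vals, nTotal) {
  nz <- length(vals)
  stopifnot(nTotal >= nz)
  nZero <- nTotal - nz
  if (nTotal == 0L) return(NA_real_)
  full <- sort(c(vals, numeric(0)))  # sorted nonzero values
  # position helper over the conceptual sorted vector of length nTotal
  at <- function(k) {
    neg <- sum(full < 0)
    if (k <= neg) return(full[k])
    if (k <= neg + nZero) return(0)
    full[k - nZero]
  }
  if (nTotal %% 2L == 1L) at((nTotal + 1L) / 2L)
  else (at(nTotal / 2L) + at(nTotal / 2L + 1L)) / 2
}

#' Write a resolved configuration JSON next to run outputs
#' @noRd
writeResolvedConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
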