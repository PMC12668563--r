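#' @useDynLib ancestrylasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis rbinom rnorm runif uniroot var sd pnorm pbinom setNames
#' @importFrom utils write.table read.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) plogis(x)

#' Mean binomial deviance
#'
#' @param y binary response vector.
#' @param prob predicted probabilities in (0, 1).
#' @param eps probabilities are clamped to `[eps, 1 - eps]` before taking logs.
#' @return Mean of `-2 * (y log p + (1 - y) log(1 - p))`.
#' @export
binomial_deviance <- function(y, prob, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Column standardization with 1/n variance; constant columns flagged.
standardize_columns <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(Xc^2) / n)
  const <- scl < 1e-12
  scl[const] <- 1
  Xs <- sweep(Xc, 2, scl, "/")
  Xs[, const] <- 0
  list(Xs = Xs, center = ctr, scale = scl, constant = const)
}

# Stratified fold assignment: within each stratum, folds are as equal as
# possible (sizes differ by <= 1) and the assignment is a seeded permutation.
stratified_folds <- function(strata, k, seed) {
  strata <- as.factor(strata)
  fold <- integer(length(strata))
  with_seed(seed, {
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
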