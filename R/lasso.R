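#' L1-penalized logistic regression with offsets and penalty factors
#'
#' Defines a penalized logistic regression problem
#' \deqn{\min_{\mu,\beta} -\frac{1}{n}\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]
#'       + \lambda \sum_j pf_j |\beta_j|,}
#' where \eqn{p_i = 1/(1 + e^{-(o_i + \mu + x_i^\top \beta)})}, \eqn{o} is a
#' fixed per-observation offset and \eqn{pf_j \ge 0} are per-feature penalty
#' factors (`0` = unpenalized, `Inf` = excluded). The log-likelihood is
#' averaged over observations so that \eqn{\lambda} does not scale with the
#' sample size.
#'
#' @param X numeric feature matrix (n x p), finite, with column names.
#' @param y binary response vector of length n with values in \{0, 1\}.
#' @param offset optional per-observation offset (default zeros).
#' @param penalty_factors optional nonnegative per-feature penalty factors;
#'   may contain `Inf` to exclude features. Default all ones.
#' @param standardize internally scale penalized columns to unit variance
#'   (coefficients are always reported on the original scale).
#' @param normalize_pf rescale the finite penalty factors to have mean one
#'   (an all-equal vector, including all-zero, rescales to all ones). This
#'   keeps the lambda scale comparable across penalty-factor choices.
#' @return An object of class `lasso_problem`.
#' @export
lasso_problem <- function(X, y, offset = NULL, penalty_factors = NULL,
                          standardize = TRUE, normalize_pf = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("column names must be unique")
  if (!all(is.finite(X))) stop("X contains non-finite values")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (all(y == y[1])) stop("degenerate response: y is constant")
  offset <- if (is.null(offset)) numeric(nrow(X)) else as.numeric(offset)
  if (length(offset) != nrow(X)) stop("offset length must equal nrow(X)")
  pf <- if (is.null(penalty_factors)) rep(1, ncol(X)) else as.numeric(penalty_factors)
  if (length(pf) != ncol(X)) stop("penalty_factors length must equal ncol(X)")
  if (any(is.na(pf)) || any(pf < 0)) stop("penalty_factors must be >= 0")
  structure(list(X = X, y = y, offset = offset, penalty_factors = pf,
                 standardize = isTRUE(standardize),
                 normalize_pf = isTRUE(normalize_pf)),
            class = "lasso_problem")
}

# Effective (possibly normalized) penalty factors; Inf entries untouched.
effective_pf <- function(problem) {
  pf <- problem$penalty_factors
  fin <- is.finite(pf)
  if (problem$normalize_pf && any(fin)) {
    f <- pf[fin]
    if (all(f == 0)) {
      pf[fin] <- 1
    } else {
      pf[fin] <- f / mean(f)
    }
  }
  pf
}

# Intercept of the offset-only model: mu with mean(plogis(offset + mu)) = mean(y).
null_intercept <- function(y, offset) {
  if (all(offset == offset[1])) return(qlogis(mean(y)) - offset[1])
  f <- function(m) mean(plogis(offset + m)) - mean(y)
  uniroot(f, lower = -50, upper = 50, extendInt = "yes", tol = 1e-12)$root
}

#' Smallest lambda with an all-zero penalized solution
#'
#' Computes the entry point of the regularization path,
#' \eqn{\lambda_{max} = \max_j |x_j^\top (y - \hat p^0)| / (n\, pf_j)} over
#' features with finite positive penalty factor, where \eqn{\hat p^0} are the
#' fitted probabilities of the intercept-plus-offset-only model and the
#' \eqn{x_j} are the standardized columns. At any `lambda >= lambda_max` all
#' penalized coefficients are zero.
#'
#' @param problem a [lasso_problem()].
#' @return `lambda_max` (scalar, possibly 0 for degenerate designs, with a
#'   `"degenerate"` attribute set in that case).
#' @export
compute_lambda_max <- function(problem) {
  pf <- effective_pf(problem)
  fin <- is.finite(pf)
  if (!any(fin)) stop("all penalty factors are infinite: nothing to fit")
  std <- standardize_columns(problem$X)
  mu0 <- null_intercept(problem$y, problem$offset)
  p0 <- plogis(problem$offset + mu0)
  r <- problem$y - p0
  n <- nrow(problem$X)
  grad <- abs(drop(crossprod(std$Xs, r))) / n
  j <- which(fin & pf > 0 & !std$constant)
  if (length(j) == 0) {
    lm <- 0
    attr(lm, "degenerate") <- TRUE
    return(lm)
  }
  lm <- max(grad[j] / pf[j])
  if (lm <= 0) attr(lm, "degenerate") <- TRUE
  lm
}

default_lambda_grid <- function(problem, nlambda = 100, lambda_min_ratio = NULL) {
  lmax <- compute_lambda_max(problem)
  if (!is.null(attr(lmax, "degenerate"))) {
    stop("lambda_max is zero (no penalized feature correlates with the response)")
  }
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (nrow(problem$X) < ncol(problem$X)) 1e-2 else 1e-4
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit the lasso path for a penalized logistic problem
#'
#' Solves the problem along a decreasing lambda grid by cyclic coordinate
#' descent on a quadratic majorization of the logistic loss (curvature bound
#' 0.25), with warm starts. Features with infinite penalty factor or zero
#' variance are held at exactly zero.
#'
#' @param problem a [lasso_problem()].
#' @param lambdas optional decreasing positive lambda grid; computed from
#'   `lambda_max` when omitted.
#' @param nlambda,lambda_min_ratio grid size and ratio `lambda_min/lambda_max`
#'   used when `lambdas` is omitted (ratio defaults to 1e-2 when n < p and
#'   1e-4 otherwise).
#' @param tol convergence threshold on the maximum coefficient change on the
#'   standardized scale.
#' @param maxit maximum outer (re-majorization) iterations per lambda.
#' @return An object of class `lasso_path` with elements `lambdas`,
#'   `intercepts`, `beta` (p x nlambda, original scale), `beta_std`
#'   (standardized scale), `pf` (effective penalty factors), convergence
#'   diagnostics and the standardization record.
#' @export
fit_lasso_path <- function(problem, lambdas = NULL, nlambda = 100,
                           lambda_min_ratio = NULL, tol = 1e-7, maxit = 1e5) {
  stopifnot(inherits(problem, "lasso_problem"))
  if (is.null(lambdas)) {
    pf_probe <- effective_pf(problem)
    if (all(pf_probe[is.finite(pf_probe)] == 0)) {
      # nothing is penalized: any single lambda gives the unpenalized MLE
      lambdas <- 1
    } else {
      lambdas <- default_lambda_grid(problem, nlambda, lambda_min_ratio)
    }
  } else {
    lambdas <- as.numeric(lambdas)
    if (any(lambdas <= 0)) stop("lambdas must be positive")
    if (length(lambdas) > 1 && any(diff(lambdas) > 0)) {
      stop("lambdas must be decreasing")
    }
  }
  pf <- effective_pf(problem)
  std <- standardize_columns(problem$X)
  include <- is.finite(pf) & !std$constant
  p <- ncol(problem$X)
  L <- length(lambdas)
  mu0 <- null_intercept(problem$y, problem$offset)

  beta_std <- matrix(0, p, L, dimnames = list(colnames(problem$X), NULL))
  if (any(include)) {
    fit <- .lasso_cd_path(std$Xs[, include, drop = FALSE], problem$y,
                          problem$offset, lambdas, pf[include], mu0,
                          tol, as.integer(maxit))
    fitted_beta <- fit$beta
    fitted_beta[abs(fitted_beta) < 1e-10] <- 0  # numerical-zero cleanup
    beta_std[include, ] <- fitted_beta
    intercepts_std <- fit$intercepts
    iterations <- fit$iterations
    converged <- fit$converged
    objective <- fit$objective
  } else {
    intercepts_std <- rep(mu0, L)
    iterations <- rep(0L, L)
    converged <- rep(TRUE, L)
    objective <- rep(NA_real_, L)
  }
  beta <- beta_std / std$scale
  intercepts <- intercepts_std - drop(crossprod(beta_std, std$center / std$scale))
  structure(list(lambdas = lambdas, intercepts = intercepts, beta = beta,
                 beta_std = beta_std, intercepts_std = intercepts_std,
                 pf = pf, include = include, center = std$center,
                 scale = std$scale, iterations = iterations,
                 converged = converged, objective = objective,
                 feature_names = colnames(problem$X)),
            class = "lasso_path")
}

#' Predicted probabilities from a path point
#'
#' @param object a `lasso_path`.
#' @param X_new feature matrix with the training columns.
#' @param offset_new optional offset for the new rows (default zeros).
#' @param index lambda index (default: all, returning a matrix).
#' @param ... unused.
#' @return Probability vector (or n x nlambda matrix when `index` is NULL).
#' @export
predict.lasso_path <- function(object, X_new, offset_new = NULL, index = NULL, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(object$beta)) stop("X_new has wrong number of columns")
  offset_new <- if (is.null(offset_new)) numeric(nrow(X_new)) else as.numeric(offset_new)
  if (length(offset_new) != nrow(X_new)) stop("offset length mismatch")
  idx <- index %||% seq_along(object$lambdas)
  eta <- X_new %*% object$beta[, idx, drop = FALSE]
  eta <- sweep(eta, 2, object$intercepts[idx], "+") + offset_new
  pr <- plogis(eta)
  if (length(idx) == 1) drop(pr) else pr
}

#' Predicted probabilities from explicit coefficients
#'
#' @param mu intercept.
#' @param beta coefficient vector on the original feature scale.
#' @param X_new feature matrix.
#' @param offset_new optional offset (default zeros).
#' @return Probability vector `plogis(offset + mu + X beta)`.
#' @export
predict_proba <- function(mu, beta, X_new, offset_new = NULL) {
  X_new <- as.matrix(X_new)
  if (length(beta) != ncol(X_new)) stop("beta length must equal ncol(X_new)")
  offset_new <- if (is.null(offset_new)) numeric(nrow(X_new)) else as.numeric(offset_new)
  if (length(offset_new) != nrow(X_new)) stop("offset length mismatch")
  drop(plogis(offset_new + mu + X_new %*% beta))
}

#' Karush-Kuhn-Tucker residuals along a fitted path
#'
#' For each lambda, computes on the standardized scale the violation of the
#' stationarity conditions of the penalized objective: for inactive features
#' `max(|grad_j| - lambda * pf_j, 0)`; for active features
#' `|grad_j + lambda * pf_j * sign(beta_j)|`.
#'
#' @param path a `lasso_path`.
#' @param problem the `lasso_problem` it was fitted to.
#' @return Numeric vector of per-lambda maximum KKT violations.
#' @export
kkt_residuals <- function(path, problem) {
  std <- standardize_columns(problem$X)
  n <- nrow(problem$X)
  vapply(seq_along(path$lambdas), function(l) {
    eta <- problem$offset + path$intercepts_std[l] +
      drop(std$Xs %*% path$beta_std[, l])
    g <- drop(crossprod(std$Xs, plogis(eta) - problem$y)) / n
    lamp <- path$lambdas[l] * path$pf
    b <- path$beta_std[, l]
    viol <- ifelse(b == 0, pmax(abs(g) - lamp, 0), abs(g + lamp * sign(b)))
    viol[!path$include] <- 0
    max(abs(mean(plogis(eta) - problem$y)), viol)
  }, numeric(1))
}

#' K-fold cross-validation for the lasso path
#'
#' Stratified (by class) K-fold cross-validation of held-out mean binomial
#' deviance along a shared lambda grid fitted on the full data.
#'
#' @param problem a [lasso_problem()].
#' @param lambdas optional lambda grid (defaults to the full-data grid).
#' @param k_folds number of folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param ... passed on to [fit_lasso_path()].
#' @return An object of class `cv_lasso`: the full-data `fit`, per-lambda
#'   `cvm` / `cvse`, the CV-minimizing `index_min` and `lambda_min`, the fold
#'   assignment and the seed.
#' @export
cross_validate <- function(problem, lambdas = NULL, k_folds = 3, seed = 1, ...) {
  stopifnot(inherits(problem, "lasso_problem"), k_folds >= 2)
  if (is.null(lambdas)) {
    full <- fit_lasso_path(problem, ...)
    lambdas <- full$lambdas
  } else {
    full <- fit_lasso_path(problem, lambdas = lambdas, ...)
  }
  fold <- stratified_folds(problem$y, k_folds, seed)
  for (k in seq_len(k_folds)) {
    yk <- problem$y[fold == k]
    if (length(unique(yk)) < 2 || length(unique(problem$y[fold != k])) < 2) {
      stop("a class is absent from fold ", k, "; use fewer folds")
    }
  }
  loss <- matrix(NA_real_, k_folds, length(lambdas))
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    sub <- lasso_problem(problem$X[tr, , drop = FALSE], problem$y[tr],
                         offset = problem$offset[tr],
                         penalty_factors = problem$penalty_factors,
                         standardize = problem$standardize,
                         normalize_pf = problem$normalize_pf)
    pk <- fit_lasso_path(sub, lambdas = lambdas, ...)
    pr <- predict(pk, problem$X[!tr, , drop = FALSE], problem$offset[!tr])
    pr <- matrix(pr, ncol = length(lambdas))
    loss[k, ] <- apply(pr, 2, function(p) binomial_deviance(problem$y[!tr], p))
  }
  cvm <- colMeans(loss)
  cvse <- apply(loss, 2, sd) / sqrt(k_folds)
  idx <- which.min(cvm)
  structure(list(fit = full, lambdas = lambdas, cvm = cvm, cvse = cvse,
                 fold_loss = loss, index_min = idx, lambda_min = lambdas[idx],
                 fold_id = fold, k_folds = k_folds, seed = seed),
            class = "cv_lasso")
}

#' Coefficients at the CV-minimizing lambda
#'
#' @param object a `cv_lasso`.
#' @param ... unused.
#' @return List with `intercept`, `beta` (original scale) and `index`.
#' @export
coef.cv_lasso <- function(object, ...) {
  list(intercept = object$fit$intercepts[object$index_min],
       beta = object$fit$beta[, object$index_min],
       index = object$index_min)
}

#' Serialize a lasso path to JSON
#'
#' Stores the lambda grid, intercepts, sparse coefficient triplets, penalty
#' factors and standardization record.
#'
#' @param path a `lasso_path`.
#' @param file destination path.
#' @export
write_lasso_path <- function(path, file) {
  nz <- which(path$beta != 0, arr.ind = TRUE)
  obj <- list(
    lambdas = path$lambdas,
    intercepts = path$intercepts,
    coef_triplets = data.frame(feature = path$feature_names[nz[, 1]],
                               lambda_index = as.integer(nz[, 2]),
                               value = path$beta[nz]),
    penalty_factors = path$pf,
    center = path$center, scale = path$scale,
    feature_names = path$feature_names
  )
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
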