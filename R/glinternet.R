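#' Candidate set for first-order interaction modeling
#'
#' Builds the candidate interaction structure: every pair formed by one
#' candidate covariate and any other variable (candidate x candidate pairs
#' included once, ordered by variable position). A "variable" is one model
#' column or a named block of columns (e.g. one-hot ancestry, which
#' interacts as a block: a pair (ancestry, v) expands to one product per
#' ancestry level, grouped together).
#'
#' @param X numeric model matrix with unique column names.
#' @param candidate_covariates character vector of variable names allowed to
#'   form interactions (e.g. age, sex, ancestry, PRS).
#' @param variables optional named list mapping variable name -> character
#'   vector of column names; defaults to one single-column variable per
#'   column of `X`.
#' @return An object of class `candidate_set` with the variable map, the
#'   ordered pair list and `X`.
#' @export
build_candidates <- function(X, candidate_covariates, variables = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("X must have unique column names")
  }
  if (is.null(variables)) {
    variables <- stats::setNames(as.list(colnames(X)), colnames(X))
  }
  bad_cols <- setdiff(unlist(variables), colnames(X))
  if (length(bad_cols)) stop("variables reference unknown columns: ",
                             paste(bad_cols, collapse = ", "))
  missing <- setdiff(candidate_covariates, names(variables))
  if (length(missing)) stop("candidate covariate(s) not found: ",
                            paste(missing, collapse = ", "))
  vnames <- names(variables)
  cand_idx <- match(candidate_covariates, vnames)
  pairs <- unique(do.call(rbind, lapply(cand_idx, function(ci) {
    others <- setdiff(seq_along(vnames), ci)
    cbind(pmin(ci, others), pmax(ci, others))
  })))
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(X = X, variables = variables,
                 candidates = candidate_covariates,
                 pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                                    a = vnames[pairs[, 1]],
                                    b = vnames[pairs[, 2]],
                                    stringsAsFactors = FALSE)),
            class = "candidate_set")
}

# Build the standardized group design for a candidate set.
#
# Base columns: standardized mains (one per model column) followed by
# standardized products of standardized parents (one per column pair within
# each variable pair). Per-pair mode duplicates main columns into each pair
# group (latent overlap formulation: the model effect of a column is the sum
# of its copies). Per-variable mode assigns the products of pair (i, j) to
# group G_i (i < j) with no duplication.
build_glinternet_design <- function(cs, grouping_mode = c("per_pair", "per_variable")) {
  grouping_mode <- match.arg(grouping_mode)
  X <- cs$X
  n <- nrow(X)
  std <- standardize_columns(X)
  Zm <- std$Xs
  p <- ncol(X)
  var_cols <- lapply(cs$variables, function(v) match(v, colnames(X)))

  prod_parent <- matrix(integer(), 0, 2) # parent column indices per product
  prod_pair <- integer()                 # pair row index per product
  for (k in seq_len(nrow(cs$pairs))) {
    ca <- var_cols[[cs$pairs$i[k]]]
    cb <- var_cols[[cs$pairs$j[k]]]
    grid <- expand.grid(a = ca, b = cb)
    prod_parent <- rbind(prod_parent, as.matrix(grid))
    prod_pair <- c(prod_pair, rep(k, nrow(grid)))
  }
  n_prod <- length(prod_pair)
  Zp <- matrix(0, n, n_prod)
  pctr <- numeric(n_prod)
  pscl <- rep(1, n_prod)
  pconst <- logical(n_prod)
  pnames <- character(n_prod)
  for (k in seq_len(n_prod)) {
    w <- Zm[, prod_parent[k, 1]] * Zm[, prod_parent[k, 2]]
    m <- mean(w)
    s <- sqrt(mean((w - m)^2))
    if (s < 1e-12) { pconst[k] <- TRUE; s <- 1 }
    Zp[, k] <- if (pconst[k]) 0 else (w - m) / s
    pctr[k] <- m
    pscl[k] <- s
    pnames[k] <- paste(colnames(X)[prod_parent[k, ]], collapse = ":")
  }
  colnames(Zp) <- pnames
  base <- cbind(Zm, Zp)

  if (grouping_mode == "per_pair") {
    groups <- c(
      lapply(var_cols, identity),  # one main group per variable
      lapply(seq_len(nrow(cs$pairs)), function(k) {
        c(var_cols[[cs$pairs$i[k]]], var_cols[[cs$pairs$j[k]]],
          p + which(prod_pair == k))
      })
    )
    group_label <- c(names(cs$variables),
                     paste(cs$pairs$a, cs$pairs$b, sep = ":"))
    group_kind <- c(rep("main", length(var_cols)),
                    rep("pair", nrow(cs$pairs)))
  } else {
    groups <- lapply(seq_along(var_cols), function(i) {
      c(var_cols[[i]], p + which(cs$pairs$i[prod_pair] == i))
    })
    group_label <- names(cs$variables)
    group_kind <- rep("per_variable", length(var_cols))
  }
  colmap <- unlist(groups)            # base-column index per design column
  gstart <- c(0L, cumsum(lengths(groups)))
  Z <- base[, colmap, drop = FALSE]
  gamma <- sqrt(lengths(groups))
  curvature <- vapply(seq_along(groups), function(g) {
    cols <- (gstart[g] + 1):gstart[g + 1]
    Gm <- crossprod(Z[, cols, drop = FALSE]) / n
    0.25 * max(eigen(Gm, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  }, numeric(1))

  list(Z = Z, base_names = colnames(base), colmap = colmap,
       gstart = gstart, gamma = gamma, curvature = curvature,
       group_label = group_label, group_kind = group_kind,
       grouping_mode = grouping_mode,
       n_main = p, prod_parent = prod_parent, prod_pair = prod_pair,
       main_center = std$center, main_scale = std$scale,
       main_constant = std$constant,
       prod_center = pctr, prod_scale = pscl, prod_constant = pconst,
       var_cols = var_cols)
}

# Rebuild the design matrix for new raw rows using a stored recipe.
design_for_new_data <- function(design, X_new) {
  X_new <- as.matrix(X_new)
  Zm <- sweep(sweep(X_new, 2, design$main_center), 2, design$main_scale, "/")
  Zm[, design$main_constant] <- 0
  n_prod <- length(design$prod_pair)
  Zp <- matrix(0, nrow(X_new), n_prod)
  for (k in seq_len(n_prod)) {
    if (design$prod_constant[k]) next
    w <- Zm[, design$prod_parent[k, 1]] * Zm[, design$prod_parent[k, 2]]
    Zp[, k] <- (w - design$prod_center[k]) / design$prod_scale[k]
  }
  cbind(Zm, Zp)[, design$colmap, drop = FALSE]
}

#' Fit a group-lasso interaction path (glinternet-style)
#'
#' Solves the group-lasso-penalized logistic objective
#' \deqn{\min_{\mu, \theta} -\ell(\mu, \theta)/n + \lambda \sum_g \gamma_g
#'   \|\theta_g\|_2} over the candidate design by block proximal
#' (group soft-thresholding) updates along a decreasing lambda path starting
#' at the computed `lambda_max` (all groups zero). Group weights are
#' `gamma_g = sqrt(|g|)`. In the default per-pair mode each interaction group
#' contains copies of both parent main effects plus the product columns,
#' which guarantees the strong hierarchy; per-variable mode implements the
#' grouping `G_i = {main i} U {products (i, j), j > i}` with a weaker
#' hierarchy guarantee.
#'
#' @param candidates a [build_candidates()] object.
#' @param y binary 0/1 response.
#' @param grouping_mode `"per_pair"` (default) or `"per_variable"`.
#' @param lambdas optional decreasing grid; computed when omitted.
#' @param nlambda,lambda_min_ratio grid parameters (defaults 50 and 0.05).
#' @param stop_rule optional pre-specified number of selected interaction
#'   pairs; the path is truncated at the first lambda reaching it.
#' @param tol,maxit solver controls.
#' @return An object of class `glinternet_path`.
#' @export
fit_glinternet <- function(candidates, y, grouping_mode = c("per_pair", "per_variable"),
                           lambdas = NULL, nlambda = 50, lambda_min_ratio = 0.05,
                           stop_rule = NULL, tol = 1e-7, maxit = 1e4) {
  stopifnot(inherits(candidates, "candidate_set"))
  grouping_mode <- match.arg(grouping_mode)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (all(y == y[1])) stop("degenerate response: y is constant")
  design <- build_glinternet_design(candidates, grouping_mode)
  n <- nrow(design$Z)
  mu0 <- qlogis(mean(y))
  p0 <- rep(mean(y), n)
  G <- length(design$gamma)
  gnorm0 <- vapply(seq_len(G), function(g) {
    cols <- (design$gstart[g] + 1):design$gstart[g + 1]
    sqrt(sum((crossprod(design$Z[, cols, drop = FALSE], y - p0) / n)^2))
  }, numeric(1))
  lambda_max <- max(gnorm0 / design$gamma)
  if (is.null(lambdas)) {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    lambdas <- as.numeric(lambdas)
    if (any(lambdas <= 0) || (length(lambdas) > 1 && any(diff(lambdas) > 0))) {
      stop("lambdas must be positive and decreasing")
    }
  }
  # Z materializes the latent copies, so design columns are already laid out
  # group by group: the flat group-column index is just 0..q-1
  fit <- .group_cd_path(design$Z, y, numeric(n), lambdas,
                        seq_along(design$colmap) - 1L,
                        as.integer(design$gstart), design$gamma,
                        design$curvature, mu0, tol, as.integer(maxit))
  beta <- fit$beta
  beta[abs(beta) < 1e-10] <- 0  # numerical-zero cleanup
  path <- structure(list(lambdas = lambdas, intercepts = fit$intercepts,
                         beta = beta, iterations = fit$iterations,
                         converged = fit$converged, objective = fit$objective,
                         design = design, candidates = candidates,
                         lambda_max = lambda_max, y = y),
                    class = "glinternet_path")
  if (!is.null(stop_rule)) {
    n_int <- vapply(seq_along(lambdas), function(l) {
      nrow(extract_network(glinternet_fit(path, l)))
    }, numeric(1))
    stop_at <- which(n_int >= stop_rule)[1]
    if (!is.na(stop_at)) {
      keep <- seq_len(stop_at)
      path$lambdas <- path$lambdas[keep]
      path$intercepts <- path$intercepts[keep]
      path$beta <- path$beta[, keep, drop = FALSE]
      path$iterations <- path$iterations[keep]
      path$converged <- path$converged[keep]
      path$objective <- path$objective[keep]
    }
  }
  path
}

#' Extract the interaction fit at one path point
#'
#' Collapses the latent (duplicated-column) solution at `index` to model
#' effects on the standardized scale: the main effect of a column is the sum
#' of its copies across groups; each product column keeps its coefficient.
#'
#' @param path a `glinternet_path`.
#' @param index lambda index.
#' @return An object of class `interaction_fit` with `mu`, `theta_main`
#'   (named, standardized scale), `theta_int` (named `"a:b"`), per-group
#'   norms, the lambda, and the design recipe (for prediction).
#' @export
glinternet_fit <- function(path, index) {
  stopifnot(inherits(path, "glinternet_path"),
            index >= 1, index <= length(path$lambdas))
  d <- path$design
  b <- path$beta[, index]
  p <- d$n_main
  base_eff <- vapply(seq_along(d$base_names), function(j) {
    sum(b[d$colmap == j])
  }, numeric(1))
  names(base_eff) <- d$base_names
  gnorms <- vapply(seq_along(d$gamma), function(g) {
    sqrt(sum(b[(d$gstart[g] + 1):d$gstart[g + 1]]^2))
  }, numeric(1))
  names(gnorms) <- d$group_label
  structure(list(mu = path$intercepts[index],
                 theta_main = base_eff[seq_len(p)],
                 theta_int = base_eff[-seq_len(p)],
                 group_norms = gnorms,
                 lambda = path$lambdas[index],
                 index = index,
                 grouping_mode = d$grouping_mode,
                 design = d, candidates = path$candidates),
            class = "interaction_fit")
}

#' Predicted probabilities from a glinternet path
#'
#' @param object a `glinternet_path`.
#' @param X_new raw feature matrix with the training columns.
#' @param index lambda index (default: all).
#' @param ... unused.
#' @return Probability vector or matrix.
#' @export
predict.glinternet_path <- function(object, X_new, index = NULL, ...) {
  Z <- design_for_new_data(object$design, X_new)
  idx <- index %||% seq_along(object$lambdas)
  eta <- sweep(Z %*% object$beta[, idx, drop = FALSE], 2,
               object$intercepts[idx], "+")
  pr <- plogis(eta)
  if (length(idx) == 1) drop(pr) else pr
}

#' Verify the strong-hierarchy property of an interaction fit
#'
#' Per-pair mode: every nonzero interaction coefficient must come with both
#' parent main effects nonzero. Per-variable mode (weaker guarantee): the
#' owning group `G_i` must be active.
#'
#' @param fit an `interaction_fit`.
#' @return `TRUE` if the hierarchy holds; otherwise a character vector of
#'   violating interaction names.
#' @export
check_hierarchy <- function(fit) {
  stopifnot(inherits(fit, "interaction_fit"))
  d <- fit$design
  nz <- which(fit$theta_int != 0)
  if (!length(nz)) return(TRUE)
  bad <- character()
  for (k in nz) {
    pa <- d$prod_parent[k, ]
    if (fit$grouping_mode == "per_pair") {
      if (fit$theta_main[pa[1]] == 0 || fit$theta_main[pa[2]] == 0) {
        bad <- c(bad, names(fit$theta_int)[k])
      }
    } else {
      g_owner <- d$prod_pair[k]
      i <- fit$candidates$pairs$i[g_owner]
      if (fit$group_norms[i] == 0) bad <- c(bad, names(fit$theta_int)[k])
    }
  }
  if (length(bad)) bad else TRUE
}

#' Interaction network of a fit
#'
#' Nonzero interaction coefficients sorted by magnitude (standardized scale),
#' ties broken lexicographically by column pair.
#'
#' @param fit an `interaction_fit`.
#' @param threshold minimum |coefficient| to report (default 0, i.e. all
#'   nonzero).
#' @return Data frame with columns `a`, `b`, `coefficient`, `magnitude`.
#' @export
extract_network <- function(fit, threshold = 0) {
  stopifnot(inherits(fit, "interaction_fit"))
  keep <- which(abs(fit$theta_int) > threshold & fit$theta_int != 0)
  d <- fit$design
  if (!length(keep)) {
    return(data.frame(a = character(), b = character(),
                      coefficient = numeric(), magnitude = numeric()))
  }
  a <- colnames(fit$candidates$X)[d$prod_parent[keep, 1]]
  b <- colnames(fit$candidates$X)[d$prod_parent[keep, 2]]
  net <- data.frame(a = a, b = b, coefficient = fit$theta_int[keep],
                    magnitude = abs(fit$theta_int[keep]))
  net <- net[order(-net$magnitude, net$a, net$b), , drop = FALSE]
  rownames(net) <- NULL
  net
}

#' Count selected interactions per candidate covariate
#'
#' Tallies variable pairs containing a nonzero interaction effect, attributed
#' to the candidate covariate(s) in the pair (a candidate x candidate pair
#' counts once under each).
#'
#' @param fit an `interaction_fit`.
#' @return Named integer vector, one entry per candidate covariate.
#' @export
interaction_count_by_covariate <- function(fit) {
  stopifnot(inherits(fit, "interaction_fit"))
  d <- fit$design
  cand <- fit$candidates$candidates
  counts <- stats::setNames(integer(length(cand)), cand)
  active_pairs <- unique(d$prod_pair[fit$theta_int != 0])
  for (k in active_pairs) {
    for (v in c(fit$candidates$pairs$a[k], fit$candidates$pairs$b[k])) {
      if (v %in% cand) counts[v] <- counts[v] + 1L
    }
  }
  counts
}

#' Export an interaction network as an edge list
#'
#' @param fit an `interaction_fit`.
#' @param file destination path for tab-delimited edges
#'   (covariate_a, covariate_b, coefficient).
#' @export
write_network <- function(fit, file) {
  net <- extract_network(fit)
  write.table(net[, c("a", "b", "coefficient")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Group Karush-Kuhn-Tucker residuals along a glinternet path
#'
#' For each lambda, the violation of the group-lasso stationarity
#' conditions: for inactive groups `max(||grad_g|| - lambda * gamma_g, 0)`;
#' for active groups `||grad_g + lambda * gamma_g * theta_g / ||theta_g||||`;
#' plus the intercept gradient. Gradients are of the average negative
#' log-likelihood on the fitted design.
#'
#' @param path a `glinternet_path`.
#' @return Numeric vector of per-lambda maximum violations.
#' @export
glinternet_kkt_residuals <- function(path) {
  stopifnot(inherits(path, "glinternet_path"))
  d <- path$design
  Z <- d$Z
  n <- nrow(Z)
  y <- path$y
  vapply(seq_along(path$lambdas), function(l) {
    b <- path$beta[, l]
    eta <- path$intercepts[l] + drop(Z %*% b)
    r <- plogis(eta) - y
    lam <- path$lambdas[l]
    viol <- vapply(seq_along(d$gamma), function(g) {
      cols <- (d$gstart[g] + 1):d$gstart[g + 1]
      grad <- drop(crossprod(Z[, cols, drop = FALSE], r)) / n
      bg <- b[cols]
      nb <- sqrt(sum(bg^2))
      if (nb == 0) {
        max(sqrt(sum(grad^2)) - lam * d$gamma[g], 0)
      } else {
        sqrt(sum((grad + lam * d$gamma[g] * bg / nb)^2))
      }
    }, numeric(1))
    max(abs(mean(r)), viol)
  }, numeric(1))
}

#' Cross-validated glinternet path
#'
#' Stratified K-fold cross-validation of held-out binomial deviance along a
#' shared lambda grid; each fold refits the design (standardization included)
#' on its training rows.
#'
#' @param candidates a [build_candidates()] object.
#' @param y binary response.
#' @param k_folds,seed fold count and assignment seed.
#' @param ... passed to [fit_glinternet()].
#' @return List of class `cv_glinternet` with the full-data `fit`, `cvm`,
#'   `cvse`, `index_min`, `lambda_min` and the fold assignment.
#' @export
cv_glinternet <- function(candidates, y, k_folds = 3, seed = 1, ...) {
  y <- as.numeric(y)
  full <- fit_glinternet(candidates, y, ...)
  lambdas <- full$lambdas
  fold <- stratified_folds(y, k_folds, seed)
  loss <- matrix(NA_real_, k_folds, length(lambdas))
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    cs_k <- build_candidates(candidates$X[tr, , drop = FALSE],
                             candidates$candidates, candidates$variables)
    fit_k <- fit_glinternet(cs_k, y[tr], lambdas = lambdas, ...)
    pr <- predict(fit_k, candidates$X[!tr, , drop = FALSE])
    pr <- matrix(pr, ncol = length(lambdas))
    loss[k, ] <- apply(pr, 2, function(p) binomial_deviance(y[!tr], p))
  }
  cvm <- colMeans(loss)
  cvse <- apply(loss, 2, sd) / sqrt(k_folds)
  idx <- which.min(cvm)
  structure(list(fit = full, lambdas = lambdas, cvm = cvm, cvse = cvse,
                 index_min = idx, lambda_min = lambdas[idx],
                 fold_id = fold, seed = seed),
            class = "cv_glinternet")
}
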