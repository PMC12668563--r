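# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: the lasso oracle is a box-constrained quasi-Newton
# solve of the split-variable reformulation, and the group-lasso oracle
# enumerates active-group patterns and smooth-optimizes each restriction.

avg_logistic_nll <- function(mu, beta, X, y, offset = 0) {
  eta <- offset + mu + drop(X %*% beta)
  mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
}

# Objective of the package's penalized problem at an explicit point
# (standardized-scale inputs expected).
lasso_objective <- function(mu, beta, X, y, lambda, pf, offset = 0) {
  avg_logistic_nll(mu, beta, X, y, offset) + lambda * sum(pf * abs(beta))
}

# Generic convex-optimizer oracle for the L1 problem: split beta into
# positive and negative parts, making the objective smooth under box
# constraints, and run L-BFGS-B with analytic gradients.
oracle_lasso <- function(X, y, lambda, pf = rep(1, ncol(X)), offset = 0) {
  n <- nrow(X)
  p <- ncol(X)
  offs <- rep(offset, length.out = n)
  fn <- function(par) {
    mu <- par[1]
    bp <- par[2:(p + 1)]
    bm <- par[(p + 2):(2 * p + 1)]
    avg_logistic_nll(mu, bp - bm, X, y, offs) + lambda * sum(pf * (bp + bm))
  }
  gr <- function(par) {
    mu <- par[1]
    bp <- par[2:(p + 1)]
    bm <- par[(p + 2):(2 * p + 1)]
    eta <- offs + mu + drop(X %*% (bp - bm))
    r <- plogis(eta) - y
    g <- drop(crossprod(X, r)) / n
    c(mean(r), g + lambda * pf, -g + lambda * pf)
  }
  best <- NULL
  for (s in 1:3) {
    start <- c(0, rep(0.01 * s, 2 * p))
    o <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * p)),
                      control = list(maxit = 2000, factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(value = best$value, mu = best$par[1],
       beta = best$par[2:(p + 1)] - best$par[(p + 2):(2 * p + 1)])
}

group_objective <- function(mu, beta, Z, y, lambda, groups, gamma) {
  pen <- sum(vapply(seq_along(groups), function(g) {
    gamma[g] * sqrt(sum(beta[groups[[g]]]^2))
  }, numeric(1)))
  avg_logistic_nll(mu, beta, Z, y) + lambda * pen
}

# Generic convex-optimizer oracle for the group-lasso problem on tiny
# designs: enumerate which groups are active; for each pattern, smooth-
# optimize over the active coordinates (the penalty is differentiable away
# from zero blocks) from a few starts; take the best value overall.
oracle_group_lasso <- function(Z, y, lambda, groups, gamma) {
  G <- length(groups)
  best <- Inf
  for (mask in 0:(2^G - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(G) - 1)) > 0)
    free <- unlist(groups[act])
    fn <- function(par) {
      beta <- numeric(ncol(Z))
      beta[free] <- par[-1]
      group_objective(par[1], beta, Z, y, lambda, groups, gamma)
    }
    for (s in 1:3) {
      start <- c(0, rep(0.05 * s, length(free)))
      o <- tryCatch(stats::optim(start, fn, method = "BFGS",
                                 control = list(maxit = 3000, reltol = 1e-14)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < best) best <- o$value
    }
  }
  best
}

# Columns standardized with the package's 1/n convention so that
# standardized-scale coefficients and objectives are directly comparable.
standardize_1n <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sweep(Xc, 2, sqrt(colSums(Xc^2) / nrow(X)), "/")
}

# Exhaustive O(n_pos * n_neg) AUC with half-credit for ties.
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
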