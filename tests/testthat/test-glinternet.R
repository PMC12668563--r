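make_xy <- function(n, p, seed, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- c(1, -0.8, rep(0, p - 2))
  y <- rbinom(n, 1, plogis(scale(X) %*% beta))
  if (all(y == y[1])) y[1] <- 1 - y[1]
  list(X = X, y = y)
}

test_that("candidate pairs enumerate exactly", {
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("x", 1:5)))
  cs1 <- build_candidates(X, "x1")
  expect_equal(nrow(cs1$pairs), 4)
  expect_equal(cs1$pairs$b, paste0("x", 2:5))

  cs_all <- build_candidates(X, colnames(X))
  expect_equal(nrow(cs_all$pairs), choose(5, 2))
  expect_equal(
    unname(as.matrix(cs_all$pairs[, c("i", "j")])),
    unname(t(combn(5, 2))))

  X10 <- matrix(rnorm(200), 20, 10)
  colnames(X10) <- c("age", "sex", paste0("m", 1:8))
  cs2 <- build_candidates(X10, c("age", "sex"))
  expect_equal(nrow(cs2$pairs), 2 * 8 + 1)

  expect_error(build_candidates(X, "nope"), "not found")
})

test_that("product columns equal elementwise products of standardized parents", {
  prb <- make_xy(80, 4, seed = 2)
  cs <- build_candidates(prb$X, "x1")
  d <- ancestrylasso:::build_glinternet_design(cs, "per_pair")
  Zm <- standardize_1n(prb$X)
  for (k in seq_along(d$prod_pair)) {
    w <- Zm[, d$prod_parent[k, 1]] * Zm[, d$prod_parent[k, 2]]
    rebuilt <- (w - d$prod_center[k]) / d$prod_scale[k]
    base_col <- d$n_main + k
    expect_equal(unname(d$Z[, which(d$colmap == base_col)[1]]),
                 unname(rebuilt), tolerance = 1e-12)
  }
})

test_that("at lambda >= lambda_max all groups are zero with intercept logit(mean y)", {
  prb <- make_xy(150, 5, seed = 3)
  cs <- build_candidates(prb$X, c("x1", "x2"))
  fit <- fit_glinternet(cs, prb$y, nlambda = 3,
                        lambdas = NULL)
  expect_true(all(fit$beta[, 1] == 0))
  expect_equal(fit$intercepts[1], qlogis(mean(prb$y)), tolerance = 1e-7)
  above <- fit_glinternet(cs, prb$y, lambdas = fit$lambda_max * 2)
  expect_true(all(above$beta == 0))
})

test_that("singleton groups reproduce the lasso path", {
  prb <- make_xy(200, 6, seed = 4)
  cs <- build_candidates(prb$X, character(0))
  gfit <- fit_glinternet(cs, prb$y, nlambda = 25, tol = 1e-8)
  lfit <- fit_lasso_path(lasso_problem(prb$X, prb$y), lambdas = gfit$lambdas,
                         tol = 1e-8)
  expect_lt(max(abs(gfit$beta - lfit$beta_std)), 1e-5)
  expect_lt(max(abs(gfit$intercepts - lfit$intercepts_std)), 1e-5)
})

test_that("group-lasso solutions match an enumeration + smooth-optimizer oracle", {
  set.seed(6)
  n <- 60
  Z <- standardize_1n(matrix(rnorm(n * 3), n, 3))
  colnames(Z) <- c("a", "b", "c")
  y <- rbinom(n, 1, plogis(0.8 * Z[, 1] - 0.5 * Z[, 2]))
  y[1:2] <- 0:1
  cs <- build_candidates(Z, character(0),
                         variables = list(ab = c("a", "b"), c = "c"))
  # grouping: one group of two, one singleton
  for (lam_frac in c(0.6, 0.25)) {
    fit <- fit_glinternet(cs, y, nlambda = 2, tol = 1e-10)
    lam <- fit$lambda_max * lam_frac
    fit <- fit_glinternet(cs, y, lambdas = lam, tol = 1e-10)
    d <- fit$design
    groups <- lapply(seq_along(d$gamma), function(g) {
      (d$gstart[g] + 1):d$gstart[g + 1]
    })
    ours <- group_objective(fit$intercepts[1], fit$beta[, 1], d$Z, y,
                            lam, groups, d$gamma)
    orc <- oracle_group_lasso(d$Z, y, lam, groups, d$gamma)
    expect_lt(abs(ours - orc), 1e-6)
  }
})

test_that("group KKT conditions hold along random paths", {
  for (seed in 1:3) {
    prb <- make_xy(120, 6, seed = 40 + seed)
    cs <- build_candidates(prb$X, c("x1", "x2"))
    fit <- fit_glinternet(cs, prb$y, nlambda = 20)
    expect_lt(max(glinternet_kkt_residuals(fit)), 1e-5)
  }
})

test_that("per-pair fits satisfy the strong hierarchy", {
  prb <- make_xy(300, 6, seed = 9,
                 beta = c(1, -0.8, 0.6, rep(0, 3)))
  cs <- build_candidates(prb$X, c("x1", "x2"))
  fit <- fit_glinternet(cs, prb$y, nlambda = 25)
  for (l in seq_along(fit$lambdas)) {
    expect_true(isTRUE(check_hierarchy(glinternet_fit(fit, l))))
  }
})

test_that("per-variable mode partitions the design and keeps its weaker hierarchy", {
  prb <- make_xy(200, 5, seed = 10)
  cs <- build_candidates(prb$X, c("x1", "x3"))
  d <- ancestrylasso:::build_glinternet_design(cs, "per_variable")
  # groups partition: every base column appears exactly once, no copies
  expect_equal(sort(d$colmap), seq_len(d$n_main + length(d$prod_pair)))
  fit <- fit_glinternet(cs, prb$y, grouping_mode = "per_variable", nlambda = 15)
  for (l in c(5, 10, 15)) {
    expect_true(isTRUE(check_hierarchy(glinternet_fit(fit, l))))
  }
})

test_that("network extraction sorts by magnitude with lexicographic ties", {
  prb <- make_xy(150, 4, seed = 12)
  cs <- build_candidates(prb$X, "x1")
  fit <- fit_glinternet(cs, prb$y, nlambda = 10)
  gf <- glinternet_fit(fit, 10)
  # empty network when all interactions are zero
  gf0 <- glinternet_fit(fit, 1)
  expect_equal(nrow(extract_network(gf0)), 0)
  # forced coefficients: order by |theta|, sign kept
  gf$theta_int[] <- 0
  gf$theta_int[1:2] <- c(-3, 2)  # pairs (x1,x2), (x1,x3)
  net <- extract_network(gf)
  expect_equal(net$coefficient, c(-3, 2))
  expect_equal(net$b, c("x2", "x3"))
  # count equals brute force over the coefficient vector
  gf2 <- glinternet_fit(fit, 10)
  expect_equal(nrow(extract_network(gf2)), sum(gf2$theta_int != 0))
})

test_that("interaction counts per covariate equal exhaustive tabulation", {
  prb <- make_xy(400, 6, seed = 13, beta = c(1.2, -1, 0.8, rep(0, 3)))
  cs <- build_candidates(prb$X, c("x1", "x2"))
  fit <- fit_glinternet(cs, prb$y, nlambda = 20)
  gf <- glinternet_fit(fit, 20)
  counts <- interaction_count_by_covariate(gf)
  # exhaustive tabulation from the network and pair list
  net <- extract_network(gf)
  manual <- sapply(c("x1", "x2"), function(v) {
    sum(apply(unique(net[, c("a", "b")]), 1, function(r) v %in% r))
  })
  expect_equal(unname(counts), unname(as.integer(manual)))
  # empty fit: all zero
  expect_true(all(interaction_count_by_covariate(glinternet_fit(fit, 1)) == 0))
})

test_that("group activity grows as lambda decreases, with rare re-entry only", {
  prb <- make_xy(300, 6, seed = 14, beta = c(1, -0.8, 0.5, rep(0, 3)))
  cs <- build_candidates(prb$X, c("x1", "x2"))
  fit <- fit_glinternet(cs, prb$y, nlambda = 30)
  d <- fit$design
  n_active <- vapply(seq_along(fit$lambdas), function(l) {
    sum(vapply(seq_along(d$gamma), function(g) {
      any(fit$beta[(d$gstart[g] + 1):d$gstart[g + 1], l] != 0)
    }, logical(1)))
  }, numeric(1))
  drops <- sum(diff(n_active) < 0)
  expect_lte(drops, 3)  # monotone up to occasional path re-entry
})

test_that("the stop rule truncates the path at the requested interaction count", {
  prb <- make_xy(400, 6, seed = 15, beta = c(1.5, -1.2, 0.8, rep(0, 3)))
  cs <- build_candidates(prb$X, c("x1", "x2"))
  fit <- fit_glinternet(cs, prb$y, nlambda = 30, stop_rule = 2)
  n_end <- nrow(extract_network(glinternet_fit(fit, length(fit$lambdas))))
  expect_gte(n_end, 2)
  if (length(fit$lambdas) > 1) {
    n_prev <- nrow(extract_network(glinternet_fit(fit, length(fit$lambdas) - 1)))
    expect_lt(n_prev, 2)
  }
})

test_that("multi-column variables interact as a block", {
  set.seed(16)
  n <- 150
  g <- sample(c("A", "B", "C"), n, replace = TRUE)
  X <- cbind(dA = as.numeric(g == "A"), dB = as.numeric(g == "B"),
             v = rnorm(n), w = rnorm(n))
  y <- rbinom(n, 1, plogis(X[, "v"]))
  y[1:2] <- 0:1
  cs <- build_candidates(X, "anc",
                         variables = list(anc = c("dA", "dB"), v = "v", w = "w"))
  expect_equal(nrow(cs$pairs), 2)
  d <- ancestrylasso:::build_glinternet_design(cs, "per_pair")
  # pair (anc, v): products dA*v and dB*v live in one group
  pair_groups <- which(d$group_kind == "pair")
  sizes <- lengths(lapply(pair_groups, function(g2) {
    (d$gstart[g2] + 1):d$gstart[g2 + 1]
  }))
  expect_true(all(sizes == 5))  # 2 ancestry mains + 1 main + 2 products
})

test_that("cross-validated glinternet is reproducible and indexes its minimum", {
  prb <- make_xy(300, 5, seed = 17, beta = c(1, -0.8, rep(0, 3)))
  cs <- build_candidates(prb$X, "x1")
  cv1 <- cv_glinternet(cs, prb$y, k_folds = 3, seed = 5, nlambda = 15)
  cv2 <- cv_glinternet(cs, prb$y, k_folds = 3, seed = 5, nlambda = 15)
  expect_equal(cv1$cvm, cv2$cvm)
  expect_equal(cv1$index_min, which.min(cv1$cvm))
})
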