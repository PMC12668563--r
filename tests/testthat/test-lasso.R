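test_that("at lambda >= lambda_max the model is null with the calibrated intercept", {
  prb <- random_problem(150, 8, seed = 11)
  problem <- lasso_problem(prb$X, prb$y)
  lmax <- compute_lambda_max(problem)
  path <- fit_lasso_path(problem, lambdas = c(2 * lmax, 1.0000001 * lmax, lmax))
  expect_true(all(path$beta == 0))
  expect_equal(path$intercepts, rep(qlogis(mean(prb$y)), 3), tolerance = 1e-8)

  # with an offset, the null intercept solves the offset-adjusted mean
  off <- rnorm(150)
  problem_o <- lasso_problem(prb$X, prb$y, offset = off)
  lmax_o <- compute_lambda_max(problem_o)
  path_o <- fit_lasso_path(problem_o, lambdas = 2 * lmax_o)
  expect_true(all(path_o$beta == 0))
  expect_equal(mean(plogis(off + path_o$intercepts[1])), mean(prb$y),
               tolerance = 1e-6)

  # just below lambda_max at least one coefficient enters
  below <- fit_lasso_path(problem, lambdas = 0.99 * lmax)
  expect_gt(sum(below$beta != 0), 0)
})

test_that("an infinite penalty factor excludes a feature at every lambda", {
  prb <- random_problem(120, 6, seed = 3)
  pf <- c(Inf, rep(1, 5))
  problem <- lasso_problem(prb$X, prb$y, penalty_factors = pf)
  path <- fit_lasso_path(problem, nlambda = 30)
  expect_true(all(path$beta[1, ] == 0))
  expect_gt(sum(path$beta[-1, ] != 0), 0)
})

test_that("path solutions match a generic convex-optimizer oracle", {
  for (seed in c(5, 17)) {
    prb <- random_problem(200, 10, seed = seed)
    problem <- lasso_problem(prb$X, prb$y, normalize_pf = FALSE)
    lmax <- compute_lambda_max(problem)
    lams <- lmax * c(0.5, 0.2, 0.05)
    path <- fit_lasso_path(problem, lambdas = lams, tol = 1e-9)
    for (l in seq_along(lams)) {
      ours <- lasso_objective(path$intercepts_std[l], path$beta_std[, l],
                              prb$X, prb$y, lams[l], rep(1, 10))
      orc <- oracle_lasso(prb$X, prb$y, lams[l])
      expect_lt(abs(ours - orc$value), 1e-6)
    }
  }
  # with offset and non-uniform penalty factors
  prb <- random_problem(150, 6, seed = 23)
  off <- rnorm(150, sd = 0.5)
  pf <- c(0, 0.5, 1, 1, 2, 1)
  problem <- lasso_problem(prb$X, prb$y, offset = off, penalty_factors = pf,
                           normalize_pf = FALSE)
  lam <- 0.03
  path <- fit_lasso_path(problem, lambdas = lam, tol = 1e-9)
  ours <- lasso_objective(path$intercepts_std[1], path$beta_std[, 1],
                          prb$X, prb$y, lam, pf, offset = off)
  orc <- oracle_lasso(prb$X, prb$y, lam, pf = pf, offset = off)
  expect_lt(abs(ours - orc$value), 1e-6)
})

test_that("KKT conditions hold along the path", {
  for (seed in 1:4) {
    prb <- random_problem(150, 12, seed = seed)
    problem <- lasso_problem(prb$X, prb$y)
    path <- fit_lasso_path(problem, nlambda = 40)
    expect_lt(max(kkt_residuals(path, problem)), 1e-5)
  }
})

test_that("lambda_max scales inversely with penalty factors and agrees with bisection", {
  prb <- random_problem(100, 5, seed = 9)
  p1 <- lasso_problem(prb$X, prb$y, normalize_pf = FALSE)
  p2 <- lasso_problem(prb$X, prb$y, penalty_factors = rep(2, 5),
                      normalize_pf = FALSE)
  expect_equal(compute_lambda_max(p2), compute_lambda_max(p1) / 2,
               tolerance = 1e-12)

  # bisection on the solver: smallest lambda with an all-zero solution
  lmax <- compute_lambda_max(p1)
  lo <- lmax / 3
  hi <- lmax * 3
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    fit <- fit_lasso_path(p1, lambdas = mid)
    if (all(fit$beta == 0)) hi <- mid else lo <- mid
  }
  expect_lt(abs(hi - lmax) / lmax, 0.01)
})

test_that("the penalized objective is non-increasing in iteration count", {
  prb <- random_problem(200, 10, seed = 31)
  problem <- lasso_problem(prb$X, prb$y)
  lam <- compute_lambda_max(problem) * 0.1
  objs <- vapply(1:8, function(k) {
    suppressWarnings(fit_lasso_path(problem, lambdas = lam, maxit = k)$objective[1])
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("cross-validation losses equal a manual per-fold refit", {
  prb <- random_problem(200, 8, seed = 41)
  problem <- lasso_problem(prb$X, prb$y)
  cv <- cross_validate(problem, k_folds = 3, seed = 7, nlambda = 25)
  for (k in 1:3) {
    tr <- cv$fold_id != k
    sub <- lasso_problem(prb$X[tr, ], prb$y[tr])
    refit <- fit_lasso_path(sub, lambdas = cv$lambdas)
    pr <- predict(refit, prb$X[!tr, ])
    manual <- apply(pr, 2, function(p) binomial_deviance(prb$y[!tr], p))
    expect_equal(unname(cv$fold_loss[k, ]), unname(manual), tolerance = 1e-12)
  }
  expect_equal(cv$index_min, which.min(cv$cvm))
  # folds are stratified: sizes differ by at most 1 within each class
  for (cls in 0:1) {
    sizes <- table(cv$fold_id[prb$y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("identical data halves produce identical per-fold losses", {
  prb <- random_problem(80, 5, seed = 53)
  X2 <- rbind(prb$X, prb$X)
  y2 <- c(prb$y, prb$y)
  grid <- default_lambda_grid(lasso_problem(X2, y2), nlambda = 15)
  losses <- lapply(1:2, function(k) {
    tr <- if (k == 1) 81:160 else 1:80
    te <- setdiff(1:160, tr)
    fit <- fit_lasso_path(lasso_problem(X2[tr, ], y2[tr]), lambdas = grid)
    apply(predict(fit, X2[te, ]), 2, function(p) binomial_deviance(y2[te], p))
  })
  expect_equal(losses[[1]], losses[[2]], tolerance = 1e-12)
})

test_that("cross-validation on pure noise selects near-null models", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 500)
    X <- matrix(rnorm(250 * 30), 250, 30)
    colnames(X) <- paste0("x", 1:30)
    y <- rbinom(250, 1, 0.3)
    if (length(unique(y)) < 2) next
    cv <- cross_validate(lasso_problem(X, y), k_folds = 3, seed = seed,
                         nlambda = 30)
    if (sum(coef(cv)$beta != 0) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 16)  # >= 80% of 20 seeds
})

test_that("predicted probabilities follow the logistic form and its invariances", {
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(predict_proba(0, rep(0, 4), X), rep(0.5, 10))
  expect_equal(predict_proba(log(3), rep(0, 4), X), rep(0.75, 10))
  beta <- rnorm(4)
  off <- rnorm(10)
  shift <- 1.7
  expect_equal(predict_proba(2 - shift, beta, X, off + shift),
               predict_proba(2, beta, X, off), tolerance = 1e-12)
  expect_error(predict_proba(0, rep(0, 3), X), "beta length")
})

test_that("the path agrees with the glmnet reference implementation", {
  skip_if_not_installed("glmnet")
  prb <- random_problem(300, 12, seed = 77)
  problem <- lasso_problem(prb$X, prb$y)
  path <- fit_lasso_path(problem, nlambda = 40, tol = 1e-9)
  g <- glmnet::glmnet(prb$X, prb$y, family = "binomial",
                      lambda = path$lambdas, standardize = TRUE,
                      thresh = 1e-14)
  cb <- as.matrix(stats::coef(g))
  expect_lt(max(abs(cb[-1, ] - path$beta)), 1e-5)
  expect_lt(max(abs(cb[1, ] - path$intercepts)), 1e-5)
})

test_that("degenerate and malformed problems are rejected", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("x", 1:4)))
  expect_error(lasso_problem(X, rep(1, 10)), "degenerate")
  expect_error(lasso_problem(X, c(rep(0:1, 5))[1:9]), "length")
  Xbad <- X
  Xbad[1, 1] <- NA
  expect_error(lasso_problem(Xbad, rep(0:1, 5)), "non-finite")
  expect_error(
    compute_lambda_max(lasso_problem(X, rep(0:1, 5),
                                     penalty_factors = rep(Inf, 4))),
    "infinite")
})
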