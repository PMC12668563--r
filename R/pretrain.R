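#' Stage 1 of the pretrained lasso: the overall model
#'
#' Fits a cross-validated L1-penalized logistic regression to the pooled
#' multi-ancestry training data and records the basis that stage 2 consumes:
#' coefficients `beta0` and intercept `mu0` at the CV-minimizing lambda, the
#' support set `S = {j : beta0_j != 0}`, and the fixed mixing parameter
#' `alpha` in \[0, 1\] (`alpha = 0`: stage 2 is fully tied to the overall
#' model; `alpha = 1`: stage 2 ignores it).
#'
#' @param X pooled feature matrix.
#' @param y binary 0/1 response.
#' @param alpha mixing parameter in \[0, 1\] (default 0.5).
#' @param cv_seed seed for the stage-1 fold assignment.
#' @param k_folds folds for stage-1 CV (default 3).
#' @param ... passed to [cross_validate()] / [fit_lasso_path()].
#' @return An object of class `pretrain_basis`.
#' @export
fit_overall <- function(X, y, alpha = 0.5, cv_seed = 1, k_folds = 3, ...) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  problem <- lasso_problem(X, y)
  cv <- cross_validate(problem, k_folds = k_folds, seed = cv_seed, ...)
  cf <- coef(cv)
  structure(list(beta0 = cf$beta, mu0 = cf$intercept,
                 support = which(cf$beta != 0), alpha = alpha,
                 cv = cv, feature_names = colnames(problem$X)),
            class = "pretrain_basis")
}

#' Replace the mixing parameter of a pretrain basis
#'
#' The stage-1 fit does not depend on `alpha`, so a sweep over `alpha` can
#' reuse one basis.
#'
#' @param basis a `pretrain_basis`.
#' @param alpha new value in \[0, 1\].
#' @return The basis with `alpha` replaced.
#' @export
set_alpha <- function(basis, alpha) {
  stopifnot(inherits(basis, "pretrain_basis"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  basis$alpha <- alpha
  basis
}

#' Stage-2 offset for a group
#'
#' Exactly `(1 - alpha) * (X_k beta0 + mu0)` elementwise: the fraction of the
#' overall model's linear predictor that the group model inherits with
#' coefficient frozen at one.
#'
#' @param basis a `pretrain_basis`.
#' @param X_k feature matrix of the group's rows.
#' @return Offset vector of length `nrow(X_k)`.
#' @export
compute_offset <- function(basis, X_k) {
  stopifnot(inherits(basis, "pretrain_basis"))
  X_k <- as.matrix(X_k)
  if (ncol(X_k) != length(basis$beta0)) stop("X_k has wrong number of columns")
  (1 - basis$alpha) * drop(X_k %*% basis$beta0 + basis$mu0)
}

#' Stage-2 penalty factors
#'
#' The literal mixing formula
#' `pf_j = (1 - alpha) * [ I(j not in S) / alpha + I(j in S) ]`:
#' at `alpha = 0` features off the stage-1 support are excluded (`pf = Inf`)
#' and support features get `pf = 1`; at `alpha = 0.5` support features get
#' 0.5 and the rest 1; at `alpha = 1` every `pf` is 0 (stage 2 unpenalized
#' as printed; with the default mean-one penalty-factor normalization of
#' [lasso_problem()] an all-equal vector rescales to ones, restoring an
#' ordinary lasso).
#'
#' @param basis a `pretrain_basis`.
#' @return Penalty-factor vector of length `p` (may contain `Inf`).
#' @export
compute_penalty_factors <- function(basis) {
  stopifnot(inherits(basis, "pretrain_basis"))
  a <- basis$alpha
  p <- length(basis$beta0)
  in_s <- seq_len(p) %in% basis$support
  off <- if (a == 0) Inf else 1 / a
  (1 - a) * ifelse(in_s, 1, off)
}

#' Stage 2 of the pretrained lasso: per-group models
#'
#' For each group (ancestry), fits a cross-validated lasso on the group's
#' rows with the stage-1 offset and the shared penalty factors; lambda is
#' chosen by the group's own CV. A group whose response is constant falls
#' back to the overall model (recorded in `fallback`).
#'
#' @param basis a `pretrain_basis` from [fit_overall()].
#' @param X,y pooled training data (same columns as stage 1).
#' @param groups group (ancestry) label per row.
#' @param cv_seed seed for stage-2 fold assignments.
#' @param k_folds folds per group (default 3).
#' @param normalize_pf passed to [lasso_problem()] (default TRUE).
#' @param ... passed to [cross_validate()].
#' @return An object of class `pretrained_model` with the basis and one
#'   stage-2 `cv_lasso` (or fallback marker) per group.
#' @export
fit_group_models <- function(basis, X, y, groups, cv_seed = 1, k_folds = 3,
                             normalize_pf = TRUE, ...) {
  stopifnot(inherits(basis, "pretrain_basis"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  pf <- compute_penalty_factors(basis)
  fits <- list()
  fallback <- character()
  for (g in unique(groups)) {
    rows <- groups == g
    fit_g <- tryCatch({
      prob <- lasso_problem(X[rows, , drop = FALSE], y[rows],
                            offset = compute_offset(basis, X[rows, , drop = FALSE]),
                            penalty_factors = pf, normalize_pf = normalize_pf)
      cross_validate(prob, k_folds = k_folds, seed = cv_seed, ...)
    }, error = function(e) e)
    if (inherits(fit_g, "error")) {
      fallback <- c(fallback, g)
      fits[[g]] <- structure(list(reason = conditionMessage(fit_g)),
                             class = "pretrain_fallback")
    } else {
      fits[[g]] <- fit_g
    }
  }
  if (length(fallback)) {
    message("pretrained lasso: fallback to overall model for group(s): ",
            paste(fallback, collapse = ", "))
  }
  structure(list(basis = basis, fits = fits, penalty_factors = pf,
                 groups = unique(groups), fallback = fallback),
            class = "pretrained_model")
}

#' Group-routed predictions from a pretrained model
#'
#' Scores each row with its group's stage-2 model (including the stage-1
#' offset term); rows from groups without a stage-2 fit — fallback groups or
#' labels unseen in training — are scored by the overall model, with a
#' warning for unseen labels.
#'
#' @param model a `pretrained_model`.
#' @param X_new feature matrix.
#' @param groups_new group label per row of `X_new`.
#' @return Probability vector.
#' @export
predict_group <- function(model, X_new, groups_new) {
  stopifnot(inherits(model, "pretrained_model"))
  X_new <- as.matrix(X_new)
  groups_new <- as.character(groups_new)
  stopifnot(nrow(X_new) == length(groups_new))
  basis <- model$basis
  out <- numeric(nrow(X_new))
  unseen <- setdiff(unique(groups_new), model$groups)
  if (length(unseen)) {
    warning("unseen group label(s) routed to the overall model: ",
            paste(unseen, collapse = ", "))
  }
  for (g in unique(groups_new)) {
    rows <- groups_new == g
    fit_g <- model$fits[[g]]
    if (is.null(fit_g) || inherits(fit_g, "pretrain_fallback")) {
      out[rows] <- predict_proba(basis$mu0, basis$beta0,
                                 X_new[rows, , drop = FALSE])
    } else {
      off <- compute_offset(basis, X_new[rows, , drop = FALSE])
      out[rows] <- predict(fit_g$fit, X_new[rows, , drop = FALSE],
                           offset_new = off, index = fit_g$index_min)
    }
  }
  out
}

#' Serialize a pretrained model to JSON
#'
#' Stores the stage-1 basis (sparse), alpha, the penalty-factor convention,
#' and each group's chosen stage-2 coefficients (sparse).
#'
#' @param model a `pretrained_model`.
#' @param file destination path.
#' @export
write_pretrained_model <- function(model, file) {
  b <- model$basis
  nz <- which(b$beta0 != 0)
  groups <- lapply(model$fits, function(f) {
    if (inherits(f, "pretrain_fallback")) return(list(fallback = TRUE))
    cf <- coef(f)
    nzg <- which(cf$beta != 0)
    list(intercept = cf$intercept,
         features = b$feature_names[nzg], beta = unname(cf$beta[nzg]),
         lambda = f$lambda_min)
  })
  obj <- list(alpha = b$alpha, mu0 = b$mu0,
              support = b$feature_names[nz], beta0 = unname(b$beta0[nz]),
              penalty_factors = model$penalty_factors,
              pf_normalized = TRUE, groups = groups)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
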