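#' Dataset configuration (All / Mix / Specific)
#'
#' @param mode `"All"` (every ancestry), `"Mix"` (majority + one focal
#'   ancestry) or `"Specific"` (focal ancestry only).
#' @param focal_ancestry required for Mix and Specific.
#' @param majority_ancestry the majority group code (default `"WB"`).
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(mode = c("All", "Mix", "Specific"),
                           focal_ancestry = NULL, majority_ancestry = "WB") {
  mode <- match.arg(mode)
  if (mode != "All" && is.null(focal_ancestry)) {
    stop(mode, " dataset requires a focal ancestry")
  }
  structure(list(mode = mode, focal_ancestry = focal_ancestry,
                 majority_ancestry = majority_ancestry),
            class = "dataset_config")
}

#' Select cohort rows for a dataset configuration
#'
#' @param cohort a `cohort`.
#' @param config a [dataset_config()].
#' @return Integer row indices.
#' @export
build_dataset <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "dataset_config"))
  anc <- cohort$ancestry
  if (config$mode != "All" && !config$focal_ancestry %in% anc) {
    stop("focal ancestry absent from cohort: ", config$focal_ancestry)
  }
  switch(config$mode,
         All = seq_along(anc),
         Mix = which(anc %in% c(config$majority_ancestry, config$focal_ancestry)),
         Specific = which(anc == config$focal_ancestry))
}

#' Stratified train/test split
#'
#' Splits rows into train and test with per-stratum proportions within one
#' row of `fraction`; strata default to ancestry crossed with a binary
#' outcome. The same split is reused across all models and dataset
#' configurations so test sets are paired.
#'
#' @param cohort a `cohort`.
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @param outcome optional binary vector to cross with ancestry for
#'   stratification.
#' @return List with integer `train` and `test` row indices.
#' @export
split_train_test <- function(cohort, fraction = 0.8, seed = 1, outcome = NULL) {
  stopifnot(inherits(cohort, "cohort"), fraction > 0, fraction < 1)
  strata <- if (is.null(outcome)) cohort$ancestry
            else paste(cohort$ancestry, outcome, sep = "/")
  train <- integer()
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 2) stop("stratum too small to split: ", s)
      n_tr <- round(fraction * length(idx))
      n_tr <- min(max(n_tr, 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(strata), train))
}

#' Study configuration
#'
#' @param cohort a `cohort` or a [cohort_spec()] (generated at run time).
#' @param diseases disease codes to analyse (default: all in the cohort).
#' @param focal_ancestries minority ancestries to evaluate (default: all
#'   non-majority ancestries).
#' @param majority_ancestry majority group (default: largest ancestry).
#' @param model_families subset of `c("lasso", "glinternet", "pretrain")`.
#' @param split_fraction training fraction (default 0.8).
#' @param cv_folds folds for every cross-validation (default 3).
#' @param seeds named list with integer `split` and `cv` seeds.
#' @param alpha pretraining mixing parameter (default 0.5).
#' @param interaction_candidates candidate covariates for glinternet
#'   (default age, sex, ancestry and the trained disease's PRS).
#' @param lasso_nlambda,glinternet_nlambda path lengths.
#' @param datasets dataset configurations to run (subset of
#'   `c("Specific", "Mix", "All")`; default all — the Specific baseline plus
#'   Mix/All for every family, i.e. the 3 + 2 + 2 combination design).
#' @param min_cases per-disease, per-ancestry minimum positive-case count
#'   for eligibility (default 20).
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort, diseases = NULL, focal_ancestries = NULL,
                         majority_ancestry = NULL,
                         model_families = c("lasso", "glinternet", "pretrain"),
                         split_fraction = 0.8, cv_folds = 3,
                         seeds = list(split = 1, cv = 2), alpha = 0.5,
                         interaction_candidates = c("age", "sex", "ancestry", "prs"),
                         lasso_nlambda = 100, glinternet_nlambda = 50,
                         datasets = c("Specific", "Mix", "All"),
                         min_cases = 20) {
  stopifnot(split_fraction > 0, split_fraction < 1, cv_folds >= 2)
  model_families <- match.arg(model_families, several.ok = TRUE)
  structure(list(cohort = cohort, diseases = diseases,
                 focal_ancestries = focal_ancestries,
                 majority_ancestry = majority_ancestry,
                 model_families = model_families,
                 split_fraction = split_fraction, cv_folds = cv_folds,
                 seeds = seeds, alpha = alpha,
                 interaction_candidates = interaction_candidates,
                 lasso_nlambda = lasso_nlambda,
                 glinternet_nlambda = glinternet_nlambda,
                 datasets = match.arg(datasets, several.ok = TRUE),
                 min_cases = min_cases),
            class = "study_config")
}

# Model matrix for one disease: age, sex, one-hot ancestry (reference =
# majority), the disease's own PRS (other diseases' PRS excluded to avoid
# leakage), then PCs and metabolites. Returns the matrix plus the variable
# map used by glinternet (ancestry dummies form one block variable).
build_model_matrix <- function(cohort, disease, majority) {
  meta <- cohort$column_meta
  anc_levels <- setdiff(unique(cohort$ancestry), majority)
  anc_cols <- sapply(anc_levels, function(a) as.numeric(cohort$ancestry == a))
  anc_cols <- matrix(anc_cols, nrow = length(cohort$ancestry),
                     dimnames = list(NULL, paste0("anc_", anc_levels)))
  own_prs <- paste0("prs_", disease)
  keep <- meta$name[meta$type != "prs" | meta$name == own_prs]
  X <- cbind(cohort$X[, c("age", "sex"), drop = FALSE], anc_cols,
             cohort$X[, setdiff(keep, c("age", "sex")), drop = FALSE])
  variables <- c(list(age = "age", sex = "sex",
                      ancestry = colnames(anc_cols), prs = own_prs),
                 stats::setNames(as.list(setdiff(colnames(X),
                                                 c("age", "sex", own_prs,
                                                   colnames(anc_cols)))),
                                 setdiff(colnames(X),
                                         c("age", "sex", own_prs,
                                           colnames(anc_cols)))))
  list(X = X, variables = variables, prs_column = own_prs)
}

#' Run the full model-comparison study
#'
#' For each disease: one stratified train/test split; baseline lasso trained
#' on the Specific, Mix and All datasets; glinternet and pretrained lasso on
#' Mix and All (seven method-dataset combinations); every model evaluated on
#' each focal ancestry's held-out test rows; one-sided DeLong comparisons of
#' each candidate model against the baseline trained on the same dataset;
#' and a win-count analysis over the full result grid.
#'
#' @param config a [study_config()].
#' @return A `study_manifest`: the resolved configuration, the evaluation
#'   `grid` (long data frame), per-fit summaries, interaction networks,
#'   skipped cells with reasons, win-count analysis and seeds.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    config$cohort
  }
  stopifnot(inherits(cohort, "cohort"))
  anc_tab <- table(cohort$ancestry)
  majority <- config$majority_ancestry %||% names(which.max(anc_tab))
  diseases <- config$diseases %||% colnames(cohort$Y)
  focal <- config$focal_ancestries %||% setdiff(names(anc_tab), majority)
  seeds <- config$seeds
  grid <- list()
  summaries <- list()
  networks <- list()
  skipped <- list()
  k <- config$cv_folds

  note_skip <- function(...) {
    skipped[[length(skipped) + 1]] <<- data.frame(...)
  }
  safe <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      note_skip(cell = label, reason = conditionMessage(e))
      NULL
    })
  }

  for (di in seq_along(diseases)) {
    d <- diseases[di]
    y <- cohort$Y[, d]
    mm <- build_model_matrix(cohort, d, majority)
    split_seed <- seeds$split + 1000L * di
    cv_seed <- seeds$cv + 1000L * di
    sp <- split_train_test(cohort, config$split_fraction, split_seed, outcome = y)
    eligible <- focal[vapply(focal, function(a) {
      sum(y[cohort$ancestry == a]) >= config$min_cases
    }, logical(1))]
    for (a in setdiff(focal, eligible)) {
      note_skip(cell = paste(d, a, sep = "/"),
                reason = sprintf("fewer than %d positive cases", config$min_cases))
    }
    if (!length(eligible)) next

    fit_lasso_on <- function(rows, label) {
      safe(label, {
        prob <- lasso_problem(mm$X[rows, , drop = FALSE], y[rows])
        cross_validate(prob, k_folds = k, seed = cv_seed,
                       nlambda = config$lasso_nlambda)
      })
    }
    fit_glint_on <- function(rows, label) {
      safe(label, {
        cs <- build_candidates(mm$X[rows, , drop = FALSE],
                               config$interaction_candidates, mm$variables)
        cv_glinternet(cs, y[rows], k_folds = k, seed = cv_seed,
                      nlambda = config$glinternet_nlambda)
      })
    }
    fit_pretrain_on <- function(rows, label) {
      safe(label, {
        basis <- fit_overall(mm$X[rows, , drop = FALSE], y[rows],
                             alpha = config$alpha, cv_seed = cv_seed,
                             k_folds = k, nlambda = config$lasso_nlambda)
        fit_group_models(basis, mm$X[rows, , drop = FALSE], y[rows],
                         cohort$ancestry[rows], cv_seed = cv_seed, k_folds = k,
                         nlambda = config$lasso_nlambda)
      })
    }

    all_rows <- sp$train
    fits_all <- list()
    if ("All" %in% config$datasets) {
      if ("lasso" %in% config$model_families) {
        fits_all$lasso <- fit_lasso_on(all_rows, paste(d, "lasso", "All", sep = "/"))
      }
      if ("glinternet" %in% config$model_families) {
        fits_all$glinternet <- fit_glint_on(all_rows, paste(d, "glinternet", "All", sep = "/"))
      }
      if ("pretrain" %in% config$model_families) {
        fits_all$pretrain <- fit_pretrain_on(all_rows, paste(d, "pretrain", "All", sep = "/"))
      }
    }

    for (a in eligible) {
      test_a <- sp$test[cohort$ancestry[sp$test] == a]
      if (length(unique(y[test_a])) < 2) {
        note_skip(cell = paste(d, a, sep = "/"),
                  reason = "test rows contain a single class")
        next
      }
      mix_rows <- sp$train[cohort$ancestry[sp$train] %in% c(majority, a)]
      spc_rows <- sp$train[cohort$ancestry[sp$train] == a]

      ds_on <- config$datasets
      fits <- list()
      if ("lasso" %in% config$model_families) {
        if ("Specific" %in% ds_on) {
          fits[["lasso/Specific"]] <- fit_lasso_on(spc_rows, paste(d, a, "lasso/Specific", sep = "/"))
        }
        if ("Mix" %in% ds_on) {
          fits[["lasso/Mix"]] <- fit_lasso_on(mix_rows, paste(d, a, "lasso/Mix", sep = "/"))
        }
        if ("All" %in% ds_on) fits[["lasso/All"]] <- fits_all$lasso
      }
      if ("glinternet" %in% config$model_families) {
        if ("Mix" %in% ds_on) {
          fits[["glinternet/Mix"]] <- fit_glint_on(mix_rows, paste(d, a, "glinternet/Mix", sep = "/"))
        }
        if ("All" %in% ds_on) fits[["glinternet/All"]] <- fits_all$glinternet
      }
      if ("pretrain" %in% config$model_families) {
        if ("Mix" %in% ds_on) {
          fits[["pretrain/Mix"]] <- fit_pretrain_on(mix_rows, paste(d, a, "pretrain/Mix", sep = "/"))
        }
        if ("All" %in% ds_on) fits[["pretrain/All"]] <- fits_all$pretrain
      }

      Xt <- mm$X[test_a, , drop = FALSE]
      yt <- y[test_a]
      preds <- list()
      for (nm in names(fits)) {
        f <- fits[[nm]]
        if (is.null(f)) next
        method <- sub("/.*", "", nm)
        preds[[nm]] <- switch(method,
          lasso = predict(f$fit, Xt, index = f$index_min),
          glinternet = predict(f$fit, Xt, index = f$index_min),
          pretrain = predict_group(f, Xt, rep(a, nrow(Xt))))
      }
      for (nm in names(fits)) {
        f <- fits[[nm]]
        method <- sub("/.*", "", nm)
        ds <- sub(".*/", "", nm)
        if (is.null(f)) {
          grid[[length(grid) + 1]] <- data.frame(
            ancestry = a, disease = d, method = method, dataset = ds,
            auc = NA_real_, delta = NA_real_, p = NA_real_, tier = "",
            n_pos = sum(yt), n_neg = sum(1 - yt), nonzero = NA_integer_)
          next
        }
        sc <- preds[[nm]]
        auc_val <- auc(sc, yt)
        delta <- NA_real_
        pval <- NA_real_
        tier <- ""
        if (method != "lasso") {
          base <- preds[[paste0("lasso/", ds)]]
          if (!is.null(base)) {
            cmp <- delong_test(sc, base, yt, alternative = "a_greater")
            delta <- cmp$delta
            pval <- cmp$p
            tier <- cmp$tier
          }
        }
        nonzero <- switch(method,
          lasso = sum(coef(f)$beta != 0),
          glinternet = {
            gf <- glinternet_fit(f$fit, f$index_min)
            sum(gf$theta_main != 0) + sum(gf$theta_int != 0)
          },
          pretrain = {
            fg <- f$fits[[a]]
            if (inherits(fg, "pretrain_fallback") || is.null(fg)) NA_integer_
            else sum(coef(fg)$beta != 0)
          })
        grid[[length(grid) + 1]] <- data.frame(
          ancestry = a, disease = d, method = method, dataset = ds,
          auc = auc_val, delta = delta, p = pval, tier = tier,
          n_pos = sum(yt), n_neg = sum(1 - yt), nonzero = nonzero)
        summaries[[length(summaries) + 1]] <- data.frame(
          disease = d, ancestry = a, method = method, dataset = ds,
          nonzero = nonzero,
          lambda = switch(method, lasso = f$lambda_min,
                          glinternet = f$lambda_min,
                          pretrain = NA_real_),
          alpha = if (method == "pretrain") config$alpha else NA_real_)
        if (method == "glinternet") {
          gf <- glinternet_fit(f$fit, f$index_min)
          networks[[paste(d, a, ds, sep = "/")]] <- extract_network(gf)
        }
      }
    }
  }
  grid <- if (length(grid)) do.call(rbind, grid) else NULL
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  win <- if (!is.null(grid)) study_win_counts(grid) else NULL
  structure(list(config = config, majority = majority, diseases = diseases,
                 focal_ancestries = focal, grid = grid,
                 fit_summaries = summaries, networks = networks,
                 skipped = skipped, win_analysis = win,
                 seeds = seeds,
                 version = as.character(utils::packageVersion("ancestrylasso"))),
            class = "study_manifest")
}

#' Win-count analysis of a study grid
#'
#' Tallies, for every result column (focal ancestry x disease), which
#' method-dataset combination attains the best test AUC; computes each
#' method's expected wins under proportional chance and a one-tailed exact
#' binomial test of its observed wins.
#'
#' @param grid the long evaluation grid from [run_study()].
#' @return List with the per-combination win table and a per-method data
#'   frame of observed wins, expected wins and binomial p-values.
#' @export
study_win_counts <- function(grid) {
  g <- grid[!is.na(grid$auc), , drop = FALSE]
  tabs <- tabulate_results(g)
  all_combos <- unique(unlist(lapply(tabs, function(t) names(t$wins))))
  combo_wins <- stats::setNames(numeric(length(all_combos)), all_combos)
  n_results <- 0
  for (t in tabs) {
    n_results <- n_results + t$n_columns
    combo_wins[names(t$wins)] <- combo_wins[names(t$wins)] + t$wins
  }
  methods <- unique(sub("/.*", "", all_combos))
  total <- length(all_combos)
  per_method <- do.call(rbind, lapply(methods, function(m) {
    rows <- grep(paste0("^", m, "/"), all_combos, value = TRUE)
    obs <- sum(combo_wins[rows])
    data.frame(method = m, datasets = length(rows), observed_wins = obs,
               expected_wins = as.numeric(expected_wins(n_results, length(rows), total)),
               p_binomial = win_count_binomial_test(n_results, obs,
                                                    length(rows), total))
  }))
  list(n_results = n_results, total_combinations = total,
       combo_wins = combo_wins, per_method = per_method)
}

#' Render a study manifest as a text report
#'
#' Per-ancestry AUC tables (column-best bracketed, significance stars from
#' the one-sided DeLong p-values), the win-count analysis, and the top
#' interactions per glinternet fit.
#'
#' @param manifest a `study_manifest`.
#' @return Character vector of report lines, invisibly printed with `cat`.
#' @export
render_report <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Ancestry-aware disease prediction study report")
  add(strrep("=", 47))
  if (is.null(manifest$grid)) {
    add("(empty evaluation grid)")
    return(invisible(lines))
  }
  tabs <- tabulate_results(manifest$grid[!is.na(manifest$grid$auc), ])
  for (a in names(tabs)) {
    add("")
    add("Test AUC by method and training dataset - focal ancestry ", a)
    tab <- tabs[[a]]$table
    txt <- utils::capture.output(print(tab, row.names = FALSE))
    lines <- c(lines, txt)
  }
  if (!is.null(manifest$win_analysis)) {
    w <- manifest$win_analysis
    add("")
    add("Win counts over ", w$n_results, " result columns (",
        w$total_combinations, " method-dataset combinations)")
    lines <- c(lines, utils::capture.output(print(w$per_method, row.names = FALSE)))
  }
  if (length(manifest$networks)) {
    add("")
    add("Top interactions (glinternet, standardized coefficients)")
    for (nm in names(manifest$networks)) {
      net <- utils::head(manifest$networks[[nm]], 5)
      if (!nrow(net)) next
      add("  ", nm, ": ",
          paste(sprintf("%s:%s=%.3f", net$a, net$b, net$coefficient),
                collapse = ", "))
    }
  }
  if (!is.null(manifest$skipped)) {
    add("")
    add("Skipped cells")
    lines <- c(lines, paste0("  ", manifest$skipped$cell, ": ",
                             manifest$skipped$reason))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
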