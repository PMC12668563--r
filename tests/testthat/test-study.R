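test_that("dataset configurations select the right rows with set relations", {
  coh <- generate_cohort(toy_spec(n = 300, seed = 5))
  all_rows <- build_dataset(coh, dataset_config("All"))
  mix_rows <- build_dataset(coh, dataset_config("Mix", "SA"))
  spc_rows <- build_dataset(coh, dataset_config("Specific", "SA"))
  expect_equal(all_rows, seq_along(coh$ancestry))
  expect_equal(mix_rows, which(coh$ancestry %in% c("WB", "SA")))
  expect_equal(spc_rows, which(coh$ancestry == "SA"))
  expect_true(all(spc_rows %in% mix_rows))
  expect_true(all(mix_rows %in% all_rows))
  # set-algebra oracle: Specific and its complement partition Mix
  expect_equal(sort(c(spc_rows, setdiff(mix_rows, spc_rows))), mix_rows)
  expect_error(build_dataset(coh, dataset_config("Mix", "AF")), "absent")
})

test_that("train/test splits are stratified, deterministic and disjoint", {
  coh <- generate_cohort(toy_spec(n = 1000, seed = 6))
  y <- coh$Y[, "DIA"]
  sp1 <- split_train_test(coh, 0.8, seed = 3, outcome = y)
  sp2 <- split_train_test(coh, 0.8, seed = 3, outcome = y)
  sp3 <- split_train_test(coh, 0.8, seed = 4, outcome = y)
  expect_identical(sp1, sp2)
  expect_false(identical(sp1$train, sp3$train))
  expect_length(intersect(sp1$train, sp1$test), 0)
  expect_equal(sort(c(sp1$train, sp1$test)), seq_len(1000))
  # per-stratum proportions within one row of the fraction
  strata <- paste(coh$ancestry, y)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- sum(idx %in% sp1$train)
    expect_lte(abs(n_tr - 0.8 * length(idx)), 1)
  }
  # simple case: 100 rows, one stratum
  sp_one <- cohort_spec(100, c(WB = 1), list(disease_spec("DIA", 0.3)),
                        n_metabolites = 2, metabolite_block_sizes = 2,
                        n_pcs_global = 4, n_pcs_local = 1, seed = 7)
  spx <- split_train_test(generate_cohort(sp_one), 0.8, seed = 1)
  expect_equal(length(spx$train), 80)
})

test_that("a tiny study produces the full 7-combination grid and manifest", {
  spec <- toy_spec(n = 900, seed = 21, wb = 0.75, prev = c(WB = 0.15, SA = 0.3))
  cfg <- study_config(spec, seeds = list(split = 1, cv = 2),
                      lasso_nlambda = 25, glinternet_nlambda = 12,
                      min_cases = 10)
  man <- run_study(cfg)
  expect_s3_class(man, "study_manifest")
  expect_equal(nrow(man$grid), 7)
  expect_setequal(paste(man$grid$method, man$grid$dataset, sep = "/"),
                  c("lasso/Specific", "lasso/Mix", "lasso/All",
                    "glinternet/Mix", "glinternet/All",
                    "pretrain/Mix", "pretrain/All"))
  expect_true(all(is.finite(man$grid$auc)))
  # candidates are compared against the baseline on the same dataset only
  cand <- man$grid[man$grid$method != "lasso", ]
  expect_true(all(is.finite(cand$p)))
  base <- man$grid[man$grid$method == "lasso", ]
  expect_true(all(is.na(base$p)))
  # delta equals the recomputable AUC difference
  for (i in seq_len(nrow(cand))) {
    b <- base$auc[base$dataset == cand$dataset[i]]
    expect_equal(cand$delta[i], cand$auc[i] - b, tolerance = 1e-12)
  }
  # stars in the report equal recomputation from stored p-values
  expect_equal(cand$tier, significance_tier(cand$p))
  rep_lines <- capture.output(render_report(man))
  expect_true(any(grepl("Win counts", rep_lines)))
})

test_that("studies are deterministic given config and seeds", {
  spec <- toy_spec(n = 700, seed = 31, wb = 0.75, prev = c(WB = 0.15, SA = 0.3))
  cfg <- study_config(spec, seeds = list(split = 9, cv = 4),
                      model_families = c("lasso", "glinternet"),
                      datasets = "Mix", lasso_nlambda = 20,
                      glinternet_nlambda = 10, min_cases = 10)
  m1 <- run_study(cfg)
  m2 <- run_study(cfg)
  expect_equal(m1$grid, m2$grid)
})

test_that("only the trained disease's PRS enters the model matrix", {
  d1 <- disease_spec("DIA", 0.2, shared_effects = c(age = 0.3))
  d2 <- disease_spec("ART", 0.2, shared_effects = c(sex = 0.3))
  sp <- cohort_spec(300, c(WB = 0.7, SA = 0.3), list(d1, d2),
                    n_metabolites = 5, n_pcs_global = 4, n_pcs_local = 1,
                    seed = 11)
  coh <- generate_cohort(sp)
  mm <- ancestrylasso:::build_model_matrix(coh, "DIA", "WB")
  expect_true("prs_DIA" %in% colnames(mm$X))
  expect_false("prs_ART" %in% colnames(mm$X))
  expect_true("anc_SA" %in% colnames(mm$X))
  expect_false("anc_WB" %in% colnames(mm$X))  # majority is the reference
})

test_that("test rows never enter any training set", {
  spec <- toy_spec(n = 600, seed = 41, wb = 0.7, prev = c(WB = 0.2, SA = 0.3))
  coh <- generate_cohort(spec)
  y <- coh$Y[, "DIA"]
  sp <- split_train_test(coh, 0.8, seed = 1001 + 1, outcome = y)
  for (mode in c("All", "Mix", "Specific")) {
    cfgd <- dataset_config(mode, if (mode != "All") "SA")
    rows <- intersect(sp$train, build_dataset(coh, cfgd))
    expect_length(intersect(rows, sp$test), 0)
  }
})

test_that("diseases below the case threshold are skipped with a reason", {
  spec <- toy_spec(n = 400, seed = 51, wb = 0.9, prev = c(WB = 0.15, SA = 0.1))
  cfg <- study_config(spec, seeds = list(split = 1, cv = 2),
                      model_families = "lasso", datasets = "Mix",
                      lasso_nlambda = 15, min_cases = 20)
  man <- run_study(cfg)  # ~4 SA cases expected: below threshold
  expect_null(man$grid)
  expect_true(any(grepl("positive cases", man$skipped$reason)))
})

test_that("win counts from a synthetic grid match an exhaustive argmax tally", {
  set.seed(61)
  combos <- c("lasso/Specific", "lasso/Mix", "lasso/All",
              "glinternet/Mix", "glinternet/All", "pretrain/Mix", "pretrain/All")
  grid <- expand.grid(ancestry = c("SA", "AF"),
                      disease = c("DIA", "ART", "GS"),
                      combo = combos, stringsAsFactors = FALSE)
  grid$method <- sub("/.*", "", grid$combo)
  grid$dataset <- sub(".*/", "", grid$combo)
  grid$auc <- runif(nrow(grid), 0.5, 0.9)
  w <- study_win_counts(grid)
  expect_equal(w$n_results, 6)
  expect_equal(w$total_combinations, 7)
  expect_equal(sum(w$combo_wins), 6)
  # manual argmax per (ancestry, disease) column
  manual <- stats::setNames(numeric(7), combos)
  for (a in c("SA", "AF")) for (d in c("DIA", "ART", "GS")) {
    sub <- grid[grid$ancestry == a & grid$disease == d, ]
    manual[sub$combo[which.max(sub$auc)]] <-
      manual[sub$combo[which.max(sub$auc)]] + 1
  }
  expect_equal(w$combo_wins[combos], manual)
  # per-method expectation and p-value recomputation
  pm <- w$per_method
  lasso_row <- pm[pm$method == "lasso", ]
  expect_equal(lasso_row$expected_wins, 6 * 3 / 7)
  expect_equal(lasso_row$p_binomial,
               win_count_binomial_test(6, lasso_row$observed_wins, 3, 7))
})
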