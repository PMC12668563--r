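#!/usr/bin/env Rscript

# Step 4 — win-count meta-analysis.
#
# Two parts. First, the worked example at the full-study scale: with 24
# result columns (8 diseases x 3 ancestry tables) and 7 method-dataset
# combinations, a method trained on 3 combinations expects 24*3/7 wins and
# one trained on 2 expects 24*2/7; observing 12 wins for a 2-combination
# method gives a one-tailed exact binomial p-value. Second, the same
# analysis applied to this repository's own study grid from step 2, if it
# has been produced.

suppressMessages(library(ancestrylasso))

cat("Worked example at the full-study scale (24 columns, 7 combinations):\n")
e3 <- expected_wins(24, 3, 7)
e2 <- expected_wins(24, 2, 7)
p12 <- win_count_binomial_test(24, 12, 2, 7)
cat(sprintf("  expected wins, 3-dataset baseline: %.4f (display %s)\n",
            as.numeric(e3), attr(e3, "display")))
cat(sprintf("  expected wins, 2-dataset method:   %.4f (display %s)\n",
            as.numeric(e2), attr(e2, "display")))
cat(sprintf("  P(wins >= 12 | n = 24, p = 2/7)  = %.4f\n", p12))

out <- list(expected_wins_3of7 = as.numeric(e3),
            expected_wins_2of7 = as.numeric(e2),
            p_binomial_12_wins = p12)

grid_path <- "results/study_grid.tsv"
if (file.exists(grid_path)) {
  grid <- read.table(grid_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  w <- study_win_counts(grid)
  cat(sprintf("\nThis study's grid: %d result columns, %d combinations\n",
              w$n_results, w$total_combinations))
  print(w$per_method, row.names = FALSE)
  out$study <- w$per_method
} else {
  cat("\n(run analysis/02_run_study.R first to analyse this study's grid)\n")
}

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(out, "results/win_meta.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nWritten to results/win_meta.json\n")
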