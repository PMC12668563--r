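#' @section Tie handling:
#' All ranking operations use the mid-rank convention, so `auc()` equals the
#' tie-corrected Mann-Whitney statistic
#' (#concordant + 0.5 * #tied) / (n_pos * n_neg).
#' @name evaluation
NULL

# Placement values (structural components) of the Mann-Whitney statistic,
# computed from midranks: v10 per positive, v01 per negative. mean(v10) =
# mean(v01) = AUC.
placement_values <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, n_pos = m, n_neg = n)
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney AUC with the mid-rank convention.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  pl <- placement_values(scores, labels)
  mean(pl$v10)
}

#' Empirical ROC curve
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return An object of class `roc_curve`: `thresholds` (decreasing, with
#'   `Inf` prepended), non-decreasing `fpr` and `tpr` from (0,0) to (1,1),
#'   and the class counts.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  m <- sum(y == 1)
  n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0), numeric(1))
  structure(list(thresholds = c(Inf, thr),
                 fpr = c(0, fp / n), tpr = c(0, tp / m),
                 n_pos = m, n_neg = n),
            class = "roc_curve")
}

#' Significance tier from a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' One-sided DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same labelled
#' observations, using the structural-components (placement-value) estimator
#' of `Var(AUC_a - AUC_b)` including their covariance. The default
#' alternative is directional: model `a` has larger AUC than model `b`.
#'
#' @param scores_a,scores_b paired score vectors on identical observations.
#' @param labels binary 0/1 labels.
#' @param alternative `"a_greater"` (one-sided, default), `"two_sided"`, or
#'   `"b_greater"`.
#' @return An object of class `auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p`, `tier`, class counts, and a `degenerate` flag
#'   set when the variance estimate collapses to zero (then `p` is 0.5 for
#'   `delta == 0` by convention, else 0/1).
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        alternative = c("a_greater", "two_sided", "b_greater")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  delta <- auc_a - auc_b
  m <- pa$n_pos
  n <- pa$n_neg
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  var_delta <- s10 / m + s01 / n
  degenerate <- !is.finite(var_delta) || var_delta <= .Machine$double.eps
  if (degenerate) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
    if (delta != 0) {
      warning("degenerate DeLong variance with nonzero AUC difference")
    }
  } else {
    z <- delta / sqrt(var_delta)
  }
  p <- switch(alternative,
              a_greater = pnorm(z, lower.tail = FALSE),
              b_greater = pnorm(z),
              two_sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 var_delta = var_delta, z = z, p = p,
                 tier = significance_tier(p), n_pos = m, n_neg = n,
                 alternative = alternative, degenerate = degenerate),
            class = "auc_comparison")
}

#' Expected wins under proportional chance
#'
#' Under the null that every method-dataset combination is equally likely to
#' produce the best score in a result column, a method trained on
#' `method_datasets` of `total_combinations` combinations expects
#' `n_results * method_datasets / total_combinations` wins.
#'
#' @param n_results number of result columns tallied.
#' @param method_datasets combinations belonging to the method.
#' @param total_combinations total method-dataset combinations.
#' @return Expected win count at full precision, with a `display` attribute
#'   rounded to one decimal.
#' @export
expected_wins <- function(n_results, method_datasets, total_combinations) {
  stopifnot(n_results >= 1, method_datasets >= 1,
            method_datasets <= total_combinations)
  e <- n_results * method_datasets / total_combinations
  attr(e, "display") <- formatC(round(e, 1), format = "f", digits = 1)
  e
}

#' One-tailed binomial win-count test
#'
#' Exact upper-tail probability of observing at least `observed_wins` wins in
#' `n_results` independent columns when the per-column win probability is
#' `method_datasets / total_combinations`.
#'
#' @param n_results number of result columns.
#' @param observed_wins observed win count (0..n_results).
#' @param method_datasets,total_combinations as in [expected_wins()].
#' @return The one-tailed p-value `P(X >= observed_wins)`.
#' @export
win_count_binomial_test <- function(n_results, observed_wins, method_datasets,
                                    total_combinations) {
  stopifnot(observed_wins >= 0, observed_wins <= n_results)
  pbinom(observed_wins - 1, n_results, method_datasets / total_combinations,
         lower.tail = FALSE)
}

#' Tabulate a study evaluation grid
#'
#' Reshapes a long evaluation grid into per-ancestry tables in the layout
#' methods x diseases, appends a per-method average column, marks the
#' column-wise best AUC, and tallies wins per method-dataset combination.
#'
#' @param grid data frame with columns `ancestry`, `disease`, `method`,
#'   `dataset`, `auc` and optionally `p` (significance annotated from it).
#' @return List with one element per ancestry: `table` (data frame of
#'   formatted cells), `auc` (numeric matrix), `wins` (named win counts per
#'   method-dataset row), and `n_columns`.
#' @export
tabulate_results <- function(grid) {
  stopifnot(all(c("ancestry", "disease", "method", "dataset", "auc") %in%
                  names(grid)))
  out <- list()
  for (a in unique(grid$ancestry)) {
    g <- grid[grid$ancestry == a, , drop = FALSE]
    rows <- unique(g[, c("method", "dataset")])
    row_id <- paste(rows$method, rows$dataset, sep = "/")
    diseases <- unique(g$disease)
    M <- matrix(NA_real_, nrow(rows), length(diseases),
                dimnames = list(row_id, diseases))
    tiers <- matrix("", nrow(rows), length(diseases),
                    dimnames = list(row_id, diseases))
    for (i in seq_len(nrow(g))) {
      rid <- paste(g$method[i], g$dataset[i], sep = "/")
      M[rid, g$disease[i]] <- g$auc[i]
      if (!is.null(g$p) && !is.na(g$p[i])) {
        tiers[rid, g$disease[i]] <- significance_tier(g$p[i])
      }
    }
    if (anyNA(M)) message("tabulate_results: missing cells rendered as NA")
    wins <- stats::setNames(integer(nrow(rows)), row_id)
    cells <- matrix("", nrow(M), ncol(M), dimnames = dimnames(M))
    for (j in seq_len(ncol(M))) {
      col <- M[, j]
      best <- if (all(is.na(col))) integer() else which.max(col)
      if (length(best)) wins[best] <- wins[best] + 1L
      cells[, j] <- ifelse(is.na(col), "NA",
                           paste0(formatC(col, format = "f", digits = 3),
                                  tiers[, j]))
      if (length(best)) cells[best, j] <- paste0("[", cells[best, j], "]")
    }
    avg <- rowMeans(M, na.rm = TRUE)
    tab <- data.frame(method = rows$method, dataset = rows$dataset,
                      cells, Avg = formatC(avg, format = "f", digits = 3),
                      check.names = FALSE)
    out[[a]] <- list(table = tab, auc = M, avg = avg, wins = wins,
                     n_columns = length(diseases))
  }
  out
}
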