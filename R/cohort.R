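#' Disease specification for the synthetic cohort generator
#'
#' Defines the ground-truth outcome model for one disease: a liability
#' (log-odds) built from shared main effects, ancestry-specific main effects
#' and pairwise feature interactions, plus a per-disease polygenic risk score
#' (PRS) column generated to correlate with that liability.
#'
#' @param name short disease code (e.g. `"DIA"`, `"ART"`).
#' @param target_prevalence named fractions in (0, 1), one per ancestry code
#'   (a single unnamed value is applied to every ancestry).
#' @param shared_effects named numeric vector of main-effect coefficients,
#'   names being column names of the generated cohort (a disease may
#'   reference its own `prs_<name>` column but no other disease's PRS).
#' @param ancestry_specific_effects named list: ancestry code -> named
#'   numeric vector of additional main effects applied only to that group.
#' @param interaction_effects named numeric vector with names `"colA:colB"`;
#'   each adds `coef * X[, colA] * X[, colB]` to the liability.
#' @param prs_liability_correlation target correlation in \[0, 1) between the
#'   generated PRS column and the PRS-free liability.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(name, target_prevalence,
                         shared_effects = numeric(),
                         ancestry_specific_effects = list(),
                         interaction_effects = numeric(),
                         prs_liability_correlation = 0.5) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  target_prevalence <- unlist(target_prevalence)
  if (any(target_prevalence <= 0 | target_prevalence >= 1)) {
    stop("target prevalences must lie in (0, 1) for disease ", name)
  }
  if (prs_liability_correlation < 0 || prs_liability_correlation >= 1) {
    stop("prs_liability_correlation must be in [0, 1)")
  }
  structure(list(name = name, target_prevalence = target_prevalence,
                 shared_effects = shared_effects,
                 ancestry_specific_effects = ancestry_specific_effects,
                 interaction_effects = interaction_effects,
                 prs_liability_correlation = prs_liability_correlation),
            class = "disease_spec")
}

#' Cohort specification
#'
#' Describes a synthetic multi-ancestry multiomics cohort: ancestry mixture,
#' feature-block layout (demographics, per-disease PRS, global and local
#' genotype principal components, exchangeably correlated metabolite blocks)
#' and the disease outcome models.
#'
#' @param n_total number of individuals.
#' @param ancestry_proportions named fractions summing to one; the first
#'   entry is treated as the majority/reference ancestry.
#' @param diseases list of [disease_spec()] objects.
#' @param n_metabolites,n_pcs_global,n_pcs_local feature-block sizes (each
#'   >= 1).
#' @param metabolite_block_sizes integer block sizes summing to
#'   `n_metabolites`; defaults to blocks of 10 with a remainder block.
#' @param metabolite_block_correlation within-block exchangeable correlation
#'   rho in \[0, 1).
#' @param seed integer seed; the generator is bitwise reproducible given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total, ancestry_proportions, diseases,
                        n_metabolites = 243, n_pcs_global = 40,
                        n_pcs_local = 10, metabolite_block_sizes = NULL,
                        metabolite_block_correlation = 0.5, seed = 1) {
  stopifnot(n_total >= 1, n_metabolites >= 1, n_pcs_global >= 1, n_pcs_local >= 1)
  props <- unlist(ancestry_proportions)
  if (is.null(names(props)) || any(!nzchar(names(props)))) {
    stop("ancestry_proportions must be named by ancestry code")
  }
  if (abs(sum(props) - 1) > 1e-9) stop("ancestry proportions must sum to 1")
  if (any(props <= 0)) stop("ancestry proportions must be positive")
  rho <- metabolite_block_correlation
  if (rho < 0 || rho >= 1) stop("metabolite_block_correlation must be in [0, 1)")
  if (is.null(metabolite_block_sizes)) {
    nb <- n_metabolites %/% 10
    metabolite_block_sizes <- if (nb >= 1) {
      c(rep(10, nb - 1), 10 + n_metabolites %% 10)
    } else {
      n_metabolites
    }
  }
  metabolite_block_sizes <- as.integer(metabolite_block_sizes)
  if (sum(metabolite_block_sizes) != n_metabolites || any(metabolite_block_sizes < 1)) {
    stop("metabolite_block_sizes must be positive and sum to n_metabolites")
  }
  if (inherits(diseases, "disease_spec")) diseases <- list(diseases)
  stopifnot(length(diseases) >= 1,
            all(vapply(diseases, inherits, logical(1), "disease_spec")))
  names(diseases) <- vapply(diseases, `[[`, character(1), "name")
  if (anyDuplicated(names(diseases))) stop("disease names must be unique")
  spec <- structure(list(n_total = as.integer(n_total),
                         ancestry_proportions = props,
                         diseases = diseases,
                         n_metabolites = as.integer(n_metabolites),
                         n_pcs_global = as.integer(n_pcs_global),
                         n_pcs_local = as.integer(n_pcs_local),
                         metabolite_block_sizes = metabolite_block_sizes,
                         metabolite_block_correlation = rho,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_effect_columns(spec)
  spec
}

#' Column layout implied by a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with `name` and `type` (one of demographic, prs,
#'   pc_global, pc_local, metabolite) for every feature column.
#' @export
spec_column_meta <- function(spec) {
  data.frame(
    name = c("age", "sex",
             paste0("prs_", names(spec$diseases)),
             paste0("gpc", seq_len(spec$n_pcs_global)),
             paste0("pc", seq_len(spec$n_pcs_local)),
             paste0("met", seq_len(spec$n_metabolites))),
    type = c("demographic", "demographic",
             rep("prs", length(spec$diseases)),
             rep("pc_global", spec$n_pcs_global),
             rep("pc_local", spec$n_pcs_local),
             rep("metabolite", spec$n_metabolites)),
    stringsAsFactors = FALSE
  )
}

validate_effect_columns <- function(spec) {
  cols <- spec_column_meta(spec)$name
  anc <- names(spec$ancestry_proportions)
  for (d in spec$diseases) {
    own_prs <- paste0("prs_", d$name)
    check <- function(nms, what) {
      bad <- setdiff(nms, cols)
      if (length(bad)) stop("disease ", d$name, ": ", what,
                            " references unknown column(s): ",
                            paste(bad, collapse = ", "))
      foreign <- grep("^prs_", nms, value = TRUE)
      foreign <- setdiff(foreign, own_prs)
      if (length(foreign)) stop("disease ", d$name, ": effects may only use ",
                                "its own PRS column, not ",
                                paste(foreign, collapse = ", "))
    }
    check(names(d$shared_effects), "shared_effects")
    for (a in names(d$ancestry_specific_effects)) {
      if (!a %in% anc) stop("disease ", d$name,
                            ": ancestry_specific_effects for unknown ancestry ", a)
      check(names(d$ancestry_specific_effects[[a]]), "ancestry_specific_effects")
    }
    if (length(d$interaction_effects)) {
      pairs <- strsplit(names(d$interaction_effects), ":", fixed = TRUE)
      if (any(lengths(pairs) != 2)) {
        stop("disease ", d$name, ": interaction names must be 'colA:colB'")
      }
      check(unique(unlist(pairs)), "interaction_effects")
    }
    tp <- d$target_prevalence
    if (!is.null(names(tp)) && any(nzchar(names(tp)))) {
      bad <- setdiff(names(tp), anc)
      if (length(bad)) stop("disease ", d$name,
                            ": target_prevalence for unknown ancestry ",
                            paste(bad, collapse = ", "))
    }
  }
  invisible(spec)
}

# Largest-remainder apportionment of n into round(n * prop) counts that sum
# exactly to n; ties broken by position.
largest_remainder_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

#' Calibrate an intercept to a target prevalence
#'
#' Finds the intercept `c` with `mean(plogis(c + lp)) == target` by monotone
#' root finding; the mean of a sigmoid is strictly increasing in `c`, so the
#' root is unique.
#'
#' @param linear_predictors numeric vector of liabilities (without intercept).
#' @param target_prevalence target fraction in (0, 1).
#' @param tol absolute tolerance on the achieved prevalence.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(linear_predictors, target_prevalence, tol = 1e-8) {
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target prevalence must be in (0, 1)")
  }
  if (!all(is.finite(linear_predictors))) stop("non-finite linear predictors")
  f <- function(c) mean(plogis(c + linear_predictors)) - target_prevalence
  uniroot(f, lower = -50, upper = 50, extendInt = "upX", tol = tol)$root
}

# Liability (log-odds scale, no intercept) for one disease given features.
# Two passes: PRS-free terms first (used to generate the PRS column), then
# terms referencing the disease's own PRS.
disease_liability <- function(d, X, ancestry, include_prs_terms = TRUE) {
  own_prs <- paste0("prs_", d$name)
  lp <- numeric(nrow(X))
  add_main <- function(lp, eff, rows = NULL) {
    for (nm in names(eff)) {
      if (!include_prs_terms && nm == own_prs) next
      if (is.null(rows)) lp <- lp + eff[[nm]] * X[, nm]
      else lp[rows] <- lp[rows] + eff[[nm]] * X[rows, nm]
    }
    lp
  }
  lp <- add_main(lp, d$shared_effects)
  for (a in names(d$ancestry_specific_effects)) {
    lp <- add_main(lp, d$ancestry_specific_effects[[a]], rows = which(ancestry == a))
  }
  if (length(d$interaction_effects)) {
    pairs <- strsplit(names(d$interaction_effects), ":", fixed = TRUE)
    for (k in seq_along(pairs)) {
      ab <- pairs[[k]]
      if (!include_prs_terms && own_prs %in% ab) next
      lp <- lp + d$interaction_effects[[k]] * X[, ab[1]] * X[, ab[2]]
    }
  }
  lp
}

# Feature matrix (everything except PRS columns, which are filled later).
generate_features <- function(spec, ancestry) {
  n <- length(ancestry)
  meta <- spec_column_meta(spec)
  X <- matrix(0, n, nrow(meta), dimnames = list(NULL, meta$name))
  X[, "age"] <- rnorm(n)
  X[, "sex"] <- rbinom(n, 1, 0.5)
  anc_codes <- names(spec$ancestry_proportions)
  # global PCs: ancestry centroids (+2.5 on one axis per non-reference
  # ancestry) + isotropic noise; gpc4 additionally carries a two-cluster
  # within-ancestry substructure when available
  for (k in seq_len(spec$n_pcs_global)) {
    X[, paste0("gpc", k)] <- rnorm(n)
  }
  for (a in seq_along(anc_codes)[-1]) {
    dim_k <- a - 1
    if (dim_k <= spec$n_pcs_global) {
      rows <- ancestry == anc_codes[a]
      X[rows, paste0("gpc", dim_k)] <- X[rows, paste0("gpc", dim_k)] + 2.5
    }
  }
  if (spec$n_pcs_global >= 4) {
    subgroup <- rbinom(n, 1, 0.5)
    X[, "gpc4"] <- X[, "gpc4"] + (subgroup - 0.5) * 2
  }
  for (k in seq_len(spec$n_pcs_local)) X[, paste0("pc", k)] <- rnorm(n)
  rho <- spec$metabolite_block_correlation
  col0 <- 0
  for (b in spec$metabolite_block_sizes) {
    f <- rnorm(n)
    block <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * b), n, b)
    X[, paste0("met", col0 + seq_len(b))] <- block
    col0 <- col0 + b
  }
  X
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: ancestry labels by largest-remainder
#' apportionment, features (standardized age, 0/1 sex, ancestry-separating
#' global PCs with within-ancestry substructure on gpc4, local PCs,
#' exchangeably correlated metabolite blocks), per-disease PRS columns
#' correlated with the PRS-free liability, and binary outcomes drawn from a
#' logistic liability model whose intercept is calibrated per ancestry so
#' realized prevalence matches the target.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort` with elements `X`, `column_meta`,
#'   `ancestry`, `Y` (n x n_diseases), `truth` (liabilities and calibrated
#'   intercepts) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  anc_codes <- names(spec$ancestry_proportions)
  counts <- largest_remainder_counts(spec$n_total, spec$ancestry_proportions)
  ancestry <- rep(anc_codes, counts)
  with_seed(spec$seed, {
    X <- generate_features(spec, ancestry)
    D <- length(spec$diseases)
    n <- spec$n_total
    Y <- matrix(0L, n, D, dimnames = list(NULL, names(spec$diseases)))
    liab <- matrix(0, n, D, dimnames = list(NULL, names(spec$diseases)))
    intercepts <- matrix(NA_real_, length(anc_codes), D,
                         dimnames = list(anc_codes, names(spec$diseases)))
    for (d in spec$diseases) {
      lp_pre <- disease_liability(d, X, ancestry, include_prs_terms = FALSE)
      rho <- d$prs_liability_correlation
      noise <- rnorm(n)
      prs <- if (sd(lp_pre) > 1e-12 && rho > 0) {
        rho * as.numeric(scale(lp_pre)) + sqrt(1 - rho^2) * noise
      } else {
        noise
      }
      X[, paste0("prs_", d$name)] <- prs
      lp <- disease_liability(d, X, ancestry, include_prs_terms = TRUE)
      tp <- d$target_prevalence
      u <- runif(n)
      for (a in anc_codes) {
        rows <- ancestry == a
        target <- if (length(tp) == 1 && is.null(names(tp))) tp else tp[[a]]
        if (is.null(target) || is.na(target)) {
          stop("disease ", d$name, ": no target prevalence for ancestry ", a)
        }
        int_a <- tryCatch(calibrate_intercept(lp[rows], target),
                          error = function(e) {
                            stop("disease ", d$name, ", ancestry ", a,
                                 ": prevalence calibration failed (",
                                 conditionMessage(e), ")")
                          })
        intercepts[a, d$name] <- int_a
        pr <- plogis(int_a + lp[rows])
        Y[rows, d$name] <- as.integer(u[rows] < pr)
        liab[rows, d$name] <- int_a + lp[rows]
      }
    }
    structure(list(X = X, column_meta = spec_column_meta(spec),
                   ancestry = ancestry, Y = Y,
                   truth = list(liability = liab, intercepts = intercepts),
                   spec = spec),
              class = "cohort")
  })
}

#' Monte-Carlo Bayes AUC for one disease and ancestry
#'
#' Upper-bound reference for fitted-model discrimination: the AUC of the true
#' liability score against outcomes simulated from it, within one ancestry.
#'
#' @param spec a [cohort_spec()].
#' @param disease disease code present in the spec.
#' @param ancestry ancestry code present in the spec.
#' @param n_mc Monte-Carlo sample size.
#' @param seed seed for the Monte-Carlo draw (default: spec seed + 1).
#' @return List with `auc`, `se` (DeLong standard error) and `n_mc`.
#' @export
bayes_auc <- function(spec, disease, ancestry, n_mc = 20000, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!disease %in% names(spec$diseases)) stop("unknown disease: ", disease)
  if (!ancestry %in% names(spec$ancestry_proportions)) {
    stop("unknown ancestry: ", ancestry)
  }
  sub <- spec
  sub$n_total <- as.integer(n_mc)
  sub$ancestry_proportions <- stats::setNames(1, ancestry)
  # keep only effects applicable to this ancestry
  sub$seed <- as.integer(seed %||% (spec$seed + 1))
  coh <- generate_cohort(sub)
  score <- coh$truth$liability[, disease]
  y <- coh$Y[, disease]
  if (length(unique(y)) < 2) stop("degenerate Monte-Carlo outcome draw")
  pl <- placement_values(score, y)
  a <- mean(pl$v10)
  se <- sqrt(var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01))
  list(auc = a, se = se, n_mc = as.integer(n_mc))
}

#' Write a cohort to delimited text with a JSON sidecar
#'
#' The table (tab-delimited; `.gz` paths are compressed transparently) holds
#' `ancestry`, one `Y_<disease>` column per disease, then the features. The
#' sidecar (same path with extension `.json`) records column names/types,
#' ancestry levels and disease codes.
#'
#' @param cohort a `cohort`.
#' @param path destination `.tsv` or `.tsv.gz` path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  tab <- data.frame(ancestry = cohort$ancestry,
                    stats::setNames(as.data.frame(cohort$Y),
                                    paste0("Y_", colnames(cohort$Y))),
                    as.data.frame(cohort$X), check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(columns = cohort$column_meta,
                  ancestry_levels = unique(cohort$ancestry),
                  diseases = colnames(cohort$Y),
                  n = nrow(cohort$X))
  jsonlite::write_json(sidecar, sidecar_path(path), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tsv(\\.gz)?$", ".json", path)

#' Read a cohort written by [write_cohort()]
#'
#' @param path the `.tsv` or `.tsv.gz` path (sidecar located automatically).
#' @return A `cohort` object (without generator provenance).
#' @export
read_cohort <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("metadata sidecar not found: ", sc)
  meta <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                   error = function(e) stop("malformed metadata sidecar: ",
                                            conditionMessage(e)))
  if (is.null(meta$columns) || is.null(meta$diseases)) {
    stop("malformed metadata sidecar: missing 'columns' or 'diseases'")
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty cohort: table has 0 rows")
  missing_cols <- setdiff(meta$columns$name, colnames(tab))
  if (length(missing_cols)) {
    stop("metadata names column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  ycols <- paste0("Y_", meta$diseases)
  if (!all(ycols %in% colnames(tab))) {
    stop("outcome column(s) absent from the table: ",
         paste(setdiff(ycols, colnames(tab)), collapse = ", "))
  }
  Y <- as.matrix(tab[, ycols, drop = FALSE])
  colnames(Y) <- meta$diseases
  if (!all(Y %in% c(0, 1))) stop("outcome entries must be 0/1")
  X <- as.matrix(tab[, meta$columns$name, drop = FALSE])
  storage.mode(X) <- "double"
  structure(list(X = X,
                 column_meta = as.data.frame(meta$columns),
                 ancestry = as.character(tab$ancestry),
                 Y = Y, truth = NULL, spec = NULL),
            class = "cohort")
}
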