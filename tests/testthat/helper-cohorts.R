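# Shared synthetic-cohort fixtures, built in code.

# Minimal two-ancestry cohort spec with a planted interaction and an
# ancestry-specific metabolite effect.
toy_spec <- function(n = 2000, seed = 1, wb = 0.8,
                     prev = c(WB = 0.10, SA = 0.22)) {
  ds <- disease_spec(
    "DIA", target_prevalence = prev,
    shared_effects = c(age = 0.4, met1 = 0.5, met6 = 0.3,
                       prs_DIA = 0.5, gpc1 = 0.2),
    ancestry_specific_effects = list(SA = c(met11 = 0.7)),
    interaction_effects = c("prs_DIA:gpc4" = 0.5, "age:met6" = 0.3))
  cohort_spec(n, c(WB = wb, SA = 1 - wb), list(ds),
              n_metabolites = 15, n_pcs_global = 5, n_pcs_local = 2,
              seed = seed)
}

# Spec with no effects at all: outcomes carry no signal.
null_spec <- function(n = 2000, seed = 1) {
  ds <- disease_spec("DIA", target_prevalence = c(WB = 0.15, SA = 0.15),
                     prs_liability_correlation = 0)
  cohort_spec(n, c(WB = 0.7, SA = 0.3), list(ds),
              n_metabolites = 10, n_pcs_global = 4, n_pcs_local = 2,
              seed = seed)
}

# Random dense logistic test problem on a standardized design.
random_problem <- function(n, p, seed, signal = 2) {
  set.seed(seed)
  X <- standardize_1n(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("x", seq_len(p))
  k <- max(1, round(p / 3))
  beta <- c(runif(k, -signal, signal), rep(0, p - k))
  y <- rbinom(n, 1, plogis(X %*% beta))
  if (all(y == y[1])) y[1] <- 1 - y[1]
  list(X = X, y = y, beta = beta)
}
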