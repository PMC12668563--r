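# Preset cohort specification emulating a UK-Biobank-like multiomics cohort:
# five ancestry groups with strong imbalance, eight common diseases with
# per-ancestry case rates taken from the published cohort breakdown, a
# metabolite-dominated feature block, and per-disease PRS columns.

# cases / totals per ancestry and disease (published cohort breakdown)
biobank_case_table <- function() {
  diseases <- c("DIA", "MI", "AST", "GS", "OST", "ART", "CYS", "CRF")
  cases <- rbind(
    WB  = c(5479, 3234, 10909, 4103, 7579, 4969, 2725, 2862),
    SA  = c(460, 151, 285, 69, 101, 122, 56, 93),
    AF  = c(232, 30, 201, 36, 86, 103, 24, 83),
    AD  = c(632, 268, 932, 285, 492, 379, 234, 213),
    NBE = c(419, 197, 768, 262, 433, 279, 178, 165))
  colnames(cases) <- diseases
  totals <- c(WB = 80810, SA = 1911, AF = 1499, AD = 6783, NBE = 5910)
  list(cases = cases, totals = totals, diseases = diseases)
}

#' Biobank-like cohort specification
#'
#' A ready-made [cohort_spec()] emulating the structure of a large
#' multi-ancestry biobank cohort: five ancestry groups (White British
#' majority plus South Asian, African, Admixed and non-British European
#' minorities, proportions taken from the published cohort breakdown),
#' eight common diseases with per-ancestry target prevalences equal to the
#' published case rates, and a feature block dominated by correlated
#' metabolites with global/local genotype PCs and per-disease PRS. Outcome
#' models combine shared main effects (metabolites, age, sex, PRS, PCs),
#' ancestry-specific metabolite effects, and interactions of PRS/age/sex
#' with other features — the structure the interaction and pretraining
#' models are designed to exploit.
#'
#' @param n_total cohort size (the published cohort has 96,913 rows; smaller
#'   values keep the same proportions).
#' @param seed generator seed.
#' @param n_metabolites,n_pcs_global,n_pcs_local feature-block sizes
#'   (defaults 243 / 40 / 10, giving p = 303 with age, sex and 8 PRS;
#'   minimums 30 / 5 / 1 so the preset effects always reference existing
#'   columns).
#' @param diseases optional subset of
#'   `c("DIA","MI","AST","GS","OST","ART","CYS","CRF")`.
#' @return A [cohort_spec()].
#' @export
biobank_spec <- function(n_total = 96913, seed = 1, n_metabolites = 243,
                         n_pcs_global = 40, n_pcs_local = 10,
                         diseases = NULL) {
  stopifnot(n_metabolites >= 30, n_pcs_global >= 5, n_pcs_local >= 1)
  tab <- biobank_case_table()
  keep <- diseases %||% tab$diseases
  stopifnot(all(keep %in% tab$diseases))
  props <- tab$totals / sum(tab$totals)
  prev <- sweep(tab$cases, 1, tab$totals, "/")

  eff <- list(
    DIA = list(shared = c(age = 0.35, sex = -0.1, prs_DIA = 0.5, met1 = 0.5,
                          met6 = 0.3, met12 = 0.3, met22 = -0.25, gpc1 = 0.15),
               spec = list(SA = c(met11 = 0.45), AF = c(met3 = 0.3)),
               inter = c("prs_DIA:gpc4" = 0.4, "age:met6" = 0.2)),
    MI  = list(shared = c(age = 0.5, sex = 0.3, prs_MI = 0.45, met2 = 0.45,
                          met7 = 0.3, met15 = -0.3, gpc2 = 0.1),
               spec = list(AD = c(met9 = 0.35)),
               inter = c("age:met2" = 0.25)),
    AST = list(shared = c(age = -0.15, sex = -0.1, prs_AST = 0.5, met4 = 0.4,
                          met13 = 0.3, met25 = 0.2),
               spec = list(SA = c(met14 = 0.4)),
               inter = c("age:met13" = 0.3, "prs_AST:gpc4" = 0.25)),
    GS  = list(shared = c(age = 0.3, sex = -0.35, prs_GS = 0.5, met5 = 0.45,
                          met16 = 0.3, gpc1 = 0.1, gpc2 = 0.1),
               spec = list(AD = c(met8 = 0.5)),
               inter = c("prs_GS:age" = 0.3)),
    OST = list(shared = c(age = 0.6, sex = 0.25, prs_OST = 0.4, met10 = 0.35,
                          met18 = 0.25),
               spec = list(SA = c(met19 = 0.35)),
               inter = c("sex:met10" = 0.2)),
    ART = list(shared = c(age = 0.45, sex = 0.2, prs_ART = 0.55, met17 = 0.4,
                          met21 = 0.3, met28 = -0.25),
               spec = list(SA = c(met20 = 0.4), AF = c(met23 = -0.4)),
               inter = c("prs_ART:gpc4" = 0.5, "sex:met21" = 0.2)),
    CYS = list(shared = c(age = 0.2, sex = -0.5, prs_CYS = 0.4, met24 = 0.35,
                          met29 = 0.25),
               spec = list(AF = c(met26 = 0.35)),
               inter = c("age:met24" = 0.2)),
    CRF = list(shared = c(age = 0.5, sex = 0.15, prs_CRF = 0.45, met27 = 0.5,
                          met30 = 0.35, gpc3 = 0.1),
               spec = list(SA = c(met2 = 0.3)),
               inter = c("prs_CRF:met27" = 0.25)))

  specs <- lapply(keep, function(d) {
    e <- eff[[d]]
    disease_spec(d, target_prevalence = prev[, d],
                 shared_effects = e$shared,
                 ancestry_specific_effects = e$spec,
                 interaction_effects = e$inter,
                 prs_liability_correlation = 0.5)
  })
  cohort_spec(n_total, props, specs,
              n_metabolites = n_metabolites, n_pcs_global = n_pcs_global,
              n_pcs_local = n_pcs_local,
              metabolite_block_correlation = 0.5, seed = seed)
}
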