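---
title: "Ancestry-aware disease prediction: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-aware disease prediction: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Risk-prediction models trained predominantly on European-ancestry cohorts
often transfer poorly to under-represented ancestries. This package studies
one concrete remedy space on multiomic cohort data: compare a baseline
L1-penalized logistic regression against two structured alternatives — a
group-lasso interaction model (glinternet-style) and a two-stage pretrained
lasso — across training sets that pool all ancestries ("All"), mix the
majority with one minority ancestry ("Mix"), or use one ancestry alone
("Specific"), evaluating each per ancestry with paired ROC comparisons.

Because the cohort that motivates this design is access-restricted, the
package ships a synthetic cohort generator with the statistical structure
the analysis needs (imbalanced ancestries, correlated metabolite blocks,
ancestry-separating genotype PCs, per-disease polygenic scores, and
ancestry-specific effects and interactions), so that every stage is testable
end to end. The repository is organised as an analysis workflow: the
package under `R/` holds every computation, the numbered scripts under
`analysis/` are thin narrative drivers writing their tables to `results/`.

## The three model families

**Baseline.** L1-penalized logistic regression
$$\min_{\mu,\beta}\; -\tfrac1n \ell(\mu,\beta) + \lambda \sum_j pf_j\,|\beta_j|,$$
where the linear predictor is $o_i + \mu + x_i^\top\beta$ with a fixed
per-observation offset $o$ and per-feature penalty factors $pf_j \ge 0$
($0$ = unpenalized, $\infty$ = excluded). We use the *average*
log-likelihood convention so $\lambda$ does not scale with $n$; an
objective written with the summed likelihood differs only by relabelling
$\lambda$. The path starts at
$\lambda_{\max} = \max_j |x_j^\top(y - \hat p^0)|/(n\,pf_j)$ (standardized
columns, $\hat p^0$ from the offset-only model), where all penalized
coefficients are exactly zero.

**Interaction model.** First-order interactions under a strong hierarchy:
an interaction $\theta_{i:j}$ may be nonzero only if both main effects are
in the model. Candidate pairs are restricted to four covariates — age, sex,
ancestry and the trained disease's PRS — crossed with every other variable.
The fit solves a group-lasso-penalized logistic objective
$\min -\tfrac1n\ell + \lambda\sum_g \gamma_g \lVert\theta_g\rVert_2$ with
$\gamma_g = \sqrt{|g|}$.

Two group structures are implemented because the usual textual description
of the grouping is ambiguous:

* `per_pair` (default): each interaction group contains *copies* of both
  parent main effects plus the product column, handled by the latent
  (duplicated-variable) overlap formulation; the model's main effect is the
  sum of the copies. This guarantees the strong hierarchy on every fit and
  matches the semantics of the original glinternet estimator.
* `per_variable`: the literal reading
  $G_i = \{\text{main } i\} \cup \{X_{i:j}: j > i\}$, a partition with no
  duplication. Its hierarchy guarantee is weaker (an interaction implies
  its *owning group* is active), and it is kept as a documented option.

One-hot ancestry interacts as a block: a pair (ancestry, $v$) expands to
one product per ancestry level, all in one group. Product columns are
formed from standardized parents and then standardized again (declared
convention). No screening is applied: the four-candidate restriction
already bounds the design.

**Pretrained lasso.** A two-stage transfer procedure with mixing parameter
$\alpha \in [0,1]$:

1. fit a pooled cross-validated lasso; keep $\hat\beta^0$, $\hat\mu^0$ and
   the support $S$ at the CV-minimizing $\lambda$;
2. per ancestry $k$, fit a lasso with offset
   $(1-\alpha)(X_k\hat\beta^0 + \hat\mu^0)$ and penalty factors
   $pf_j = (1-\alpha)\,[\,I(j\notin S)/\alpha + I(j\in S)\,]$, choosing
   $\lambda$ by the group's own 3-fold CV.

At $\alpha = 0$ off-support features are excluded ($pf=\infty$) and the
second stage can only re-weight the pooled support; at $\alpha = 1$ the
printed formula zeroes every penalty factor, i.e. a literally unpenalized
second stage. Under the default mean-one penalty-factor normalization an
all-equal vector rescales to ones, so $\alpha = 1$ recovers an ordinary
per-ancestry lasso — we ship both behaviours and default to
normalization-on, which reconciles the formula with standard lasso-software
semantics. The value of $\alpha$ used in the motivating study is not
reported; the default here is $\alpha = 0.5$, with `set_alpha()` supporting
a sweep over $\{0, 0.25, 0.5, 0.75, 1\}$ from one stage-1 fit.

## Solvers and numerical choices

Both penalized fits use a majorize–minimize scheme written for this
package: the logistic Hessian is globally dominated by $0.25\,X^\top X/n$,
so re-expanding a curvature-0.25 quadratic at the current linear predictor
and sweeping coordinates (or blocks, with per-group curvature bound
$0.25\,\lambda_{\max}(Z_g^\top Z_g/n)$ and group soft-thresholding
$\theta_g \leftarrow u_g\,(1 - \lambda\gamma_g/\lVert u_g\rVert)_+ / H_g$)
decreases the true penalized objective at every sweep. Consequences that
the test suite checks: monotone objectives, KKT residuals below $10^{-5}$,
and objective values within $10^{-6}$ of generic convex-optimizer oracles.

Further conventions:

* convergence at maximum standardized-scale coefficient change
  $< 10^{-7}$ (path fits), $10^5$ iteration cap; coefficients below
  $10^{-10}$ are snapped to exact zero;
* $\lambda$ grids: 100 log-spaced points for the lasso with
  $\lambda_{\min}/\lambda_{\max} = 10^{-2}$ when $n < p$ and $10^{-4}$
  otherwise (declared defaults — the motivating study does not state its
  grid); 50 points with ratio 0.05 for the interaction model;
* standardization is internal (unit 1/n-variance of penalized columns);
  coefficients are reported on the original scale, interaction networks on
  the standardized scale;
* penalty factors are rescaled to mean one over their finite entries
  (switch `normalize_pf = FALSE` for the literal scale);
* cross-validation folds are stratified by class, sized within one row of
  each other, and seeded; the loss is held-out mean binomial deviance.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` draw cohorts with:

* ancestry labels by largest-remainder apportionment of the requested
  proportions (deterministic, sums exactly);
* standardized age, 0/1 sex; global genotype PCs as per-ancestry centroids
  (+2.5 on one axis per non-reference ancestry) plus unit noise, with a
  two-cluster within-ancestry substructure on `gpc4` so that a PRS-by-PC4
  interaction has a realistic carrier; local PCs as pure noise;
* metabolite blocks with exchangeable (compound-symmetry) correlation
  $\rho = 0.5$ by default — the simplest structure producing the
  collinearity that motivates group selection;
* per-disease PRS columns correlated (default 0.5) with the PRS-free
  liability;
* outcomes drawn from a logistic liability combining shared main effects,
  ancestry-specific main effects and pairwise interactions, with the
  intercept calibrated per ancestry by monotone root finding so realized
  prevalence matches the target to $10^{-6}$ in expectation.

`biobank_spec()` is a preset with five ancestry groups at the published
cohort's proportions, eight diseases at the published per-ancestry case
rates (the printed case table is used as input), and a default layout of
243 metabolites, 40 global and 10 local PCs — p = 303 with age, sex and the
eight PRS columns. Effect magnitudes are this package's own choices (the
motivating study reports no per-feature effect sizes): main effects of
0.1–0.6 on the liability scale, interactions of 0.2–0.5, yielding
per-ancestry Bayes AUCs around 0.8 — the range a well-powered multiomics
model typically reaches. `bayes_auc()` reports the Monte-Carlo AUC of the
true liability, the ceiling for any fitted model.

What the generator deliberately does **not** emulate: linkage
disequilibrium or any real genotype process (PRS is an abstract correlated
score, as consumed — not computed — by the analysis), missing data,
measurement batch effects, or cross-disease outcome dependence (outcomes
are independent given features). Passing tests therefore demonstrate
correctness of the estimators and pipeline on cohorts with this idealized
structure, not performance claims about any real biobank.

## Evaluation and the study design

ROC-AUC is the tie-corrected Mann–Whitney statistic (mid-rank convention
throughout). Paired models are compared with a DeLong test from placement
values, one-sided by default in the direction "candidate model improves on
the baseline" — the directional hypothesis of the study design — with
significance annotated `*` (p < 0.05) and `**` (p < 0.01) and no
multiple-testing correction by default. Degenerate-variance cases are
flagged: identical curves give p = 0.5 by convention.

`run_study()` performs, per disease: one stratified 80/20 train/test split
(ancestry × outcome, so minority cases land on both sides); baseline lasso
on Specific, Mix and All training rows; glinternet and pretrained lasso on
Mix and All (3 + 2 + 2 = 7 combinations); evaluation of every model on each
focal ancestry's held-out rows; and DeLong comparisons only within matching
training datasets. The split is made once on the full cohort and dataset
configurations select rows within it, so all models of a disease share one
paired test set. Only the trained disease's PRS column enters the design
(other diseases' PRS are excluded as a leakage guard; the motivating text
is ambiguous and this is the conservative reading). Ancestries with fewer
than 20 positive cases for a disease are skipped, mirroring the full-size
study's eligibility rule. Three named seeds (generation, split, CV) make
runs bit-reproducible.

The win-count meta-analysis treats each result column's best AUC as one
Bernoulli trial with success probability proportional to a method's share
of trained combinations, and tests observed wins with an *exact* binomial
upper tail — with only 24 columns at full scale a normal approximation is
avoidable, so the exact test is the declared choice.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen once: the analysis
scripts simulate n = 12,000 with 30 metabolites, 6 global and 2 local PCs
(p = 48); solver-correctness checks use n ≤ 200, p ≤ 20 against convex
oracles; recovery batteries use n = 2,000–3,000 with 20 seeds; the
end-to-end comparison battery runs 20 seeded studies at n = 2,500. The
full-size preset (n = 96,913, p = 303) is available but not exercised by
the tests.

## Known limitations

* The group solver's fixed curvature bound is conservative near
  well-separated fits; paths with hundreds of candidate variables are
  noticeably slower than the specialised original implementation.
* The per-variable grouping mode trades away the strong-hierarchy
  guarantee; it exists for comparability, not as the recommended estimator.
* DeLong inference uses the normal approximation; with very few positive
  cases (near the 20-case eligibility floor) p-values are coarse.
* The generator's PCs encode ancestry by construction; models can therefore
  partially read ancestry off PCs even in "Specific" datasets, which real
  within-ancestry PCs would not provide to the same degree.
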