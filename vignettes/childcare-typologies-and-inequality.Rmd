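---
title: "Childcare typologies, mental health inequalities, and hypothetical universal-childcare scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Childcare typologies, mental health inequalities, and hypothetical universal-childcare scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careseq)
```

## The scientific question

Socioeconomic inequalities in child mental health are visible by the start
of primary school. Early-years childcare is one of the few policy levers
that reaches essentially all children, so a natural question is whether
universal provision of a particular childcare *type* before age three
would widen or narrow those inequalities. careseq implements the full
analysis pipeline for this question on longitudinal cohort data:

1. the *exposure* A is maternal education in infancy (four levels, Degree
   down to lower-level Standard Grades or none);
2. the *mediator* M is a typology of longitudinal childcare use, built by
   clustering each child's sequence of main childcare provision over four
   survey sweeps (10 months, 2, 3 and 4 years) across a seven-state
   alphabet;
3. the *outcome* Y is a binary "raised" Strengths and Difficulties
   Questionnaire Total Difficulties score at the start of school;
4. marginal structural models with inverse-probability-of-treatment
   weights (IPTW) estimate the average treatment effect (ATE) of maternal
   education on Y, and controlled direct effects (CDE) in hypothetical
   scenarios where every child's mediator is fixed at one typology
   (universal private group childcare; universal single-professional
   care).

Because the cohort that motivates this pipeline is confidential, the
package ships a synthetic-cohort generator calibrated so that every
published headline quantity is *planted* in the simulated population.
All testing is parameter recovery: the pipeline must re-estimate from
synthetic data the values the generator was calibrated to.

## The synthetic cohort generator

`generate_cohort()` draws, per child:

* **education** from the analytic-sample distribution
  (26.6/31.9/26.0/15.4%);
* **confounders given education**: baseline confounders (child ethnicity,
  mother's age at first birth) and intermediate confounders (maternal
  attachment on the 8–48 scale, maternal mental health at sweeps 1 and 5
  on the 0–100 SF-12 scale, child general health, maternal employment,
  family composition, significant life events), plus covariates (sex,
  school adjustment). Confounders are mutually independent given
  education; their education gradients are not published, so the defaults
  are realistic values for a UK birth cohort, chosen once (see
  `default_confounders()`). They create genuine confounding that the
  weighting estimators must remove.
* **latent typology given education** from a 4x4 mixing matrix whose
  education gradients reproduce the published typology-membership odds
  ratios and whose intercepts are solved so the marginal prevalences are
  35.8/32.7/23.5/8.1% (parents/friends/family, grandparents, private
  group, single professional);
* **childcare states**: each typology has a canonical path (e.g.
  grandparent care at sweeps 1–3, then a local-authority universal place
  at sweep 4); with probability `emission_noise` (default 0.1) per sweep
  the state is replaced by a uniformly drawn other state. Within-typology
  heterogeneity in the source data is richer than independent per-sweep
  noise; the noise parameter is a deliberate simplification, so passing
  tests show recovery of a noisy mixture of canonical paths, not of
  arbitrary real-world sequence heterogeneity.
* **outcome**: a latent logistic score with education, typology,
  education x typology and confounder effects, thresholded at 0. The
  published analysis dichotomises a validated questionnaire cut-point
  that is not printed; the binary outcome, not the cut-point, is the
  contract.
* **weights and attrition**: gamma(20, 20) survey design weights
  (mean 1), and a logistic retention model (education, life events,
  family composition) whose intercept is solved for 61% marginal
  retention. `apply_attrition()` keeps retained children and multiplies
  design weights by inverse retention probabilities, so weighted
  analytic marginals match the baseline cohort — the synthetic analogue
  of combined sampling and response weights.

`n_children` (default 3205) is the target *analytic* size;
`generate_cohort()` draws `round(n_children / 0.61) = 5254` baseline
children so the complete-case subset lands at the published analytic
scale. The random stream is split per variable block, so adding a
confounder never perturbs earlier draws.

### Calibration

The free constants — three typology-mixing intercepts, the retention
intercept, and the 13 outcome coefficients (intercept, three education
log-odds, three typology log-odds, six interaction log-odds) — are solved
once by `data-raw/calibrate.R` and stored in
`inst/extdata/calibration.yaml`, which `default_calibration()` reads.
The solver computes each implied quantity by marginalising the logistic
model over the confounder distribution (Monte-Carlo with 200,000 common
random draws per education level, so the objective is smooth and the
solve deterministic) and minimises squared log-scale residuals against:

* marginal raised-TD prevalence 10.9%;
* ATE odds ratios 1.352 / 2.596 / 3.181 (vs Degree), defined on the
  interventional population (baseline confounders at their marginal
  distribution, intermediate confounders and mediator following the
  education level under intervention);
* CDE odds ratios 2.164 / 3.600 / 3.778 with the mediator fixed at
  private group childcare, and 0.713 / 1.782 / 2.420 fixed at single
  professional care;
* covariate-standardised typology risk ratios 1.052 / 0.832 / 0.770.

The system is 13 equations in 13 unknowns and solves to residuals below
1e-6. A calibration that cannot reach its targets within 1e-3 raises an
error rather than clipping.

## Sequence analysis and typology construction

`om_distance()` is the classical optimal-matching edit distance: the
minimum total cost of substitutions and insertions/deletions transforming
one state sequence into the other, by dynamic programming (implemented in
C++ for the all-pairs case). The source analysis does not state its cost
scheme; the default is the conventional constant substitution cost 2 with
indel cost 1, and a transition-rate-based substitution matrix is
available via `transition_cost_scheme()`. With equal-length sequences
indels are never forced, but they stay enabled because a one-position
shift (one deletion plus one insertion, cost 2) can beat two
substitutions (cost 4). With substitution cost at twice the indel cost
the distance is a pseudometric, verified property-style in the tests
against an exhaustive-enumeration oracle.

`assign_typologies()` aggregates identical sequences (summing analysis
weights), computes pairwise distances between unique sequences, and runs
Ward-criterion agglomeration with observation weights via the weighted
Lance–Williams update (`stats::hclust` with `members`). Aggregation
makes the procedure exactly invariant to input order (unique sequences
are sorted lexicographically) and fast enough to re-cluster hundreds of
replicates. Cutting at k = 4 and naming each cluster by its weighted
modal state over sweeps 1–3 — the pre-universal-entitlement period where
nearly all variation lives — yields the four named typologies; `None`
and `FamilyFriends` both map to "Parents, friends & family". Naming
collisions fall back deterministically to the next most frequent state,
heavier cluster first. `cluster_quality_range()` (weighted average
silhouette width, within/total dissimilarity ratio) supports the choice
of k, and `bootstrap_stability()` reports, per reference cluster, the
mean maximum Jaccard overlap with clusters of weighted bootstrap
resamples; the exact bootstrap validation statistic of the source
analysis is not recoverable, so this standard Jaccard scheme is used and
named. Degenerate cases are defined explicitly: identical points give
silhouette 0 by convention, and a cluster emptied in a resample scores
overlap 0.

## Inequality models

`fit_weighted_multinomial()` quantifies inequalities in typology
membership: a baseline-category multinomial logit (reference "Parents,
friends & family"; education reference Degree; adjusted for ethnicity)
fitted by weighted maximum likelihood, with Horvitz–Thompson-type
model-robust variances — the HC0 sandwich with the analysis weights in
both bread and meat, built from the per-observation multinomial scores.
Empty exposure x typology cells raise an error naming the cell.
`fit_modified_poisson_rr()` estimates typology -> outcome risk ratios by
log-link quasi-Poisson regression of the binary outcome with sandwich
variances, at three adjustment presets: unadjusted; *partial* (baseline
measurements of the intermediate confounders only, guarding against
overadjustment); *full* (adding the time-varying composites). Only
analysis weights are honoured: the source cohort's strata and clusters
are confidential, so no PSU/stratum machinery is offered, and sandwich
variances treat children as independent.

## Marginal structural models

`fit_exposure_propensity()` models education on the baseline confounders
(multinomial), with an intercept-only stabilisation numerator;
`fit_mediator_propensity()` models the typology on education plus
baseline and intermediate confounders, stabilised by the
education-conditional numerator. `compose_weights()` multiplies design
weights by the stabilised exposure ratio and, for CDEs, the stabilised
mediator ratio. Stabilisation is the default; truncation is off by
default (matching the deliberately wide published intervals) with
percentile winsorisation available. Weight diagnostics (min/max/mean,
effective sample size) and `covariate_balance()` (weighted standardized
mean differences, maximum pairwise across groups, unweighted pooled SD
as scale) accompany every fit.

`estimate_ate()` is the weighted logistic (quasibinomial) regression of
the outcome on education alone; `estimate_cde()` adds the typology and
the education x typology interaction, and evaluates
`exp(beta_a + delta_am)` at the scenario's fixed mediator. Confidence
intervals use the HC0 sandwich treating weights as known (the
single-stage style of the published tables); a nonparametric bootstrap
is available and agrees with the sandwich within 25% interval length on
well-populated designs. Weight-estimation uncertainty is not propagated
by default — a known limitation shared with standard practice.

## Numerical and reporting choices

* Reference levels everywhere: Degree (exposure), "Parents, friends &
  family" (mediator).
* Wald inference on the log scale throughout, matching the published
  interval style.
* Multinomial fits use tight convergence (`reltol 1e-12`) so that the
  two-category case reproduces binary logistic ML to 1e-6.
* Merge ties in the clustering are resolved by `stats::hclust`'s
  deterministic ordering on the lexicographically sorted unique
  sequences, so results are reproducible across platforms and input
  orders; observation weights are normalised to mean one (and rounded to
  10 significant digits) before agglomeration, making the partition
  exactly invariant to uniform weight rescaling — the Ward criterion is
  scale-free in the weights, but floating-point perturbations would
  otherwise reorder exact ties.
* In replicate studies, odds- and risk-ratio estimates are pooled on the
  log scale (geometric mean): ratio estimates from sparse cells are
  strongly right-skewed, and arithmetic means of ORs are inflated by
  Jensen's inequality (at the default study size the private-group CDE
  replicate log-OR spread is ~0.78, inflating the arithmetic mean by
  ~35%). The single-professional CDE is summarised by its median: with
  that typology at 8.1% prevalence and ~3% membership among the lowest
  education level, the smallest exposure x mediator cell holds ~12-15
  children, and replicates with zero outcome events there produce
  degenerate (zero) odds-ratio estimates — the synthetic counterpart of
  the very wide published interval for this scenario.

## Problem sizes

The replicate studies in the tests and the acceptance script use 200
replicates at the analytic size (~3205 children after attrition) for the
effect-recovery checks, 20 seeds for the cluster-prevalence check, and a
single cohort of 100,000 children for generator-calibration checks; these
sizes give Monte-Carlo error well inside each stated tolerance while the
whole suite runs on a single CPU in minutes.

## Known limitations

* The generator's confounders are independent given education; real
  cohort confounders are mutually correlated. A dependence structure can
  be supplied by editing `default_confounders()`, but none is calibrated.
* Emission noise is independent across sweeps, so the generator cannot
  represent state-duration heterogeneity within typologies.
* The mediator depends on confounders only through education in the
  default calibration, so mediator-weight misspecification cannot be
  studied without a custom configuration.
* Survey design is reduced to a single weight; clustering/stratification
  effects on variances are not represented.
* At the analytic scale, single-professional-scenario CDEs are extremely
  noisy (by design, faithfully to the source sample sizes): their
  replicate medians sit below the planted value because of the
  zero-event point mass, even though the estimator is consistent — at an
  analytic size of ~100,000 the same pipeline recovers the planted CDE
  to within Monte-Carlo error.

## A minimal run

```{r example, eval = FALSE}
params <- default_calibration()
baseline <- generate_cohort(params, seed = 1)
cohort <- apply_attrition(baseline, params)
seqs <- build_sequences(cohort)
typ <- assign_typologies(seqs, k = 4)
cohort <- add_typology(cohort, typ)

exp_fit <- fit_exposure_propensity(cohort)
w_ate <- compose_weights(cohort$design_weight, exp_fit)
estimate_ate(cohort, w_ate)

med_fit <- fit_mediator_propensity(cohort)
w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
estimate_cde(cohort, w_cde, scenario_spec("PrivateGroup"))
```

The numbered scripts under `analysis/` run the same stages end to end and
write every table under `results/`; `scripts/acceptance.R` repeats the
whole study across 200 seeds and reports the recovered headline
quantities.
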