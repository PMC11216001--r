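# careseq

Socioeconomic inequalities in child mental health are measurable by the
first year of school. Early-years childcare reaches nearly every child,
so the type of childcare provided universally before age three could
plausibly widen or narrow those inequalities. **careseq** implements the
complete analysis pipeline for that question, for epidemiologists and
quantitative social scientists working with longitudinal birth-cohort
data:

1. **Sequence analysis of childcare histories.** Each child's main
   childcare provision at four sweeps (10 months, 2, 3, 4 years) over a
   seven-state alphabet is a state sequence; pairwise optimal-matching
   (OM) edit distances `d(x, y) = min` total substitution/indel cost are
   computed by dynamic programming and clustered with weighted
   Ward-criterion agglomeration into childcare *typologies* — the
   mediator `M` (four groups: parents/friends/family, grandparents,
   private group childcare, single professional care), validated by
   weighted silhouettes and bootstrap Jaccard stability.
2. **Survey-weighted inequality models.** Baseline-category multinomial
   regression of typology membership on maternal education `A` (four
   levels, Degree reference) with Horvitz–Thompson-type sandwich
   variances; modified-Poisson (log-link quasi-Poisson, robust SE)
   regression of the binary raised Total Difficulties outcome `Y` on
   typology, yielding risk ratios at three adjustment presets.
3. **Marginal structural models.** With stabilized
   inverse-probability-of-treatment weights
   `w_i = design_i · P(A=a_i) / P(A=a_i | L_i)` the weighted logistic
   regression of `Y` on `A` estimates the average treatment effect
   (ATE); adding the mediator weight
   `P(M=m_i | A=a_i) / P(M=m_i | A=a_i, L_i, Z_i)` and fitting
   `Y ~ A + M + A×M` gives controlled direct effects
   `CDE(a; m) = exp(β_a + δ_am)` under hypothetical scenarios where
   everyone receives childcare type `m` (universal private group care;
   universal single-professional care).
4. **A calibrated synthetic-cohort generator.** The cohort motivating
   this design is confidential, so `default_calibration()` returns a
   generator whose population quantities are *planted* at the published
   values (typology prevalences 35.8/32.7/23.5/8.1%, raised-TD
   prevalence 10.9%, ATE OR 3.18 and CDE ORs 3.78 / 2.42 for
   lowest-vs-highest education, membership OR 0.09, adjusted RR 0.83,
   61% complete-case retention). Every downstream stage is tested as
   parameter recovery against these planted truths.

## Worked example

```r
library(careseq)

params <- default_calibration()
baseline <- generate_cohort(params, seed = 1)   # ~5250 children
cohort   <- apply_attrition(baseline, params)   # ~3205 analytic sample

seqs <- build_sequences(cohort)
typ  <- assign_typologies(seqs, k = 4)
print(typ)
#> Weighted Ward clustering: k = 4
#>   1 Grandparents                  35.1%
#>   2 Parents, friends & family     33.5%
#>   3 Private Group Childcare       22.3%
#>   4 Single Professional Care       9.1%
cohort <- add_typology(cohort, typ)

exp_fit <- fit_exposure_propensity(cohort)
w_ate   <- compose_weights(cohort$design_weight, exp_fit)
estimate_ate(cohort, w_ate)
#> MSM ATE (ESS 1850)
#>                term estimate ci_low ci_high p_value
#>        Degree (ref)     1.00   1.00    1.00      NA
#>             Highers     1.64   1.10    2.44 1.6e-02
#>      UpperStdGrades     3.32   2.27    4.84 5.0e-10
#>  LowerStdGradesNone     3.25   2.05    5.15 5.0e-07
```

The typology shares recover the planted weighted prevalences
(35.8/32.7/23.5/8.1%), and the lowest-vs-highest education odds ratio of
a raised Total Difficulties score (3.25 here; planted marginal value
3.18) is the headline inequality: after balancing baseline confounders
by IPTW, children of mothers with the lowest educational qualifications
have about three times the odds of raised difficulties. Adding the
mediator weight and the education × typology interaction
(`estimate_cde(cohort, w_cde, scenario_spec("PrivateGroup"))`) evaluates
the same contrast in the universal-childcare scenarios; in the
private-group scenario the planted inequality *widens* to 3.78, in the
single-professional scenario it *narrows* to 2.42 (with very wide
intervals — that typology holds only ~8% of children).

The numbered scripts in `analysis/` run these stages end to end
(`01_simulate.R` … `05_parameter_recovery.R`), writing every table as
CSV under `results/`.

## Repository layout

- `R/`, `src/` — package code (generator, sequences/OM/clustering,
  inequality models, MSM/CDE, pipeline orchestration).
- `data-raw/calibrate.R` — one-time solver producing
  `inst/extdata/calibration.yaml` (the planted-parameter config).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/childcare-typologies-and-inequality.Rmd` — the methods
  account: model assumptions, calibration targets, tuning parameters,
  degenerate-case conventions, and limitations.
- `tests/testthat/` — unit, property and acceptance suites (OM distances
  verified against an exhaustive-enumeration oracle; estimator
  reductions verified against closed forms and base-R fits).
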