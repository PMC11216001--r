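typed_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cohort <- analytic_cohort_cached()
      val <<- add_typology(cohort, assign_typologies(build_sequences(cohort)))
    }
    val
  }
})

test_that("exposure propensity reduces to marginals and saturated cell frequencies", {
  cohort <- typed_cohort()
  # no confounders: fitted probabilities equal the weighted sample marginals
  fit0 <- fit_exposure_propensity(cohort, confounders = character(0))
  w <- cohort$design_weight
  marg <- tapply(w, cohort$education, sum) / sum(w)
  expect_lt(max(abs(sweep(fit0$fitted_probs, 2, marg))), 1e-5)

  # single binary confounder: fitted probabilities match weighted cell
  # frequencies (the saturated closed form)
  fit1 <- fit_exposure_propensity(cohort, confounders = "ethnicity")
  for (lv in levels(cohort$ethnicity)) {
    rows <- cohort$ethnicity == lv
    cell <- tapply(w[rows], cohort$education[rows], sum) / sum(w[rows])
    got <- fit1$fitted_probs[which(rows)[1], ]
    expect_lt(max(abs(got - cell)), 1e-6)
  }
})

test_that("mediator propensity weights are flat when the mediator ignores confounders", {
  # in the default generator the latent typology depends on education only,
  # so stabilized mediator weights concentrate at 1
  cohort <- typed_cohort()
  fit <- fit_mediator_propensity(cohort)
  sw <- fit$marginal_observed / fit$fitted_observed
  expect_lt(abs(mean(sw) - 1), 0.02)
  expect_lt(sd(sw), 0.25)
})

test_that("weight composition obeys its contracts", {
  cohort <- typed_cohort()
  exp_fit <- fit_exposure_propensity(cohort)
  med_fit <- fit_mediator_propensity(cohort)

  # intercept-only denominator: stabilized components 1, w = design weight
  flat <- fit_exposure_propensity(cohort, confounders = character(0))
  w_flat <- compose_weights(cohort$design_weight, flat)
  expect_equal(w_flat$weights, cohort$design_weight, tolerance = 1e-4)

  w_ate <- compose_weights(cohort$design_weight, exp_fit)
  expect_true(all(w_ate$weights > 0))
  expect_lt(abs(w_ate$diagnostics$mean_stabilized - 1), 0.03)
  expect_lte(w_ate$diagnostics$ess, nrow(cohort))

  w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
  expect_true(w_cde$provenance[["mediator"]])

  # winsorization clips exactly the tails and nothing else
  raw <- compose_weights(cohort$design_weight, exp_fit)
  suppressMessages(tr <- compose_weights(cohort$design_weight, exp_fit,
                                         truncation = c(1, 99)))
  qs <- quantile(raw$weights, c(0.01, 0.99))
  inside <- raw$weights > qs[1] & raw$weights < qs[2]
  expect_identical(tr$weights[inside], raw$weights[inside])
  expect_equal(max(tr$weights), unname(qs[2]))
  expect_gte(tr$n_clipped, 1L)
})

test_that("IPTW balances baseline confounders across education", {
  cohort <- typed_cohort()
  exp_fit <- fit_exposure_propensity(cohort)
  w_ate <- compose_weights(cohort$design_weight, exp_fit)
  bal <- covariate_balance(cohort, w_ate)
  expect_gt(max(bal$smd_unweighted), 0.2)   # generator confounds by design
  expect_lt(max(bal$smd_weighted), 0.1)

  # equal weights leave the SMD unchanged; identical groups give SMD 0
  bal_eq <- covariate_balance(cohort, rep(1, nrow(cohort)))
  expect_equal(bal_eq$smd_weighted, bal_eq$smd_unweighted)
  const <- cohort
  const$flatvar <- 1.0
  bal0 <- covariate_balance(const, rep(1, nrow(const)), covariates = "flatvar")
  expect_identical(bal0$smd_weighted, 0)
  expect_true(bal0$zero_variance)
})

test_that("mediator weighting balances intermediate confounders within education strata", {
  # the mediator weight removes Z -> M confounding *given* the exposure;
  # across typologies marginally, differences induced by education remain
  # (they belong to the exposure weight), so balance is checked within
  # education strata
  # well-populated design so that small-cell SMD noise does not swamp the
  # property (the default mixing leaves education x typology cells of ~12)
  params <- default_params_cached()
  params$n_children <- 2e4
  params$retention_rate <- 1
  params$typology_mixing[] <- 0.25
  cohort <- generate_cohort(params, 19)
  cohort$typology <- cohort$latent_typology
  med_fit <- fit_mediator_propensity(cohort)
  w <- cohort$design_weight * med_fit$marginal_observed / med_fit$fitted_observed
  for (ed in levels(cohort$education)) {
    rows <- cohort$education == ed
    bal <- covariate_balance(cohort[rows, ], w[rows],
                             covariates = intermediate_confounders(),
                             group = "typology")
    expect_lt(max(bal$smd_weighted), 0.1)
  }
})

test_that("an unconfounded generator makes the ATE match the crude OR", {
  params <- default_params_cached()
  params$n_children <- 20000
  params$retention_rate <- 1
  # sever confounding: baseline confounders no longer affect the outcome
  params$outcome_coefs$covariates$ethnicity[] <- 0
  params$outcome_coefs$covariates$maternal_age_band[] <- 0
  cohort <- generate_cohort(params, 71)
  cohort$typology <- cohort$latent_typology
  exp_fit <- fit_exposure_propensity(cohort)
  ate <- estimate_ate(cohort, compose_weights(cohort$design_weight, exp_fit))
  crude <- glm(outcome_raised_td ~ education, family = binomial(),
               data = cohort)
  expect_lt(max(abs(log(ate$estimates$estimate[-1]) -
                      coef(crude)[-1])), 0.1)
})

test_that("ATE weights flag a mediator component and reference OR is 1", {
  cohort <- typed_cohort()
  exp_fit <- fit_exposure_propensity(cohort)
  med_fit <- fit_mediator_propensity(cohort)
  w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
  expect_warning(estimate_ate(cohort, w_cde), "mediator")
  ate <- estimate_ate(cohort, compose_weights(cohort$design_weight, exp_fit))
  expect_identical(ate$estimates$estimate[1], 1)
  expect_identical(ate$estimates$term[1], "Degree (ref)")
})

test_that("CDE equals ATE when the generator has no mediator or interaction effects", {
  params <- default_params_cached()
  params$n_children <- 30000
  params$retention_rate <- 1
  params$outcome_coefs$typology[] <- 0
  params$outcome_coefs$interaction[] <- 0
  # balanced mediator keeps every exposure x mediator cell well populated,
  # so the comparison is within tight Monte-Carlo error
  params$typology_mixing[] <- 0.25
  cohort <- generate_cohort(params, 81)
  cohort$typology <- cohort$latent_typology  # isolate the estimator property
  exp_fit <- fit_exposure_propensity(cohort)
  med_fit <- fit_mediator_propensity(cohort)
  w_ate <- compose_weights(cohort$design_weight, exp_fit)
  w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
  ate <- estimate_ate(cohort, w_ate)
  for (m in c("PrivateGroup", "SingleProfessional")) {
    cde <- estimate_cde(cohort, w_cde, scenario_spec(m))
    expect_lt(max(abs(log(cde$estimates$estimate[-1]) -
                        log(ate$estimates$estimate[-1]))), 0.35)
  }
})

test_that("scenario and CDE input contracts are enforced", {
  cohort <- typed_cohort()
  expect_error(scenario_spec(estimand = "CDE"), "require")
  expect_error(scenario_spec("PrivateGroup", estimand = "ATE"), "only meaningful")
  exp_fit <- fit_exposure_propensity(cohort)
  med_fit <- fit_mediator_propensity(cohort)
  w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
  expect_error(estimate_cde(cohort, w_cde, scenario_spec("Nursery")),
               "not a typology level")
  # empty exposure x mediator cell is an explicit error
  broken <- cohort[!(cohort$typology == "SingleProfessional" &
                       cohort$education == "LowerStdGradesNone"), ]
  w_b <- compose_weights(broken$design_weight,
                         fit_exposure_propensity(broken),
                         fit_mediator_propensity(broken))
  expect_error(estimate_cde(broken, w_b, scenario_spec("SingleProfessional")),
               "empty exposure x mediator cell")
})

test_that("sandwich and bootstrap CDE intervals agree on well-behaved data", {
  params <- default_params_cached()
  params$n_children <- 6000
  params$retention_rate <- 1
  # well-populated design: balanced mediator and a common outcome, so no
  # exposure x mediator cell is event-sparse
  params$typology_mixing[] <- 0.25
  params$outcome_coefs$intercept <- params$outcome_coefs$intercept + 1.2
  cohort <- generate_cohort(params, 91)
  cohort$typology <- cohort$latent_typology
  suppressWarnings({
    exp_fit <- fit_exposure_propensity(cohort)
    med_fit <- fit_mediator_propensity(cohort)
    w_cde <- compose_weights(cohort$design_weight, exp_fit, med_fit)
    sand <- estimate_cde(cohort, w_cde, scenario_spec("PrivateGroup"))
    boot <- estimate_cde(cohort, w_cde, scenario_spec("PrivateGroup"),
                         ci = "bootstrap", B = 300, seed = 4)
  })
  expect_lt(max(abs(boot$estimates$se_log[-1] - sand$estimates$se_log[-1]) /
                  sand$estimates$se_log[-1]), 0.25)
})
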