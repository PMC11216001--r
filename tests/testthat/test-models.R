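test_that("weighted multinomial with two categories reduces to binary logistic ML", {
  set.seed(5)
  n <- 400
  df <- data.frame(
    y = factor(sample(c("A", "B"), n, TRUE), levels = c("A", "B")),
    x = factor(sample(c("lo", "hi"), n, TRUE), levels = c("lo", "hi")),
    z = rnorm(n),
    design_weight = rep(1, n)
  )
  fit <- fit_weighted_multinomial(df, model_spec("y", c("x", "z")))
  ref <- glm(y ~ x + z, family = binomial(), data = df)
  expect_lt(max(abs(as.data.frame(fit)$estimate - exp(coef(ref)))), 1e-6)
  # sandwich SEs match the established estimator for the binary reduction
  se_ref <- sqrt(diag(sandwich::vcovHC(ref, type = "HC0")))
  expect_lt(max(abs(fit$se_log - se_ref) / se_ref), 1e-4)
})

test_that("multinomial ORs are invariant to weight rescaling and invert with the reference", {
  cohort <- analytic_cohort_cached()
  cohort <- add_typology(cohort, assign_typologies(build_sequences(cohort)))
  spec <- model_spec("typology", c("education", "ethnicity"))
  fit <- fit_weighted_multinomial(cohort, spec)

  scaled <- cohort
  scaled$design_weight <- scaled$design_weight * 12
  fit_s <- fit_weighted_multinomial(scaled, spec)
  expect_equal(fit_s$estimate, fit$estimate, tolerance = 1e-6)
  expect_equal(fit_s$se_log, fit$se_log, tolerance = 1e-6)

  # swapping the exposure reference inverts the OR
  flipped <- cohort
  flipped$education <- relevel(flipped$education, "LowerStdGradesNone")
  fit_f <- fit_weighted_multinomial(flipped, spec)
  or <- function(f, term) as.data.frame(f)$estimate[f$term == term]
  expect_equal(
    or(fit_f, "SingleProfessional:educationDegree"),
    1 / or(fit, "SingleProfessional:educationLowerStdGradesNone"),
    tolerance = 1e-4)
})

test_that("multinomial separation is reported with the offending cell", {
  cohort <- analytic_cohort_cached()
  cohort <- add_typology(cohort, assign_typologies(build_sequences(cohort)))
  broken <- cohort[!(cohort$typology == "SingleProfessional" &
                       cohort$education == "LowerStdGradesNone"), ]
  expect_error(
    fit_weighted_multinomial(broken, model_spec("typology", "education")),
    "SingleProfessional x LowerStdGradesNone")
})

test_that("null multinomial gradients stay inside their confidence intervals", {
  # education permuted at random: every OR should cover 1 in most runs
  cohort <- analytic_cohort_cached()
  cohort <- add_typology(cohort, assign_typologies(build_sequences(cohort)))
  set.seed(8)
  covered <- replicate(50, {
    null <- cohort
    null$education <- sample(null$education)
    fit <- fit_weighted_multinomial(null,
                                    model_spec("typology", "education"))
    ed <- grepl("^education", fit$coefficient)
    c(sum(fit$ci_low[ed] <= 1 & fit$ci_high[ed] >= 1), sum(ed))
  })
  # nominal 95% intervals: per-interval coverage across the 9 education ORs
  expect_gte(sum(covered[1, ]) / sum(covered[2, ]), 0.90)
})

test_that("modified Poisson reproduces the closed-form risk ratio", {
  df <- data.frame(
    y = rep(c(1, 0, 1, 0), c(20, 80, 10, 90)),
    g = factor(rep(c("exposed", "unexposed"), each = 100),
               levels = c("unexposed", "exposed")),
    design_weight = 1
  )
  fit <- fit_modified_poisson_rr(df, model_spec("y", "g"))
  expect_equal(as.data.frame(fit)$estimate[fit$term == "gexposed"], 2,
               tolerance = 1e-8)
})

test_that("risk-ratio CIs cover 1 when the outcome ignores the typology", {
  params <- default_params_cached()
  params$n_children <- 5000
  params$retention_rate <- 1
  # a fully null outcome: no typology, education, interaction or covariate
  # effects, so the marginal typology RRs are truly 1
  params$outcome_coefs$typology[] <- 0
  params$outcome_coefs$interaction[] <- 0
  params$outcome_coefs$education[] <- 0
  for (nm in names(params$outcome_coefs$covariates)) {
    cc <- params$outcome_coefs$covariates[[nm]]
    params$outcome_coefs$covariates[[nm]] <-
      if (is.list(cc)) list(center = cc$center, slope = 0) else 0 * cc
  }
  covered <- sapply(1:40, function(s) {
    cohort <- generate_cohort(params, 300 + s)
    cohort <- add_typology(cohort, assign_typologies(build_sequences(cohort)))
    fit <- fit_modified_poisson_rr(
      cohort, model_spec("outcome_raised_td", "typology"))
    typ <- grepl("^typology", fit$term)
    c(sum(fit$ci_low[typ] <= 1 & fit$ci_high[typ] >= 1), sum(typ))
  })
  # nominal 95% robust intervals: per-interval coverage of the 3 RRs
  expect_gte(sum(covered[1, ]) / sum(covered[2, ]), 0.88)
})

test_that("sandwich SEs approach model-based SEs under correct equal-weight Poisson data", {
  set.seed(17)
  n <- 10000
  x <- rnorm(n)
  y <- rpois(n, exp(-1 + 0.3 * x))
  df <- data.frame(y = y, x = x, design_weight = 1)
  fit <- fit_modified_poisson_rr(df, model_spec("y", "x"))
  model_se <- sqrt(diag(vcov(attr(fit, "fit"))))["x"]
  expect_gt(fit$se_log, 0)
  expect_lt(abs(fit$se_log - model_se) / model_se, 0.1)
})
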