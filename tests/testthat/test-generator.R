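test_that("parameter invariants are enforced", {
  params <- default_params_cached()
  expect_s3_class(params, "care_params")
  expect_silent(validate_params(params))

  bad <- params
  bad$education_probs <- c(.5, .3, .1, .2)
  expect_error(validate_params(bad), "sum to 1")

  bad <- params
  bad$emission_noise <- 0.6
  expect_error(validate_params(bad), "emission_noise")

  bad <- params
  bad$typology_mixing[2, 1] <- -0.1
  expect_error(validate_params(bad), "outside")

  bad <- params
  bad$outcome_coefs$education[2] <- Inf
  expect_error(validate_params(bad), "finite")

  bad <- params
  bad$canonical_paths[1, 1] <- "Creche"
  expect_error(validate_params(bad), "alphabet")
})

test_that("generation is deterministic and seeds differentiate draws", {
  params <- default_params_cached()
  params$n_children <- 400
  a <- generate_cohort(params, 7)
  b <- generate_cohort(params, 7)
  expect_identical(a, b)
  cc <- generate_cohort(params, 8)
  expect_false(identical(a$education, cc$education))
  # categorical supports and weight positivity
  expect_true(all(as.character(a$childcare_sw2) %in% state_alphabet()$state))
  expect_true(all(a$design_weight > 0))
  expect_true(all(a$retained %in% 0:1))
  expect_true(all(a$attachment_score >= 8 & a$attachment_score <= 48))
  expect_true(all(a$maternal_mental_health_sw5 >= 0 &
                    a$maternal_mental_health_sw5 <= 100))
  # the latent score thresholds into the binary outcome
  expect_identical(a$outcome_raised_td, as.integer(a$td_latent > 0))
})

test_that("noiseless generation reproduces every canonical path", {
  params <- default_params_cached()
  params$n_children <- 500
  params$emission_noise <- 0
  cohort <- generate_cohort(params, 3)
  canon <- params$canonical_paths
  states <- as.matrix(sapply(cohort[paste0("childcare_sw", 1:4)], as.character))
  for (i in seq_len(nrow(cohort)))
    expect_identical(unname(states[i, ]),
                     unname(canon[as.character(cohort$latent_typology[i]), ]))
})

test_that("typology draws follow the mixing matrix (law of large numbers)", {
  params <- default_params_cached()
  params$n_children <- 1e5
  params$retention_rate <- 1
  cohort <- generate_cohort(params, 12)
  emp <- prop.table(table(cohort$education, cohort$latent_typology), 1)
  expect_lt(max(abs(emp - params$typology_mixing)), 0.01)
})

test_that("null outcome coefficients remove the education gradient", {
  params <- default_params_cached()
  params$n_children <- 6e4
  params$retention_rate <- 1
  params$outcome_coefs$education[] <- 0
  params$outcome_coefs$typology[] <- 0
  params$outcome_coefs$interaction[] <- 0
  for (nm in names(params$outcome_coefs$covariates)) {
    cc <- params$outcome_coefs$covariates[[nm]]
    params$outcome_coefs$covariates[[nm]] <-
      if (is.list(cc)) list(center = cc$center, slope = 0) else 0 * cc
  }
  cohort <- generate_cohort(params, 5)
  p <- tapply(cohort$outcome_raised_td, cohort$education, mean)
  or <- (p / (1 - p)) / (p[1] / (1 - p[1]))
  expect_lt(max(abs(or - 1)), 0.15)  # marginal ORs all ~1
})

test_that("attrition retains the expected fraction and reweights marginals", {
  params <- default_params_cached()
  params$n_children <- 1e4
  params$retention_rate <- 1  # baseline draw of exactly n children
  # intercept-only retention at 61%
  params$attrition_coefs <- list(intercept = qlogis(0.61))
  cohort <- generate_cohort(params, 21)
  kept <- apply_attrition(cohort, params)
  expect_gt(nrow(kept) / nrow(cohort), 0.59)
  expect_lt(nrow(kept) / nrow(cohort), 0.63)

  # P(retain) = 1 leaves the cohort untouched
  params_all <- params
  params_all$attrition_coefs <- list(intercept = 40)
  cohort_all <- generate_cohort(params_all, 21)
  expect_identical(apply_attrition(cohort_all, params_all), cohort_all)

  # education-dependent retention: unweighted retained distribution shifts,
  # weighted distribution still matches the baseline cohort
  params_ed <- params
  params_ed$attrition_coefs <- list(
    intercept = qlogis(0.61),
    education = c(Degree = 0.6, Highers = 0.2, UpperStdGrades = -0.2,
                  LowerStdGradesNone = -0.6))
  cohort_ed <- generate_cohort(params_ed, 22)
  kept_ed <- apply_attrition(cohort_ed, params_ed)
  base_marg <- prop.table(table(cohort_ed$education))
  raw_marg <- prop.table(table(kept_ed$education))
  wt_marg <- tapply(kept_ed$design_weight, kept_ed$education, sum) /
    sum(kept_ed$design_weight)
  expect_gt(max(abs(raw_marg - base_marg)), 0.02)   # attrition distorts
  expect_lt(max(abs(wt_marg - base_marg)), 0.02)    # weights restore

  # attrition that removes everyone is an explicit error
  params_none <- params
  params_none$attrition_coefs <- list(intercept = -40)
  cohort_none <- generate_cohort(params_none, 23)
  expect_error(apply_attrition(cohort_none, params_none), "every child")
})

test_that("cohorts round-trip through CSV with a provenance sidecar", {
  params <- default_params_cached()
  params$n_children <- 60
  cohort <- generate_cohort(params, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(sidecar$seed, 9L)
  back <- read_cohort(path)
  expect_equal(back$design_weight, cohort$design_weight)
  expect_identical(as.character(back$childcare_sw1),
                   as.character(cohort$childcare_sw1))
})
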