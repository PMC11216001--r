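## Marginal structural models with stabilized inverse-probability weights:
## exposure (maternal education) propensity, mediator (typology)
## propensity, weight composition, ATE and CDE estimation, and balance
## diagnostics.

.baseline_confounders <- c("ethnicity", "maternal_age_band")
.intermediate_confounders <- c("attachment_score", "maternal_mental_health_sw1",
                               "maternal_mental_health_sw5", "general_health",
                               "employment", "family_composition", "life_events")

#' Default confounder sets for the weight models
#'
#' Baseline confounders (child ethnicity and mother's age at first birth)
#' condition the exposure model; the intermediate set (maternal attachment,
#' maternal mental health at sweeps 1 and 5, child general health, maternal
#' employment, family composition, significant life events) additionally
#' conditions the mediator model.
#'
#' @return Character vector of column names.
#' @export
baseline_confounders <- function() .baseline_confounders

#' @rdname baseline_confounders
#' @export
intermediate_confounders <- function() .intermediate_confounders

.fit_propensity <- function(data, target, denominator_rhs, numerator_rhs,
                            weight_column, floor) {
  y <- data[[target]]
  if (!is.factor(y)) stop("propensity target must be a factor")
  dat <- data
  dat$.w <- data[[weight_column]]
  den_f <- stats::reformulate(denominator_rhs, response = target)
  num_f <- stats::reformulate(numerator_rhs, response = target)
  den_fit <- nnet::multinom(den_f, data = dat, weights = .w, trace = FALSE,
                            maxit = 1000, reltol = 1e-14, abstol = 1e-12)
  num_fit <- nnet::multinom(num_f, data = dat, weights = .w, trace = FALSE,
                            maxit = 1000, reltol = 1e-14, abstol = 1e-12)
  prob_of <- function(fit) {
    P <- stats::fitted(fit)
    if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
    if (ncol(P) == 1L) P <- cbind(1 - P[, 1L], P[, 1L])
    colnames(P) <- fit$lev
    P
  }
  den_p <- prob_of(den_fit)
  num_p <- prob_of(num_fit)
  obs <- cbind(seq_len(nrow(dat)), as.integer(y))
  fitted_obs <- den_p[obs]
  if (any(fitted_obs < floor))
    stop(sprintf(paste0("%d fitted propensities fall below the floor %.1e; ",
                        "consider truncation or a simpler conditioning set"),
                 sum(fitted_obs < floor), floor))
  structure(list(target = target, conditioning_set = denominator_rhs,
                 fitted_probs = den_p, marginal_probs = num_p,
                 fitted_observed = fitted_obs,
                 marginal_observed = num_p[obs],
                 den_fit = den_fit, num_fit = num_fit),
            class = "care_propensity")
}

#' Exposure propensity model
#'
#' Weighted multinomial model of the 4-level maternal-education exposure on
#' the baseline confounders; the stabilization numerator is the
#' intercept-only (marginal) exposure model.
#'
#' @param cohort Analytic cohort.
#' @param confounders Baseline confounder columns.
#' @param weight_column Design-weight column.
#' @param floor Smallest admissible fitted probability.
#' @return A `care_propensity` object with per-child category probability
#'   matrices for the denominator and numerator models.
#' @export
fit_exposure_propensity <- function(cohort,
                                    confounders = baseline_confounders(),
                                    weight_column = "design_weight",
                                    floor = 1e-6) {
  rhs <- if (length(confounders)) confounders else "1"
  .fit_propensity(cohort, "education", rhs, "1", weight_column, floor)
}

#' Mediator propensity model
#'
#' Weighted multinomial model of the 4-level childcare typology on the
#' exposure plus baseline and intermediate confounders; the stabilization
#' numerator conditions on the exposure only.
#'
#' @param cohort Analytic cohort carrying a `typology` column (see
#'   [add_typology()]).
#' @param confounders Confounder columns for the denominator model (the
#'   exposure is always included).
#' @inheritParams fit_exposure_propensity
#' @return A `care_propensity` object.
#' @export
fit_mediator_propensity <- function(cohort,
                                    confounders = c(baseline_confounders(),
                                                    intermediate_confounders()),
                                    weight_column = "design_weight",
                                    floor = 1e-6) {
  if (is.null(cohort$typology)) stop("cohort lacks a typology column")
  .fit_propensity(cohort, "typology", c("education", confounders),
                  "education", weight_column, floor)
}

#' Compose design and inverse-probability weights
#'
#' Per-child analysis weight
#' `w_i = design_i x P(A = a_i) / P(A = a_i | L_i)` with, optionally for
#' controlled-direct-effect estimation, the mediator factor
#' `P(M = m_i | A = a_i) / P(M = m_i | A = a_i, L_i, Z_i)`. Optional
#' percentile truncation winsorizes the composed weight at the given
#' bounds (default none, preserving honestly wide confidence intervals).
#'
#' @param design Design weights.
#' @param exposure_fit A `care_propensity` for the exposure.
#' @param mediator_fit Optional `care_propensity` for the mediator.
#' @param truncation Optional length-2 percentile pair, e.g. `c(1, 99)`.
#' @return A `care_weights` object: list with `weights`, the stabilized
#'   components, provenance flags, truncation record, and diagnostics
#'   (min/max/mean and effective sample size).
#' @export
compose_weights <- function(design, exposure_fit, mediator_fit = NULL,
                            truncation = NULL) {
  sw_a <- exposure_fit$marginal_observed / exposure_fit$fitted_observed
  sw_m <- if (!is.null(mediator_fit))
    mediator_fit$marginal_observed / mediator_fit$fitted_observed
  else rep(1, length(sw_a))
  w <- design * sw_a * sw_m
  if (any(!is.finite(w)) || any(w <= 0))
    stop("composed weights must be strictly positive and finite")
  n_clipped <- 0L
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L)
    bounds <- stats::quantile(w, truncation / 100, type = 7)
    n_clipped <- sum(w < bounds[1L] | w > bounds[2L])
    w <- pmin(pmax(w, bounds[1L]), bounds[2L])
    message(n_clipped, " weights winsorized at the ",
            truncation[1L], "/", truncation[2L], " percentiles")
  }
  structure(list(
    weights = w,
    stabilized_exposure = sw_a,
    stabilized_mediator = sw_m,
    provenance = c(design = TRUE, exposure = TRUE,
                   mediator = !is.null(mediator_fit)),
    truncation = truncation, n_clipped = n_clipped,
    diagnostics = list(min = min(w), max = max(w), mean = mean(w),
                       mean_stabilized = mean(sw_a * sw_m),
                       ess = sum(w)^2 / sum(w^2))
  ), class = "care_weights")
}

#' @export
print.care_weights <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "IP weights (%s): min %.3f | mean %.3f | max %.3f | ESS %.0f | mean stabilized %.3f\n",
    paste(names(x$provenance)[x$provenance], collapse = "+"),
    d$min, d$mean, d$max, d$ess, d$mean_stabilized))
  invisible(x)
}

.msm_effects <- function(fit, contrasts) {
  V <- sandwich::vcovHC(fit, type = "HC0")
  cf <- stats::coef(fit)
  est <- vapply(contrasts, function(cv) sum(cv * cf), numeric(1))
  se <- vapply(contrasts, function(cv)
    sqrt(drop(t(cv) %*% V %*% cv)), numeric(1))
  .wald_table(names(contrasts), est, se)
}

.education_contrasts <- function(fit, data, modifier = NULL) {
  ## contrast vector for level a vs Degree (optionally at fixed mediator m):
  ## difference of model-matrix rows, which generalises to any coding
  mm_row <- function(a, m) {
    nd <- data[1L, , drop = FALSE]
    nd$education <- factor(a, levels = levels(data$education))
    if (!is.null(m)) nd$typology <- factor(m, levels = levels(data$typology))
    stats::model.matrix(stats::delete.response(stats::terms(fit)), nd)[1L, ]
  }
  lev <- levels(data$education)
  out <- lapply(lev[-1L], function(a) mm_row(a, modifier) - mm_row(lev[1L], modifier))
  names(out) <- lev[-1L]
  out
}

#' Average treatment effect of the exposure via the weighted MSM
#'
#' Weighted logistic (quasibinomial) regression of the binary outcome on
#' the exposure alone, with the composed design x stabilized-IPTW weights
#' and HC0 sandwich standard errors treating the weights as known. Under
#' correct exposure-weight specification the exponentiated coefficients
#' are marginal odds ratios per education level versus Degree.
#'
#' @param cohort Analytic cohort.
#' @param weights A `care_weights` from exposure-only composition.
#' @param outcome Outcome column.
#' @return A `care_msm` object: `estimates` (a `care_effects` table with
#'   the reference row OR = 1 first), `estimand`, weight diagnostics, and
#'   the fitted model.
#' @export
estimate_ate <- function(cohort, weights, outcome = "outcome_raised_td") {
  if (isTRUE(weights$provenance[["mediator"]]))
    warning("ATE weights should not include a mediator component")
  .check_cells(cohort$education, cohort[[outcome]], "education")
  dat <- cohort
  dat$.w <- weights$weights
  f <- stats::reformulate("education", response = outcome)
  fit <- stats::glm(f, data = dat, weights = .w, family = stats::quasibinomial())
  eff <- .msm_effects(fit, .education_contrasts(fit, dat))
  structure(list(estimates = .with_reference_row(eff),
                 estimand = "ATE", scenario = NULL,
                 weight_diagnostics = weights$diagnostics, fit = fit),
            class = "care_msm")
}

#' Scenario specification for controlled direct effects
#'
#' @param fixed_mediator Typology code at which the mediator is fixed for
#'   everyone (`"PrivateGroup"` or `"SingleProfessional"` in the two
#'   universal-childcare scenarios; any typology level is accepted).
#' @param estimand `"CDE"` (requires `fixed_mediator`) or `"ATE"`.
#' @return A `care_scenario` list.
#' @export
scenario_spec <- function(fixed_mediator = NULL,
                          estimand = c("CDE", "ATE")) {
  estimand <- match.arg(estimand)
  if (estimand == "CDE" && is.null(fixed_mediator))
    stop("CDE scenarios require a fixed mediator level")
  if (estimand == "ATE" && !is.null(fixed_mediator))
    stop("fixed_mediator is only meaningful for CDE estimands")
  structure(list(fixed_mediator = fixed_mediator, estimand = estimand),
            class = "care_scenario")
}

#' Controlled direct effect under a universal-childcare scenario
#'
#' Weighted logistic (quasibinomial) regression of the outcome on exposure,
#' mediator, and their interaction, with composed design x exposure x
#' mediator stabilized weights. The CDE odds ratio for education level `a`
#' with the mediator fixed at `m` is `exp(beta_a + delta_am)`; confidence
#' intervals use the HC0 sandwich (or a nonparametric bootstrap).
#'
#' @param cohort Analytic cohort with a `typology` column.
#' @param weights A `care_weights` including the mediator component.
#' @param scenario A [scenario_spec()] with `estimand = "CDE"`.
#' @param outcome Outcome column.
#' @param ci One of `"sandwich"` (default) or `"bootstrap"`.
#' @param B Bootstrap resamples when `ci = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return A `care_msm` object.
#' @export
estimate_cde <- function(cohort, weights, scenario,
                         outcome = "outcome_raised_td",
                         ci = c("sandwich", "bootstrap"), B = 200, seed = 1) {
  ci <- match.arg(ci)
  stopifnot(inherits(scenario, "care_scenario"), scenario$estimand == "CDE")
  if (is.null(cohort$typology)) stop("cohort lacks a typology column")
  if (!scenario$fixed_mediator %in% levels(cohort$typology))
    stop("scenario mediator '", scenario$fixed_mediator,
         "' is not a typology level")
  if (!isTRUE(weights$provenance[["mediator"]]))
    warning("CDE weights should include the mediator component")
  tab <- table(cohort$education, cohort$typology)
  if (any(tab == 0)) {
    cell <- which(tab == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty exposure x mediator cell (%s x %s): the interaction model is not estimable",
                 rownames(tab)[cell[1L]], colnames(tab)[cell[2L]]))
  }
  dat <- cohort
  dat$.w <- weights$weights
  f <- stats::reformulate("education * typology", response = outcome)
  fit <- stats::glm(f, data = dat, weights = .w, family = stats::quasibinomial())
  contrasts <- .education_contrasts(fit, dat, modifier = scenario$fixed_mediator)
  eff <- .msm_effects(fit, contrasts)
  if (ci == "bootstrap") {
    eff <- .cde_bootstrap_ci(cohort, weights, scenario, outcome, f, eff, B, seed)
  }
  structure(list(estimates = .with_reference_row(eff),
                 estimand = "CDE", scenario = scenario$fixed_mediator,
                 weight_diagnostics = weights$diagnostics, fit = fit),
            class = "care_msm")
}

.cde_bootstrap_ci <- function(cohort, weights, scenario, outcome, f, eff,
                              B, seed) {
  n <- nrow(cohort)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draws <- matrix(NA_real_, B, nrow(eff))
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    dat <- cohort[take, , drop = FALSE]
    dat$.w <- weights$weights[take]
    bf <- tryCatch(
      stats::glm(f, data = dat, weights = .w, family = stats::quasibinomial()),
      error = function(e) NULL)
    if (is.null(bf)) next
    cvs <- .education_contrasts(bf, dat, modifier = scenario$fixed_mediator)
    draws[b, ] <- vapply(cvs, function(cv) sum(cv * stats::coef(bf)), numeric(1))
  }
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2L,
              stats::quantile, probs = c(0.025, 0.975))
  eff$ci_low <- exp(qs[1L, ])
  eff$ci_high <- exp(qs[2L, ])
  eff$se_log <- apply(draws[ok, , drop = FALSE], 2L, stats::sd)
  eff
}

.with_reference_row <- function(eff) {
  ref <- data.frame(term = "Degree (ref)", estimate = 1, se_log = 0,
                    ci_low = 1, ci_high = 1, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  out <- rbind(ref, eff[names(ref)])
  class(out) <- c("care_effects", "data.frame")
  out
}

.check_cells <- function(exposure, outcome, what) {
  tab <- table(exposure, outcome)
  if (any(rowSums(tab) == 0))
    stop("an ", what, " level has no observations")
  if (any(tab[, "1"] == 0) || any(tab[, "0"] == 0))
    stop("outcome is separated within an ", what, " level")
}

#' @export
print.care_msm <- function(x, ...) {
  cat(sprintf("MSM %s%s (ESS %.0f)\n", x$estimand,
              if (!is.null(x$scenario)) paste0(" | mediator fixed at ", x$scenario) else "",
              x$weight_diagnostics$ess))
  print(x$estimates)
  invisible(x)
}

#' Weighted covariate balance diagnostics
#'
#' Standardized mean differences of each covariate across the groups of a
#' grouping variable (exposure or mediator), before and after weighting.
#' Categorical covariates are expanded to level indicators; the reported
#' SMD per covariate is the maximum absolute pairwise SMD across groups,
#' using the unweighted pooled standard deviation as the scale. Covariates
#' with zero variance are reported as SMD 0 and flagged.
#'
#' @param cohort Data frame.
#' @param weights A `care_weights`, or a numeric vector of weights.
#' @param covariates Covariate columns.
#' @param group Grouping column (default the exposure).
#' @return Data frame with columns `covariate`, `smd_unweighted`,
#'   `smd_weighted`, `zero_variance`.
#' @export
covariate_balance <- function(cohort, weights,
                              covariates = baseline_confounders(),
                              group = "education") {
  w <- if (inherits(weights, "care_weights")) weights$weights else weights
  stopifnot(all(w > 0), length(w) == nrow(cohort))
  g <- cohort[[group]]
  cols <- list()
  for (nm in covariates) {
    x <- cohort[[nm]]
    if (is.null(x)) stop("covariate '", nm, "' not found")
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      x <- as.factor(x)
      for (lv in levels(x)[-1L])
        cols[[paste0(nm, ":", lv)]] <- as.numeric(x == lv)
    }
  }
  smd <- function(x, wt) {
    s <- stats::sd(x)
    if (s == 0) return(c(0, TRUE))
    ms <- vapply(split(data.frame(x = x, wt = wt), g),
                 function(d) stats::weighted.mean(d$x, d$wt), numeric(1))
    c(max(abs(outer(ms, ms, "-"))) / s, FALSE)
  }
  un <- vapply(cols, smd, numeric(2), wt = rep(1, nrow(cohort)))
  wt <- vapply(cols, smd, numeric(2), wt = w)
  data.frame(covariate = names(cols),
             smd_unweighted = un[1L, ],
             smd_weighted = wt[1L, ],
             zero_variance = as.logical(un[2L, ]),
             row.names = NULL)
}
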