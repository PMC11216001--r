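## Survey-weighted inequality models: multinomial typology-membership ORs
## and modified-Poisson (log-link, robust variance) risk ratios. Only
## analysis weights are honoured; survey strata/PSU information is not
## modelled (the source cohort's design variables are not public).

.adjustment_sets <- list(
  unadjusted = character(0),
  partial = c("sex", "ethnicity", "education", "attachment_score",
              "family_composition", "maternal_age_band", "school_adjustment",
              "maternal_mental_health_sw1", "general_health", "employment"),
  full = c("sex", "ethnicity", "education", "attachment_score",
           "family_composition", "maternal_age_band", "school_adjustment",
           "maternal_mental_health_sw1", "maternal_mental_health_sw5",
           "general_health", "employment", "life_events")
)

#' Model specification for the inequality models
#'
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns (the first is
#'   the focal one reported in effect tables).
#' @param weight_column Column holding analysis weights.
#' @param adjustment One of `"unadjusted"`, `"partial"`, `"full"`: preset
#'   covariate lists added to `predictors` (the partial set uses only
#'   time-fixed intermediate confounders; the full set adds the
#'   time-varying composites).
#' @return A `care_model_spec` list.
#' @export
model_spec <- function(outcome, predictors, weight_column = "design_weight",
                       adjustment = c("unadjusted", "partial", "full")) {
  adjustment <- match.arg(adjustment)
  structure(list(outcome = outcome, predictors = predictors,
                 weight_column = weight_column, adjustment = adjustment),
            class = "care_model_spec")
}

.spec_formula <- function(spec) {
  rhs <- unique(c(spec$predictors, .adjustment_sets[[spec$adjustment]]))
  stats::reformulate(rhs, response = spec$outcome)
}

.wald_table <- function(term, est_log, se_log) {
  z <- est_log / se_log
  data.frame(
    term = term,
    estimate = exp(est_log),
    se_log = se_log,
    ci_low = exp(est_log - stats::qnorm(0.975) * se_log),
    ci_high = exp(est_log + stats::qnorm(0.975) * se_log),
    p_value = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
}

#' Survey-weighted multinomial regression with sandwich variances
#'
#' Baseline-category multinomial logit of typology membership fitted by
#' weighted maximum likelihood (`nnet::multinom`), with model-robust
#' (Horvitz-Thompson-type HC0 sandwich) standard errors in which the
#' analysis weights enter both the bread and the meat. The reference
#' typology is the first level of the outcome factor and the reference
#' exposure level the first level of each predictor factor.
#'
#' @param data Data frame with the outcome, predictors and weights.
#' @param spec A [model_spec()]; typical use has
#'   `outcome = "typology"`, `predictors = c("education", "ethnicity")`.
#' @return A data.frame of effect estimates (class `care_effects`): one row
#'   per (outcome category, coefficient), with odds ratios, sandwich SEs on
#'   the log scale, 95% Wald CIs and p-values. The fitted `nnet::multinom`
#'   object is attached as attribute `"fit"`.
#' @export
fit_weighted_multinomial <- function(data, spec) {
  f <- .spec_formula(spec)
  w <- data[[spec$weight_column]]
  stopifnot(all(w > 0))
  y <- data[[spec$outcome]]
  if (!is.factor(y)) stop("multinomial outcome must be a factor")
  ## separation guard: every outcome x focal-predictor cell must be occupied
  focal <- data[[spec$predictors[1L]]]
  if (is.factor(focal)) {
    tab <- table(y, focal)
    if (any(tab == 0)) {
      cell <- which(tab == 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("empty cell %s x %s: multinomial model is separated",
                   rownames(tab)[cell[1L]], colnames(tab)[cell[2L]]))
    }
  }
  dat <- data
  dat$.w <- w
  fit <- nnet::multinom(f, data = dat, weights = .w, trace = FALSE,
                        maxit = 500, reltol = 1e-12, abstol = 1e-10,
                        Hess = TRUE, model = TRUE)
  V <- .multinom_sandwich(fit)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(fit$lev[2L], names(cf)))
  terms <- as.vector(t(outer(rownames(cf), colnames(cf), paste, sep = ":")))
  est <- as.vector(t(cf))
  se <- sqrt(diag(V))
  out <- .wald_table(terms, est, se)
  out$outcome_level <- rep(rownames(cf), each = ncol(cf))
  out$coefficient <- rep(colnames(cf), times = nrow(cf))
  attr(out, "fit") <- fit
  class(out) <- c("care_effects", "data.frame")
  out
}

## HC0 sandwich for a weighted nnet::multinom fit: bread = inverse observed
## information of the weighted log-likelihood (vcov from the Hessian), meat
## = crossproduct of per-observation weighted scores
## s_i = w_i * vec_j[(1{y_i = j} - p_ij) x_i], class-major to match vcov.
.multinom_sandwich <- function(fit) {
  X <- stats::model.matrix(stats::terms(fit), fit$model)
  y <- stats::model.response(fit$model)
  w <- stats::model.weights(fit$model)
  if (is.null(w)) w <- rep(1, nrow(X))
  P <- fit$fitted.values
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  if (ncol(P) == 1L) P <- cbind(1 - P[, 1L], P[, 1L])  # two-category fit
  lev <- fit$lev
  yi <- as.integer(factor(y, levels = lev))
  K <- length(lev); p <- ncol(X)
  S <- matrix(0, nrow(X), (K - 1L) * p)
  for (j in 2:K) {
    r <- w * ((yi == j) - P[, j])
    S[, ((j - 2L) * p + 1L):((j - 1L) * p)] <- r * X
  }
  bread <- stats::vcov(fit)
  meat <- crossprod(S)
  V <- bread %*% meat %*% bread
  dimnames(V) <- dimnames(bread)
  V
}

#' Modified-Poisson risk-ratio regression with robust variances
#'
#' Log-link Poisson-family (quasi-Poisson) regression of a binary outcome,
#' yielding risk ratios, with HC0 sandwich standard errors and analysis
#' weights. This is the standard device for obtaining correctly-scaled
#' standard errors for relative risks from a binary outcome.
#'
#' @param data Data frame.
#' @param spec A [model_spec()]; typical use has
#'   `outcome = "outcome_raised_td"`, `predictors = "typology"`, and an
#'   `adjustment` preset.
#' @return A `care_effects` data.frame of risk ratios for every model
#'   coefficient, with the fitted `glm` attached as attribute `"fit"`.
#' @export
fit_modified_poisson_rr <- function(data, spec) {
  f <- .spec_formula(spec)
  w <- data[[spec$weight_column]]
  stopifnot(all(w > 0))
  dat <- data
  dat$.w <- w
  fit <- stats::glm(f, data = dat, weights = .w,
                    family = stats::quasipoisson(link = "log"))
  if (!fit$converged)
    stop("modified-Poisson fit did not converge after ", fit$iter,
         " IWLS iterations")
  V <- sandwich::vcovHC(fit, type = "HC0")
  cf <- stats::coef(fit)
  keep <- names(cf) != "(Intercept)"
  out <- .wald_table(names(cf)[keep], unname(cf[keep]),
                     sqrt(diag(V))[keep])
  attr(out, "fit") <- fit
  class(out) <- c("care_effects", "data.frame")
  out
}

#' @export
print.care_effects <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  df$p_value <- signif(df$p_value, 2)
  print.data.frame(df[c("term", "estimate", "ci_low", "ci_high", "p_value")],
                   row.names = FALSE)
  invisible(x)
}
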