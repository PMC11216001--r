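#!/usr/bin/env Rscript
## One-time calibration solver for the default synthetic-cohort generator.
##
## Solves, in order:
##   1. the typology-mixing matrix P(typology | education): education
##      gradients are fixed at the published typology-membership log odds
##      ratios; the three baseline-category intercepts are solved exactly
##      so the marginal typology prevalences are 35.8/32.7/23.5/8.1%;
##   2. the attrition-model intercept giving 61% marginal retention over
##      the exact education x life-events x family-composition lattice;
##   3. the outcome-model coefficients (intercept; education, typology and
##      education x typology log-odds) such that the generator's implied
##      marginal raised-TD prevalence, marginal-structural ATE odds
##      ratios, controlled-direct-effect odds ratios under the two
##      universal-childcare scenarios, and covariate-standardised
##      typology risk ratios all match their published values.
##      Expectations over the confounder lattice are Monte-Carlo averages
##      with common random numbers (N = 200,000 per education level), so
##      the objective is smooth and the solve deterministic.
##
## Writes inst/extdata/calibration.yaml. Run from the repository root:
##   Rscript data-raw/calibrate.R

library(careseq)

N <- 200000L
SEED <- 20240523L

educ_probs <- c(Degree = .266, Highers = .319, UpperStdGrades = .260,
                LowerStdGradesNone = .154)
educ_probs <- educ_probs / sum(educ_probs)

typ_marginals <- c(ParentsFamilyFriends = .358, Grandparents = .327,
                   PrivateGroup = .235, SingleProfessional = .081)
typ_marginals <- typ_marginals / sum(typ_marginals)

## published typology-membership ORs vs Degree (rows: typology, cols: educ)
theta <- rbind(
  Grandparents       = log(c(0.914, 0.625, 0.368)),
  PrivateGroup       = log(c(0.457, 0.211, 0.123)),
  SingleProfessional = log(c(0.443, 0.267, 0.089))
)

mix_from_alpha <- function(alpha) {
  ## rows = education, cols = typology; baseline-category logit
  eta <- cbind(0, t(alpha + cbind(0, theta)))  # 4 educ x 4 typ
  exp(eta) / rowSums(exp(eta))
}

alpha_obj <- function(alpha) {
  marg <- as.numeric(educ_probs %*% mix_from_alpha(alpha))
  sum((marg[-1] - typ_marginals[-1])^2)
}
alpha_fit <- optim(c(0, 0, -1), alpha_obj, method = "BFGS",
                   control = list(reltol = 1e-16, maxit = 5000))
alpha_fit <- optim(alpha_fit$par, alpha_obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-16, maxit = 5000))
cat("alpha objective:", alpha_fit$value, "\n")
stopifnot(alpha_fit$value < 1e-12)
mixing <- mix_from_alpha(alpha_fit$par)
dimnames(mixing) <- list(names(educ_probs), names(typ_marginals))
cat("typology mixing solved; marginals:",
    sprintf("%.4f", educ_probs %*% mixing), "\n")

## ---- attrition intercept: exact lattice over educ x life_events x family
conf <- default_confounders()
educ_cf <- c(Degree = 0, Highers = -0.25, UpperStdGrades = -0.50,
             LowerStdGradesNone = -0.80)
life_cf <- c(None = 0, Any = -0.20)
fam_cf  <- c(AlwaysCouple = 0, AlwaysLone = -0.30, Mixture = -0.15)
ret_marg <- function(r0) {
  p <- 0
  for (a in 1:4) for (l in 1:2) for (f in 1:3)
    p <- p + educ_probs[a] * conf$life_events$probs[a, l] *
      conf$family_composition$probs[a, f] *
      plogis(r0 + educ_cf[a] + life_cf[l] + fam_cf[f])
  unname(p)
}
r0 <- uniroot(function(x) ret_marg(x) - 0.61, c(-2, 3), tol = 1e-12)$root
cat(sprintf("attrition intercept %.6f -> marginal retention %.6f\n",
            r0, ret_marg(r0)))

## ---- outcome model -------------------------------------------------------
## Monte-Carlo confounder draws per education level, plus a marginal
## baseline-confounder draw for the do()-interventional populations.
cov_coefs <- default_outcome_covariate_coefs()
L_vars <- c("ethnicity", "maternal_age_band")

draw_conf <- function(n, a) {
  out <- list()
  for (nm in names(conf)) {
    cf <- conf[[nm]]
    out[[nm]] <- switch(cf$type,
      categorical = {
        idx <- findInterval(runif(n), cumsum(cf$probs[a, ]),
                            rightmost.closed = TRUE) + 1L
        factor(cf$levels[idx], levels = cf$levels)
      },
      normal = pmin(pmax(rnorm(n, cf$mean[a], cf$sd), cf$min), cf$max),
      linked_normal = {
        src <- out[[cf$source]]
        pmin(pmax(rnorm(n, cf$base + cf$slope * (src - cf$base) + cf$shift[a],
                        cf$sd), cf$min), cf$max)
      })
  }
  out
}

cov_lp <- function(cc, vars) {
  lp <- 0
  for (nm in vars) {
    co <- cov_coefs[[nm]]
    lp <- lp + if (is.list(co)) co$slope * (cc[[nm]] - co$center)
               else co[as.integer(cc[[nm]])]
  }
  lp
}

set.seed(SEED)
Z_vars <- setdiff(names(conf), L_vars)
lp_obs <- lp_doZ <- vector("list", 4L)
for (a in 1:4) {
  cc <- draw_conf(N, a)
  lp_obs[[a]] <- cov_lp(cc, names(conf))
  lp_doZ[[a]] <- cov_lp(cc, Z_vars)
}
## marginal baseline-confounder draw (shared across education levels)
am <- findInterval(runif(N), cumsum(educ_probs), rightmost.closed = TRUE) + 1L
lp_L_marg <- numeric(N)
for (a in 1:4) {
  ids <- which(am == a)
  if (length(ids)) {
    cc <- draw_conf(length(ids), a)
    lp_L_marg[ids] <- cov_lp(cc, L_vars)
  }
}
lp_do <- lapply(1:4, function(a) lp_doZ[[a]] + lp_L_marg)

targets <- list(
  marginal_y = 0.109,
  ate_or = c(1.352, 2.596, 3.181),
  cde_private_or = c(2.164, 3.600, 3.778),
  cde_singleprof_or = c(0.713, 1.782, 2.420),
  rr = c(Grandparents = 1.052, PrivateGroup = 0.832,
         SingleProfessional = 0.770)
)

unpack <- function(par) {
  list(b0 = par[1],
       bA = c(0, par[2:4]),
       bM = c(0, par[5:7]),
       dI = rbind(0, cbind(0, matrix(par[8:13], nrow = 3))))
  # dI rows = education (Degree first), cols = typology (ParentsFF first);
  # par[8:13] fills column-major: (H,U,L) x (PrivateGroup, SingleProfessional)
}

implied <- function(par) {
  p <- unpack(par)
  dI <- matrix(0, 4, 4)
  dI[2:4, 3] <- par[8:10]   # education x PrivateGroup
  dI[2:4, 4] <- par[11:13]  # education x SingleProfessional
  q_do <- q_obs <- matrix(0, 4, 4)
  for (a in 1:4) for (m in 1:4) {
    eta <- p$b0 + p$bA[a] + p$bM[m] + dI[a, m]
    q_do[a, m]  <- mean(plogis(eta + lp_do[[a]]))
    q_obs[a, m] <- mean(plogis(eta + lp_obs[[a]]))
  }
  odds <- function(x) x / (1 - x)
  p_ate <- rowSums(mixing * q_do)
  marg <- sum(educ_probs * rowSums(mixing * q_obs))
  risk_m <- as.numeric(educ_probs %*% q_obs)
  list(marginal_y = marg,
       ate_or = odds(p_ate[2:4]) / odds(p_ate[1]),
       cde_private_or = odds(q_do[2:4, 3]) / odds(q_do[1, 3]),
       cde_singleprof_or = odds(q_do[2:4, 4]) / odds(q_do[1, 4]),
       rr = risk_m[2:4] / risk_m[1])
}

objective <- function(par) {
  im <- implied(par)
  sum((qlogis(im$marginal_y) - qlogis(targets$marginal_y))^2,
      (log(im$ate_or) - log(targets$ate_or))^2,
      (log(im$cde_private_or) - log(targets$cde_private_or))^2,
      (log(im$cde_singleprof_or) - log(targets$cde_singleprof_or))^2,
      (log(im$rr) - log(targets$rr))^2)
}

start <- c(-2.5,
           log(targets$ate_or),
           log(targets$rr),
           log(targets$cde_private_or) - log(targets$ate_or),
           log(targets$cde_singleprof_or) - log(targets$ate_or))
cat("solving outcome coefficients (this takes a few minutes)...\n")
fit <- optim(start, objective, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
cat(sprintf("objective %.3e after %d evals (convergence %d)\n",
            fit$value, fit$counts[1], fit$convergence))
im <- implied(fit$par)
res <- mapply(function(a, b) max(abs(unlist(a) - unlist(b))),
              im, targets)
print(data.frame(target = names(res), max_abs_residual = as.numeric(res)))
if (max(res) > 1e-3)
  stop("calibration failed: residuals exceed 1e-3; targets: ",
       paste(sprintf("%s=%.4g", names(res), res), collapse = ", "))

p <- unpack(fit$par)
educ_names <- names(educ_probs); typ_names <- names(typ_marginals)
interaction <- matrix(0, 4, 4, dimnames = list(educ_names, typ_names))
interaction[2:4, 3] <- fit$par[8:10]
interaction[2:4, 4] <- fit$par[11:13]

as_named_list <- function(x) as.list(setNames(as.numeric(x), names(x)))
cal <- list(
  provenance = list(
    solver = "data-raw/calibrate.R",
    mc_draws_per_level = N,
    solver_seed = SEED,
    solved = format(Sys.time(), "%Y-%m-%d"),
    objective = fit$value
  ),
  education_probs = as_named_list(educ_probs),
  typology_mixing = setNames(lapply(1:4, function(a)
    as_named_list(setNames(mixing[a, ], typ_names))), educ_names),
  retention_rate = 0.61,
  attrition_coefs = list(intercept = r0),
  outcome_coefs = list(
    intercept = p$b0,
    education = as_named_list(setNames(p$bA, educ_names)),
    typology = as_named_list(setNames(p$bM, typ_names)),
    interaction = setNames(lapply(1:4, function(a)
      as_named_list(setNames(interaction[a, ], typ_names))), educ_names)
  ),
  residual = as.list(setNames(as.numeric(res), names(res))),
  implied = lapply(im, function(x) as.numeric(x))
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
yaml::write_yaml(cal, "inst/extdata/calibration.yaml", precision = 12)
cat("wrote inst/extdata/calibration.yaml\n")
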