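## Independent oracles and small fixtures shared across test files.

## Exhaustive-enumeration oracle for the optimal-matching edit distance:
## recursively explores every alignment (substitution / deletion /
## insertion path) without memoisation, so it shares no code path with the
## dynamic-programming implementation.
om_enumerate <- function(a, b, sub, indel) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L && j > 0L) best <- min(best, rec(i - 1L, j - 1L) + sub[a[i], b[j]])
    if (i > 0L) best <- min(best, rec(i - 1L, j) + indel)
    if (j > 0L) best <- min(best, rec(i, j - 1L) + indel)
    best
  }
  rec(length(a), length(b))
}

## Sequence set built directly from a state matrix.
make_seqs <- function(states, weights = NULL, alphabet = state_alphabet()) {
  structure(list(child_id = paste0("c", seq_len(nrow(states))),
                 states = states,
                 weights = if (is.null(weights)) rep(1, nrow(states)) else weights,
                 alphabet = alphabet$state),
            class = "care_seqs")
}

## Cached default calibration + one analytic cohort reused across tests.
default_params_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- default_calibration()
    val
  }
})

analytic_cohort_cached <- local({
  val <- NULL
  function(seed = 101) {
    if (is.null(val)) {
      params <- default_params_cached()
      val <<- apply_attrition(generate_cohort(params, seed), params)
    }
    val
  }
})

## Adjusted Rand index between two labelings (independent check metric).
ari <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}

## One full study replicate at the default calibration: generate, attrite,
## cluster, and fit every estimator; returns the headline quantities.
run_study_replicate <- function(params, seed) {
  base <- generate_cohort(params, seed)
  coh <- apply_attrition(base, params)
  seqs <- build_sequences(coh)
  fit <- assign_typologies(seqs, k = 4)
  coh <- add_typology(coh, fit)
  shares <- stats::setNames(100 * fit$cluster_weights / sum(fit$weights),
                            fit$typology_codes)
  low <- function(msm)
    msm$estimates$estimate[msm$estimates$term == "LowerStdGradesNone"]
  suppressWarnings({
    ef <- fit_exposure_propensity(coh)
    w_ate <- compose_weights(coh$design_weight, ef)
    ate <- estimate_ate(coh, w_ate)
    mf <- fit_mediator_propensity(coh)
    w_cde <- compose_weights(coh$design_weight, ef, mf)
    cde_p <- estimate_cde(coh, w_cde, scenario_spec("PrivateGroup"))
    cde_s <- estimate_cde(coh, w_cde, scenario_spec("SingleProfessional"))
    mn <- fit_weighted_multinomial(coh,
                                   model_spec("typology", c("education", "ethnicity")))
    rr <- fit_modified_poisson_rr(coh,
                                  model_spec("outcome_raised_td", "typology",
                                             adjustment = "full"))
  })
  list(
    n = nrow(coh),
    ate = low(ate),
    cde_private = low(cde_p),
    cde_singleprof = low(cde_s),
    or_sp_low = mn$estimate[mn$term ==
                              "SingleProfessional:educationLowerStdGradesNone"],
    rr_private = rr$estimate[rr$term == "typologyPrivateGroup"],
    share_sp = if ("SingleProfessional" %in% names(shares))
      shares[["SingleProfessional"]] else NA_real_,
    mean_stab_exposure = mean(w_ate$stabilized_exposure),
    max_smd_weighted = max(covariate_balance(coh, w_ate)$smd_weighted),
    labels = fit$labels,
    latent = coh$latent_typology
  )
}
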