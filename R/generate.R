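## Cohort generation: one row per child, drawn block by block with a
## dedicated RNG substream per variable block so that adding a block never
## perturbs draws made by earlier blocks.

.block_ids <- c(education = 1L, confounders = 2L, typology = 3L,
                sequences = 4L, outcome = 5L, design_weight = 6L,
                retention = 7L)

.block_seed <- function(seed, block) {
  id <- .block_ids[[block]]
  as.integer((as.numeric(seed) %% 1e6) * 1009 + id * 9973) %% 2147483629L
}

.with_block_seed <- function(seed, block, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.block_seed(seed, block))
  expr
}

## Vectorised draw of a categorical variable whose distribution depends on
## a grouping index (education level 1..4).
.sample_cat_by_group <- function(group_idx, probs, levels) {
  cum <- t(apply(probs, 1L, cumsum))
  u <- stats::runif(length(group_idx))
  idx <- rowSums(u > cum[group_idx, , drop = FALSE]) + 1L
  factor(levels[idx], levels = levels)
}

.rnorm_trunc <- function(n, mean, sd, min, max) {
  pmin(pmax(stats::rnorm(n, mean, sd), min), max)
}

#' Generate a synthetic birth cohort
#'
#' Draws a baseline cohort of `round(n_children / retention_rate)` children:
#' maternal education, confounders given education, a latent childcare
#' typology given education, per-sweep childcare states as the typology's
#' canonical path with independent per-sweep emission noise, a latent Total
#' Difficulties score (logistic model on education, typology, their
#' interaction, and confounders) thresholded into the binary raised-TD
#' outcome, gamma-distributed survey design weights, and a retention
#' indicator from the logistic attrition model.
#'
#' The draw is deterministic given `(params, seed)`; each variable block
#' uses its own RNG substream.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed.
#' @return A `data.frame` of class `care_cohort`, one row per baseline
#'   child, with childcare states in columns `childcare_sw1..childcare_sw4`,
#'   the generator-truth `latent_typology` (withheld from estimators),
#'   `td_latent`, `outcome_raised_td`, `design_weight`, `p_retain`, and
#'   `retained`.
#' @export
generate_cohort <- function(params, seed) {
  validate_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n <- as.integer(round(params$n_children / params$retention_rate))

  educ <- .with_block_seed(seed, "education", {
    .sample_cat_by_group(rep(1L, n),
                         matrix(params$education_probs, nrow = 1L),
                         .educ_levels)
  })
  ei <- as.integer(educ)

  conf <- .with_block_seed(seed, "confounders", {
    out <- list()
    for (nm in names(params$confounders)) {
      cf <- params$confounders[[nm]]
      out[[nm]] <- switch(cf$type,
        categorical = .sample_cat_by_group(ei, cf$probs, cf$levels),
        normal = .rnorm_trunc(n, cf$mean[ei], cf$sd, cf$min, cf$max),
        linked_normal = {
          src <- out[[cf$source]]
          if (is.null(src)) stop("linked_normal source '", cf$source,
                                 "' must be generated first")
          mu <- cf$base + cf$slope * (src - cf$base) + cf$shift[ei]
          .rnorm_trunc(n, mu, cf$sd, cf$min, cf$max)
        },
        stop("unknown confounder type: ", cf$type))
    }
    out
  })

  typ <- .with_block_seed(seed, "typology", {
    .sample_cat_by_group(ei, params$typology_mixing, .typ_levels)
  })
  ti <- as.integer(typ)

  states <- .with_block_seed(seed, "sequences", {
    alph <- params$alphabet$state
    canon <- params$canonical_paths[.typ_levels, , drop = FALSE]
    s <- matrix(canon[ti, ], nrow = n, ncol = 4L)
    if (params$emission_noise > 0) {
      flip <- matrix(stats::runif(n * 4L) < params$emission_noise, n, 4L)
      if (any(flip)) {
        cur <- match(s[flip], alph)
        # uniform draw over the other |alphabet| - 1 states
        r <- floor(stats::runif(length(cur)) * (length(alph) - 1L)) + 1L
        r <- ifelse(r >= cur, r + 1L, r)
        s[flip] <- alph[r]
      }
    }
    s
  })

  lp <- outcome_linear_predictor(params, educ, typ, conf)
  outc <- .with_block_seed(seed, "outcome", {
    td <- lp + stats::rlogis(n)
    list(td_latent = td, raised = as.integer(td > params$td_threshold))
  })

  dw <- .with_block_seed(seed, "design_weight", {
    stats::rgamma(n, shape = params$design_weight$shape,
                  rate = params$design_weight$rate)
  })

  p_ret <- retention_probability(params, educ, conf)
  ret <- .with_block_seed(seed, "retention", {
    as.integer(stats::runif(n) < p_ret)
  })

  cohort <- data.frame(
    child_id = sprintf("c%06d", seq_len(n)),
    education = educ,
    stringsAsFactors = FALSE
  )
  for (nm in names(conf)) cohort[[nm]] <- conf[[nm]]
  cohort$latent_typology <- typ
  for (j in 1:4) cohort[[paste0("childcare_sw", j)]] <-
    factor(states[, j], levels = params$alphabet$state)
  cohort$td_latent <- outc$td_latent
  cohort$outcome_raised_td <- outc$raised
  cohort$design_weight <- dw
  cohort$p_retain <- p_ret
  cohort$retained <- ret
  attr(cohort, "seed") <- seed
  class(cohort) <- c("care_cohort", "data.frame")
  cohort
}

#' Outcome-model linear predictor
#'
#' Latent-scale (log-odds) linear predictor of the raised-TD outcome model
#' for given education, typology and confounder values.
#'
#' @param params A `care_params` object.
#' @param educ Factor of education levels.
#' @param typ Factor of latent typologies.
#' @param conf Named list (or data.frame) of confounder values.
#' @return Numeric vector of log-odds.
#' @keywords internal
outcome_linear_predictor <- function(params, educ, typ, conf) {
  oc <- params$outcome_coefs
  ei <- as.integer(factor(educ, levels = .educ_levels))
  ti <- as.integer(factor(typ, levels = .typ_levels))
  lp <- oc$intercept + oc$education[ei] + oc$typology[ti] +
    oc$interaction[cbind(ei, ti)]
  for (nm in names(oc$covariates)) {
    cc <- oc$covariates[[nm]]
    x <- conf[[nm]]
    if (is.null(x)) stop("outcome covariate '", nm, "' missing from confounders")
    lp <- lp + if (is.list(cc)) cc$slope * (x - cc$center)
               else cc[as.integer(x)]
  }
  unname(lp)
}

#' Retention probability under the attrition model
#'
#' @inheritParams outcome_linear_predictor
#' @return Numeric vector of per-child retention probabilities.
#' @keywords internal
retention_probability <- function(params, educ, conf) {
  ac <- params$attrition_coefs
  lp <- rep(ac$intercept, length(educ))
  if (!is.null(ac$education))
    lp <- lp + ac$education[as.integer(factor(educ, levels = .educ_levels))]
  for (nm in setdiff(names(ac), c("intercept", "education"))) {
    x <- conf[[nm]]
    if (is.null(x)) stop("attrition covariate '", nm, "' missing from confounders")
    lp <- lp + ac[[nm]][as.integer(x)]
  }
  unname(stats::plogis(lp))
}

#' Apply attrition to a generated cohort
#'
#' Subsets the cohort to the retained (complete-case) children and rescales
#' each retained child's design weight by the inverse of its retention
#' probability, so that weighted marginals of the retained sample
#' approximate the full baseline cohort (the synthetic analogue of combined
#' sample and response weights).
#'
#' @param cohort A `care_cohort` from [generate_cohort()].
#' @param params The `care_params` used to generate it.
#' @return The retained subset, with `design_weight` rescaled.
#' @export
apply_attrition <- function(cohort, params) {
  stopifnot(inherits(cohort, "care_cohort"))
  p_ret <- retention_probability(params, cohort$education, cohort)
  keep <- cohort$retained == 1L
  if (!any(keep)) stop("attrition removed every child; no analytic sample")
  out <- cohort[keep, , drop = FALSE]
  out$design_weight <- out$design_weight / p_ret[keep]
  rownames(out) <- NULL
  out
}

#' Write a cohort to CSV with a provenance sidecar
#'
#' Writes the cohort as an RFC-4180 CSV and a JSON sidecar recording the
#' seed, package version and generation time.
#'
#' @param cohort A `care_cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  sidecar <- list(
    seed = attr(cohort, "seed"),
    n = nrow(cohort),
    package_version = as.character(utils::packageVersion("careseq")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @param alphabet A [state_alphabet()] used to re-level the state columns.
#' @return A `care_cohort` data frame.
#' @export
read_cohort <- function(path, alphabet = state_alphabet()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$education <- factor(df$education, levels = .educ_levels)
  if ("latent_typology" %in% names(df))
    df$latent_typology <- factor(df$latent_typology, levels = .typ_levels)
  if ("typology" %in% names(df))
    df$typology <- factor(df$typology,
                          levels = if (all(df$typology %in% .typ_levels))
                            .typ_levels else sort(unique(df$typology)))
  for (j in grep("^childcare_sw", names(df)))
    df[[j]] <- factor(df[[j]], levels = alphabet$state)
  # restore the canonical factor level order of categorical confounders
  for (nm in names(default_confounders())) {
    cf <- default_confounders()[[nm]]
    if (identical(cf$type, "categorical") && nm %in% names(df) &&
        all(df[[nm]] %in% cf$levels))
      df[[nm]] <- factor(df[[nm]], levels = cf$levels)
  }
  class(df) <- c("care_cohort", "data.frame")
  df
}
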