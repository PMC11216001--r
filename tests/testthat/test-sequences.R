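test_that("om_distance reproduces hand-checkable edit costs", {
  costs <- cost_scheme(substitution = 2, indel = 1)
  sub <- costs$substitution

  # identical sequences are at distance zero
  s <- c("PrivateGroup", "LAGroup", "None", "Grandparent")
  expect_identical(om_distance(s, s, costs), 0)

  # single mismatch under constant costs: one substitution
  a <- c("PrivateGroup", "PrivateGroup", "LAGroup", "LAGroup")
  b <- c("PrivateGroup", "PrivateGroup", "LAGroup", "PrivateGroup")
  expect_equal(om_distance(a, b, costs), om_enumerate(a, b, sub, 1))
  expect_equal(om_distance(a, b, costs), 2)

  # a one-position shift: one deletion + one insertion beats two substitutions
  a <- c("None", "Grandparent", "Grandparent", "Grandparent")
  b <- c("Grandparent", "Grandparent", "Grandparent", "LAGroup")
  expect_equal(om_distance(a, b, costs), om_enumerate(a, b, sub, 1))
  expect_equal(om_distance(a, b, costs), 2)

  expect_error(om_distance(c("Nope", "None"), c("None", "None"), costs),
               "alphabet")
})

test_that("pairwise distances agree with the enumeration oracle on random sets", {
  set.seed(42)
  costs <- cost_scheme()
  alph <- state_alphabet()
  states <- matrix(sample(alph$state, 20 * 4, replace = TRUE), 20, 4)
  seqs <- make_seqs(states)
  D <- pairwise_distances(seqs, costs)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D <= max(costs$substitution) * 4))
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(D[i, j],
                 om_enumerate(states[i, ], states[j, ], costs$substitution, 1))
})

test_that("om distance is a pseudometric and bounded by the Hamming cost", {
  set.seed(7)
  costs <- cost_scheme(substitution = 2, indel = 1)
  alph <- state_alphabet()$state
  rseq <- function() sample(alph, 4, replace = TRUE)
  for (i in 1:200) {
    a <- rseq(); b <- rseq(); cc <- rseq()
    dab <- om_distance(a, b, costs)
    dba <- om_distance(b, a, costs)
    expect_identical(dab, dba)
    expect_lte(dab, om_distance(a, cc, costs) + om_distance(cc, b, costs) + 1e-12)
    expect_lte(dab, 2 * sum(a != b) + 1e-12)  # substitution-only upper bound
  }
})

test_that("build_sequences validates states and applies recodes", {
  params <- default_params_cached()
  cohort <- analytic_cohort_cached()

  seqs <- build_sequences(cohort)
  expect_identical(nrow(seqs$states), nrow(cohort))
  expect_identical(seqs$states[, 3],
                   as.character(cohort$childcare_sw3))
  expect_identical(seqs$weights, cohort$design_weight)

  # identity recode changes nothing
  idmap <- setNames(state_alphabet()$state, state_alphabet()$state)
  expect_identical(build_sequences(cohort, recode = idmap)$states, seqs$states)

  # collapsing recode produces a 6-state effective alphabet
  coll <- idmap
  coll["LAGroup"] <- "PrivateGroup"
  seqs6 <- build_sequences(cohort, recode = coll)
  expect_false("LAGroup" %in% seqs6$states)
  expect_length(seqs6$alphabet, 6L)

  # missing sweep state errors with child id and sweep number
  broken <- cohort
  broken$childcare_sw3[5] <- NA
  expect_error(build_sequences(broken),
               paste0("child ", cohort$child_id[5], " at sweep 3"))

  # unmapped raw category
  expect_error(build_sequences(cohort, recode = coll[-1]),
               "does not cover")
})

test_that("sequence aggregation preserves total weight and membership", {
  set.seed(11)
  alph <- state_alphabet()
  states <- matrix(sample(alph$state[1:3], 50 * 4, replace = TRUE), 50, 4)
  seqs <- make_seqs(states, weights = runif(50, 0.5, 2))
  agg <- aggregate_sequences(seqs)
  expect_equal(sum(agg$seqs$weights), sum(seqs$weights))
  # every child maps back to its own sequence
  for (i in 1:50)
    expect_identical(agg$seqs$states[agg$index[i], ], states[i, ])
  # unique rows are sorted, so aggregation is order-invariant
  perm <- sample(50)
  seqs_p <- make_seqs(states[perm, ], weights = seqs$weights[perm])
  agg_p <- aggregate_sequences(seqs_p)
  expect_identical(agg_p$seqs$states, agg$seqs$states)
  expect_equal(agg_p$seqs$weights, agg$seqs$weights)
})

test_that("sequences round-trip through long CSV", {
  set.seed(3)
  states <- matrix(sample(state_alphabet()$state, 12 * 4, replace = TRUE), 12, 4)
  seqs <- make_seqs(states, weights = runif(12, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequences(seqs, path)
  back <- read_sequences(path)
  expect_identical(back$states, seqs$states)
  expect_equal(back$weights, seqs$weights)
})

test_that("transition-based substitution costs are a valid scheme", {
  cohort <- analytic_cohort_cached()
  seqs <- build_sequences(cohort)
  costs <- transition_cost_scheme(seqs)
  expect_true(isSymmetric(unname(costs$substitution)))
  expect_true(all(diag(costs$substitution) == 0))
  expect_gt(costs$indel, 0)
  # frequent transitions are cheaper than never-observed ones
  expect_lt(costs$substitution["None", "LAGroup"],
            max(costs$substitution))
})
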