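#' Substitution/indel cost scheme for optimal matching
#'
#' Constant costs (the conventional default: substitution 2, indel 1) or a
#' transition-rate-based substitution matrix derived from a sequence set,
#' where the cost of substituting states i and j is
#' `2 - p(i -> j) - p(j -> i)` with `p` the observed probability of
#' transitioning between the states at consecutive sweeps.
#'
#' @param substitution Constant substitution cost, or a symmetric
#'   zero-diagonal matrix with one row/column per alphabet state.
#' @param indel Insertion/deletion cost (> 0).
#' @param alphabet A [state_alphabet()].
#' @return An object of class `care_costs`: list with elements
#'   `substitution` (matrix) and `indel`.
#' @export
cost_scheme <- function(substitution = 2, indel = 1, alphabet = state_alphabet()) {
  k <- nrow(alphabet)
  if (is.matrix(substitution)) {
    sub <- substitution
  } else {
    sub <- matrix(substitution, k, k)
    diag(sub) <- 0
  }
  dimnames(sub) <- list(alphabet$state, alphabet$state)
  costs <- structure(list(substitution = sub, indel = indel,
                          alphabet = alphabet$state),
                     class = "care_costs")
  validate_costs(costs)
  costs
}

validate_costs <- function(costs) {
  sub <- costs$substitution
  if (!isSymmetric(unname(sub))) stop("substitution matrix must be symmetric")
  if (any(diag(sub) != 0)) stop("substitution matrix must have zero diagonal")
  if (any(sub < 0)) stop("substitution costs must be nonnegative")
  if (!(costs$indel > 0)) stop("indel cost must be positive")
  invisible(costs)
}

#' Transition-rate-based substitution costs
#'
#' @param seqs A `care_seqs` set from [build_sequences()].
#' @param indel Indel cost; defaults to half the maximum substitution cost.
#' @return A `care_costs` object.
#' @rdname cost_scheme
#' @export
transition_cost_scheme <- function(seqs, indel = NULL) {
  alph <- seqs$alphabet
  k <- length(alph)
  counts <- matrix(0, k, k, dimnames = list(alph, alph))
  s <- seqs$states
  for (t in seq_len(ncol(s) - 1L)) {
    tab <- table(factor(s[, t], levels = alph), factor(s[, t + 1L], levels = alph))
    counts <- counts + unclass(tab)
  }
  from <- rowSums(counts)
  p <- counts / ifelse(from == 0, 1, from)
  sub <- 2 - p - t(p)
  diag(sub) <- 0
  sub[sub < 0] <- 0
  sub <- (sub + t(sub)) / 2
  if (is.null(indel)) indel <- max(sub) / 2
  costs <- structure(list(substitution = sub, indel = indel, alphabet = alph),
                     class = "care_costs")
  validate_costs(costs)
  costs
}

#' Build childcare state sequences from a cohort
#'
#' One length-4 sequence per child from the `childcare_sw1..childcare_sw4`
#' columns, carrying the child's design weight as analysis weight. An
#' optional recode map (named character vector raw -> alphabet code) is
#' applied first; it must cover every observed raw category.
#'
#' @param cohort A cohort data frame (typically the retained sample from
#'   [apply_attrition()]).
#' @param recode Optional named character vector mapping raw categories to
#'   alphabet codes.
#' @param alphabet A [state_alphabet()]; when `recode` collapses states the
#'   effective alphabet is the set of mapped codes.
#' @return An object of class `care_seqs`: list with `child_id`, `states`
#'   (character matrix n x 4), `weights`, `alphabet`.
#' @export
build_sequences <- function(cohort, recode = NULL, alphabet = state_alphabet()) {
  swcols <- paste0("childcare_sw", 1:4)
  if (!all(swcols %in% names(cohort))) stop("cohort lacks per-sweep state columns")
  s <- sapply(cohort[swcols], as.character)
  if (!is.matrix(s)) s <- matrix(s, ncol = 4L)
  for (t in 1:4) {
    bad <- which(is.na(s[, t]))
    if (length(bad))
      stop(sprintf("missing childcare state for child %s at sweep %d",
                   cohort$child_id[bad[1L]], t))
  }
  alph <- alphabet$state
  if (!is.null(recode)) {
    unmapped <- setdiff(unique(as.vector(s)), names(recode))
    if (length(unmapped))
      stop("recode map does not cover raw categories: ",
           paste(unmapped, collapse = ", "))
    s[] <- recode[as.vector(s)]
    alph <- intersect(alph, unique(as.vector(recode)))
  }
  bad <- setdiff(unique(as.vector(s)), alph)
  if (length(bad)) stop("states outside the alphabet: ", paste(bad, collapse = ", "))
  w <- cohort$design_weight
  if (is.null(w)) w <- rep(1, nrow(s))
  if (any(w <= 0)) stop("analysis weights must be strictly positive")
  structure(list(child_id = cohort$child_id, states = s,
                 weights = as.numeric(w), alphabet = alph),
            class = "care_seqs")
}

#' @export
print.care_seqs <- function(x, ...) {
  cat("Childcare state sequences: n =", nrow(x$states),
      "| sweeps =", ncol(x$states),
      "| alphabet =", length(x$alphabet), "states\n")
  invisible(x)
}

.seqs_int <- function(seqs) {
  m <- matrix(match(seqs$states, seqs$alphabet), nrow = nrow(seqs$states))
  if (anyNA(m)) stop("sequence states outside the alphabet")
  m
}

#' Optimal-matching distance between two sequences
#'
#' Minimum total cost of transforming one state sequence into the other by
#' substitutions and insertions/deletions, computed by dynamic programming.
#'
#' @param a,b Character vectors of states over the same alphabet.
#' @param costs A [cost_scheme()].
#' @return Nonnegative dissimilarity (symmetric in `a`, `b`).
#' @export
om_distance <- function(a, b, costs = cost_scheme()) {
  validate_costs(costs)
  ai <- match(a, costs$alphabet)
  bi <- match(b, costs$alphabet)
  if (anyNA(ai) || anyNA(bi))
    stop("sequence contains states outside the cost scheme's alphabet")
  .om_dist_pair_cpp(ai, bi, costs$substitution, costs$indel)
}

#' Pairwise optimal-matching distance matrix
#'
#' @param seqs A `care_seqs` set.
#' @param costs A [cost_scheme()].
#' @return Symmetric n x n matrix with zero diagonal, dimnames = child ids.
#' @export
pairwise_distances <- function(seqs, costs = cost_scheme()) {
  validate_costs(costs)
  if (!setequal(seqs$alphabet, costs$alphabet) &&
      !all(seqs$alphabet %in% costs$alphabet))
    stop("sequence alphabet is not covered by the cost scheme")
  ints <- matrix(match(seqs$states, costs$alphabet), nrow = nrow(seqs$states))
  D <- .om_dist_matrix_cpp(ints, costs$substitution, costs$indel)
  dimnames(D) <- list(seqs$child_id, seqs$child_id)
  D
}

#' Aggregate identical sequences
#'
#' Collapses a sequence set to its unique sequences with summed weights,
#' recording the mapping back to children. Clustering unique sequences with
#' their aggregate weights is equivalent to (and much faster than)
#' clustering all children, because identical sequences are at distance
#' zero. Unique sequences are ordered lexicographically, which makes every
#' downstream clustering invariant to the input order of children.
#'
#' @param seqs A `care_seqs` set.
#' @return List with `seqs` (unique `care_seqs`, weights summed),
#'   `index` (for each child, the row of its unique sequence).
#' @export
aggregate_sequences <- function(seqs) {
  key <- apply(seqs$states, 1L, paste, collapse = "\r")
  ord <- order(key, method = "radix")
  ukey <- unique(key[ord])
  idx <- match(key, ukey)
  states <- seqs$states[ord[!duplicated(key[ord])], , drop = FALSE]
  w <- as.numeric(tapply(seqs$weights, idx, sum))
  uniq <- structure(list(child_id = paste0("u", seq_along(ukey)),
                         states = states, weights = w,
                         alphabet = seqs$alphabet),
                    class = "care_seqs")
  list(seqs = uniq, index = idx)
}

#' Read/write sequences as CSV
#'
#' `write_sequences()` writes long format (`child_id`, `sweep`, `state`,
#' `weight`); `read_sequences()` reads it back.
#'
#' @param seqs A `care_seqs` set.
#' @param path CSV path.
#' @export
write_sequences <- function(seqs, path) {
  Tn <- ncol(seqs$states)
  long <- data.frame(
    child_id = rep(seqs$child_id, each = Tn),
    sweep = rep(seq_len(Tn), times = length(seqs$child_id)),
    state = as.vector(t(seqs$states)),
    weight = rep(seqs$weights, each = Tn)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @param alphabet A [state_alphabet()].
#' @export
read_sequences <- function(path, alphabet = state_alphabet()) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$child_id)
  Tn <- max(long$sweep)
  long <- long[order(match(long$child_id, ids), long$sweep), ]
  s <- matrix(long$state, ncol = Tn, byrow = TRUE)
  w <- long$weight[!duplicated(long$child_id)]
  structure(list(child_id = ids, states = s, weights = w,
                 alphabet = alphabet$state),
            class = "care_seqs")
}
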