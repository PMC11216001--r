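#' Weighted Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under the Ward criterion where each observation
#' carries an analysis weight, via the weighted Lance-Williams update
#' (`stats::hclust` with `members`). The tree is cut at `k` clusters and
#' cluster labels are renumbered by decreasing total weight, so label 1 is
#' always the heaviest cluster.
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param weights Positive observation weights.
#' @param k Number of clusters (2 <= k <= n).
#' @return Object of class `care_clustering`: list with `labels` (integer
#'   vector in 1..k), `k`, `merge_tree` (the `hclust` object), `weights`,
#'   `cluster_weights`.
#' @export
weighted_ward_cluster <- function(D, weights = NULL, k) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (!all(is.finite(D))) stop("dissimilarity matrix contains non-finite values")
  if (k > n) stop("k (", k, ") exceeds the number of observations (", n, ")")
  if (k < 1L) stop("k must be at least 1")
  # members normalised to mean 1: the Ward criterion is scale-free in the
  # weights, and normalising makes invariance to uniform weight rescaling
  # exact (no floating-point tie reordering)
  tree <- stats::hclust(stats::as.dist(D), method = "ward.D",
                        members = signif(weights / mean(weights), 10))
  labels <- stats::cutree(tree, k = k)
  cw <- as.numeric(tapply(weights, labels, sum))
  relab <- order(order(-cw))  # heaviest cluster becomes 1
  labels <- relab[labels]
  cw <- as.numeric(tapply(weights, labels, sum))
  structure(list(labels = unname(labels), k = k, merge_tree = tree,
                 weights = weights, cluster_weights = cw),
            class = "care_clustering")
}

#' @export
print.care_clustering <- function(x, ...) {
  cat("Weighted Ward clustering: k =", x$k, "\n")
  share <- 100 * x$cluster_weights / sum(x$weights)
  nm <- if (!is.null(x$typology_names)) x$typology_names else
    paste0("cluster_", seq_len(x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  %d %-28s %5.1f%%\n", i, nm[i], share[i]))
  invisible(x)
}

#' Weighted cluster quality statistics
#'
#' Weighted average silhouette width (ASW) and the ratio of within-cluster
#' to total weighted sum of dissimilarities, for one clustering or (via
#' `cluster_quality_range()`) for each k along the same merge tree.
#' Weights are treated as case multiplicities: the silhouette `a(i)` term
#' excludes the observation's own weight from its cluster's denominator.
#' Observations whose cluster carries no other weight, and fully degenerate
#' inputs where all dissimilarities are zero, are assigned silhouette 0 by
#' convention.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels.
#' @param weights Positive observation weights.
#' @return List with `asw` (weighted average silhouette width), `wss_ratio`
#'   (within / total weighted dissimilarity sum) and per-cluster `silhouette`.
#' @export
cluster_quality <- function(D, labels, weights = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1, n)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("cluster quality needs at least two clusters")
  ## weighted mean dissimilarity from each observation to each cluster
  W <- vapply(ks, function(g) as.numeric(D %*% (weights * (labels == g))), numeric(n))
  cw <- vapply(ks, function(g) sum(weights[labels == g]), numeric(1))
  own <- match(labels, ks)
  a_den <- cw[own] - weights
  a <- ifelse(a_den > 0, W[cbind(seq_len(n), own)] / a_den, NA_real_)
  Wb <- sweep(W, 2L, cw, "/")
  Wb[cbind(seq_len(n), own)] <- Inf
  b <- apply(Wb, 1L, min)
  s <- ifelse(is.na(a) | pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  per_cluster <- as.numeric(tapply(weights * s, own, sum) /
                              tapply(weights, own, sum))
  within <- sum(weights * W[cbind(seq_len(n), own)])
  total <- sum(weights * (D %*% weights))
  list(asw = sum(weights * s) / sum(weights),
       wss_ratio = if (total > 0) within / total else 0,
       silhouette = per_cluster)
}

#' @rdname cluster_quality
#' @param ks Integer vector of cluster counts to evaluate.
#' @export
cluster_quality_range <- function(D, weights = NULL, ks = 2:8) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1, n)
  tree <- stats::hclust(stats::as.dist(D), method = "ward.D",
                        members = signif(weights / mean(weights), 10))
  out <- lapply(ks, function(k) {
    labels <- stats::cutree(tree, k = k)
    q <- cluster_quality(D, labels, weights)
    data.frame(k = k, asw = q$asw, wss_ratio = q$wss_ratio)
  })
  do.call(rbind, out)
}

#' Bootstrap stability of a cluster solution
#'
#' For each of `B` weighted bootstrap resamples (children drawn with
#' replacement with probability proportional to their analysis weight), the
#' resample is re-clustered at the same `k` and, for each reference
#' cluster, the maximum Jaccard overlap with any bootstrap cluster is
#' recorded (computed over the distinct children present in the resample).
#' Stability is the mean overlap across resamples; a reference cluster
#' absent from a resample scores 0 in that resample.
#'
#' @param seqs A `care_seqs` set.
#' @param k Number of clusters.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param costs A [cost_scheme()].
#' @return Numeric vector of length `k`: per-cluster stability in \[0, 1\].
#' @export
bootstrap_stability <- function(seqs, k, B = 50, seed = 1,
                                costs = cost_scheme()) {
  if (B < 1L) stop("B must be at least 1")
  ref <- assign_typologies(seqs, costs = costs, k = k, name = FALSE)
  n <- length(seqs$child_id)
  prob <- seqs$weights / sum(seqs$weights)
  jac <- matrix(0, B, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE, prob = prob)
    bs <- structure(list(child_id = seqs$child_id[take],
                         states = seqs$states[take, , drop = FALSE],
                         weights = seqs$weights[take],
                         alphabet = seqs$alphabet), class = "care_seqs")
    bfit <- tryCatch(assign_typologies(bs, costs = costs, k = k, name = FALSE),
                     error = function(e) NULL)
    if (is.null(bfit)) next  # degenerate resample recorded as overlap 0
    ids <- unique(take)
    ref_lab <- ref$labels[ids]
    boot_lab <- bfit$labels[!duplicated(take)]
    for (r in seq_len(k)) {
      A <- ref_lab == r
      if (!any(A)) { jac[b, r] <- 0; next }
      jac[b, r] <- max(vapply(seq_len(k), function(cc) {
        Bm <- boot_lab == cc
        inter <- sum(A & Bm)
        if (inter == 0) 0 else inter / sum(A | Bm)
      }, numeric(1)))
    }
  }
  colMeans(jac)
}

.state_typology_names <- c(
  None = "Parents, friends & family",
  FamilyFriends = "Parents, friends & family",
  Grandparent = "Grandparents",
  PrivateGroup = "Private Group Childcare",
  SingleProfessional = "Single Professional Care",
  LAGroup = "Local Authority Group Childcare",
  Other = "Other Care"
)

.typology_name_codes <- c(
  "Parents, friends & family" = "ParentsFamilyFriends",
  "Grandparents" = "Grandparents",
  "Private Group Childcare" = "PrivateGroup",
  "Single Professional Care" = "SingleProfessional",
  "Local Authority Group Childcare" = "LAGroup",
  "Other Care" = "OtherCare"
)

#' Name clusters after their dominant early-years childcare state
#'
#' For a k = 4 solution each cluster is named after its weighted modal
#' state over sweeps 1-3 (the pre-universal-entitlement period, where most
#' variation in childcare use occurs), with the `None` and `FamilyFriends`
#' states both mapping to "Parents, friends & family". Naming collisions
#' are resolved deterministically: the heavier cluster keeps the name and
#' the lighter one falls back to its next most frequent state (with a
#' message); for k != 4 generic `cluster_1..k` names are returned.
#'
#' @param assignment A `care_clustering` whose labels align with `seqs`.
#' @param seqs The `care_seqs` that were clustered.
#' @param prefix_sweeps Number of initial sweeps used for the modal state.
#' @return Character vector of length `k`: display name per cluster.
#' @export
label_typologies <- function(assignment, seqs, prefix_sweeps = 3L) {
  k <- assignment$k
  if (k != 4L) return(paste0("cluster_", seq_len(k)))
  s <- seqs$states[, seq_len(prefix_sweeps), drop = FALSE]
  w <- rep(seqs$weights, times = prefix_sweeps)
  lab <- rep(assignment$labels, times = prefix_sweeps)
  ranked <- lapply(seq_len(k), function(g) {
    tab <- tapply(w[lab == g], as.vector(s)[lab == g], sum)
    nm <- .state_typology_names[names(sort(tab, decreasing = TRUE))]
    unique(unname(nm))
  })
  names_out <- rep(NA_character_, k)
  for (g in order(-assignment$cluster_weights)) {
    cand <- setdiff(ranked[[g]], names_out)
    if (length(cand)) {
      if (!identical(ranked[[g]][1L], cand[1L]))
        message("typology naming collision: cluster ", g,
                " falls back to '", cand[1L], "'")
      names_out[g] <- cand[1L]
    } else {
      names_out[g] <- paste0("cluster_", g)
    }
  }
  names_out
}

#' Cluster childcare sequences into typologies
#'
#' The full mediator-construction stage: aggregates identical sequences
#' (summing weights), computes pairwise optimal-matching dissimilarities on
#' the unique sequences, clusters them with weighted Ward linkage, cuts at
#' `k`, maps labels back to children, and (for k = 4) names the clusters by
#' their dominant early childcare state.
#'
#' @param seqs A `care_seqs` set.
#' @param costs A [cost_scheme()].
#' @param k Number of typologies.
#' @param name Attach typology names (k = 4 only)?
#' @return A `care_clustering` with per-child `labels`, `typology_names`
#'   (display names per cluster), `typology_codes` (factor-safe codes), the
#'   aggregated-level merge tree, and cluster weights.
#' @export
assign_typologies <- function(seqs, costs = cost_scheme(), k = 4L, name = TRUE) {
  agg <- aggregate_sequences(seqs)
  D <- pairwise_distances(agg$seqs, costs)
  cl <- weighted_ward_cluster(D, agg$seqs$weights, k = k)
  labels <- cl$labels[agg$index]
  cw <- as.numeric(tapply(seqs$weights, labels, sum))
  out <- structure(list(labels = labels, k = k, merge_tree = cl$merge_tree,
                        weights = seqs$weights, cluster_weights = cw,
                        child_id = seqs$child_id),
                   class = "care_clustering")
  if (name) {
    out$typology_names <- label_typologies(out, seqs)
    out$typology_codes <- unname(.typology_name_codes[out$typology_names])
    out$typology_codes[is.na(out$typology_codes)] <-
      paste0("cluster_", which(is.na(out$typology_codes)))
  }
  out
}

#' Attach typology labels to a cohort
#'
#' Adds a `typology` factor to the cohort. When the four canonical names
#' are present the factor levels are ordered with "Parents, friends &
#' family" first (the reference category of all downstream models).
#'
#' @param cohort Cohort data frame aligned row-for-row with the clustered
#'   sequences.
#' @param assignment A named `care_clustering` from [assign_typologies()].
#' @return The cohort with a `typology` column.
#' @export
add_typology <- function(cohort, assignment) {
  stopifnot(nrow(cohort) == length(assignment$labels))
  codes <- assignment$typology_codes
  if (is.null(codes)) codes <- paste0("cluster_", seq_len(assignment$k))
  lev <- if (all(.typ_levels %in% codes)) .typ_levels else codes
  cohort$typology <- factor(codes[assignment$labels], levels = lev)
  cohort
}
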