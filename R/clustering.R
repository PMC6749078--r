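# Two-stage k-means++ over windowed centrality vectors, under correlation
# distance (1 - Pearson r). Group-level clustering with randomized k-means++
# initialization first; the resulting centers then seed a second round of
# Lloyd refinement within each subject. Cluster centers are the metastates.

#' Correlation distance between two vectors
#'
#' `1 - Pearson(u, v)`, in `[0, 2]`.
#'
#' @param u,v Numeric vectors of equal length with nonzero variance.
#' @return A single distance value.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors differ in length")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stopf("correlation distance undefined for a constant vector")
  1 - stats::cor(u, v)
}

# Row-wise correlation distance between samples (n x d) and centers (k x d).
#' @noRd
cross_corr_dist <- function(samples, centers) {
  d <- 1 - suppressWarnings(stats::cor(t(samples), t(centers)))
  if (anyNA(d)) stopf("correlation distance undefined: constant vector present")
  d  # n x k
}

#' @noRd
assign_nearest <- function(dmat) {
  # ties broken by lowest state index (max.col picks first on ties)
  max.col(-dmat, ties.method = "first")
}

#' @noRd
total_inertia <- function(dmat, labels) {
  sum(dmat[cbind(seq_along(labels), labels)])
}

# k-means++ seeding: first center uniform, then D^2 sampling under
# correlation distance.
#' @noRd
kmeanspp_seed <- function(samples, k) {
  n <- nrow(samples)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- cross_corr_dist(samples, samples[idx[1], , drop = FALSE])[, 1]^2
    for (j in 2:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(n, 1)
      else idx[j] <- sample.int(n, 1, prob = d2)
      dn <- cross_corr_dist(samples, samples[idx[j], , drop = FALSE])[, 1]^2
      d2 <- pmin(d2, dn)
    }
  }
  samples[idx, , drop = FALSE]
}

# Lloyd iterations from given centers; centroid = arithmetic mean of member
# vectors. Inertia (total within-cluster correlation distance) is checked
# for monotone descent every iteration. Empty clusters are re-seeded at the
# sample farthest from its current center.
#' @noRd
lloyd <- function(samples, centers, max_iter = 300L, tol = 1e-9) {
  k <- nrow(centers)
  labels <- assign_nearest(cross_corr_dist(samples, centers))
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (length(members) == 0) {
        d_self <- cross_corr_dist(samples, centers)
        far <- which.max(d_self[cbind(seq_len(nrow(samples)), labels)])
        message(sprintf("empty cluster %d re-seeded at sample %d", j, far))
        centers[j, ] <- samples[far, ]
        labels[far] <- j
      } else {
        centers[j, ] <- colMeans(samples[members, , drop = FALSE])
      }
    }
    dmat <- cross_corr_dist(samples, centers)
    new_labels <- assign_nearest(dmat)
    new_inertia <- total_inertia(dmat, new_labels)
    if (new_inertia > inertia + tol)
      stopf("internal error: inertia increased (%.12g -> %.12g)",
            inertia, new_inertia)
    converged <- all(new_labels == labels) && it > 1
    labels <- new_labels
    inertia <- new_inertia
    if (converged) break
  }
  list(centers = centers, labels = labels, inertia = inertia, iterations = it)
}

#' k-means++ clustering under correlation distance
#'
#' k-means++ seeding followed by Lloyd iterations with correlation distance
#' (1 - Pearson r); centroids are arithmetic means of member vectors (for
#' z-scored rows, all of equal norm, this is the exact minimizer of summed
#' correlation distance). Deterministic given `seed`.
#'
#' @param samples Numeric matrix, one sample (window) per row; every row
#'   must have nonzero variance.
#' @param k Number of clusters (<= number of samples).
#' @param seed Integer seed.
#' @param restarts Number of random restarts; the fit with lowest inertia
#'   wins.
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `"metastate_model"`: `centers` (k x region),
#'   `labels` (per-sample state index in 1..k), `k`, `inertia` (total
#'   within-cluster correlation distance), `distance`, `seed`, `restarts`.
#' @export
kmeans_pp <- function(samples, k, seed = 1L, restarts = 1L, max_iter = 300L) {
  samples <- as.matrix(samples)
  if (!is_count(k) || k < 1) stopf("k must be a positive count")
  if (nrow(samples) < k)
    stopf("need at least k = %d samples (got %d)", k, nrow(samples))
  rv <- apply(samples, 1, stats::sd)
  if (any(rv == 0))
    stopf("constant sample row(s): %s",
          paste(utils::head(which(rv == 0), 5), collapse = ", "))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd(samples, kmeanspp_seed(samples, k), max_iter = max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(centers = best$centers, labels = best$labels,
                 k = as.integer(k), inertia = best$inertia,
                 distance = "correlation", seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 iterations = best$iterations,
                 region_labels = colnames(samples)),
            class = "metastate_model")
}

#' @export
print.metastate_model <- function(x, ...) {
  cat(sprintf("<metastate_model> k = %d, %d windows, inertia %.4f (%s distance, seed %d)\n",
              x$k, length(x$labels), x$inertia, x$distance, x$seed))
  invisible(x)
}

#' Elbow-based selection of the number of metastates
#'
#' Fits k-means++ for every k in `k_range` (each with `restarts` restarts,
#' best inertia kept) and selects k* as the arg-max of the second-order
#' difference of the best-inertia curve — the point of maximal curvature.
#' A mean-silhouette curve (same correlation distance) is reported
#' alongside as a complementary validity index.
#'
#' @param samples Sample matrix as in [kmeans_pp()].
#' @param k_range Integer vector (or 2-vector range) of candidate k; at
#'   least 3 candidates are required for a second difference.
#' @param seed Integer seed.
#' @param restarts Restarts per k (default 10).
#' @return List with `k` (selected), `validity` (data frame: k, inertia,
#'   silhouette, curvature) and `models` (fitted model per k).
#' @export
elbow_select_k <- function(samples, k_range = c(2L, 10L), seed = 1L,
                           restarts = 10L) {
  samples <- as.matrix(samples)
  ks <- if (length(k_range) == 2) seq(k_range[1], k_range[2]) else
    sort(unique(as.integer(k_range)))
  if (length(ks) < 3) stopf("elbow undefined for fewer than 3 candidate k")
  if (max(ks) > nrow(samples)) stopf("k_range exceeds sample count")
  dfull <- 1 - suppressWarnings(stats::cor(t(samples)))
  if (anyNA(dfull)) stopf("constant sample row present")
  models <- vector("list", length(ks))
  inertia <- sil <- numeric(length(ks))
  for (i in seq_along(ks)) {
    models[[i]] <- kmeans_pp(samples, ks[i], seed = sub_seed(seed, ks[i]),
                             restarts = restarts)
    inertia[i] <- models[[i]]$inertia
    s <- cluster::silhouette(models[[i]]$labels, dmatrix = dfull)
    sil[i] <- mean(s[, "sil_width"])
  }
  curv <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1))
    curv[i] <- inertia[i - 1] - 2 * inertia[i] + inertia[i + 1]
  k_star <- ks[which.max(curv)]
  list(k = k_star,
       validity = data.frame(k = ks, inertia = inertia, silhouette = sil,
                             curvature = curv),
       models = stats::setNames(models, paste0("k", ks)))
}

#' Two-stage clustering: group model, then per-subject refinement
#'
#' Stage 1 pools every subject's windowed centrality vectors and fits
#' k-means++ with randomized initialization. Stage 2 re-runs Lloyd
#' iterations within each subject, initialized at the group centers; each
#' subject's refined centers are then matched back to the group states (via
#' [match_states()]) so per-subject labels are reported in the group state
#' indexing. Subjects with fewer samples than k get nearest-group-center
#' labels without refinement.
#'
#' @param subject_samples Named list of per-subject sample matrices sharing
#'   the region dimension.
#' @param k Number of metastates.
#' @param seed Integer seed.
#' @param restarts Group-stage restarts (default 10).
#' @return List with `group` (the group `metastate_model`),
#'   `subject_labels` (list of per-window state indices, group indexing),
#'   `subject_centers` (list of matched per-subject center matrices) and
#'   `pooled_index` (subject id per pooled row).
#' @export
two_stage_fit <- function(subject_samples, k, seed = 1L, restarts = 10L) {
  stopifnot(is.list(subject_samples), length(subject_samples) >= 1)
  dims <- vapply(subject_samples, ncol, integer(1))
  if (length(unique(dims)) != 1)
    stopf("subjects disagree on region dimension")
  if (is.null(names(subject_samples)))
    names(subject_samples) <- paste0("sub", seq_along(subject_samples))
  pooled <- do.call(rbind, subject_samples)
  group <- kmeans_pp(pooled, k, seed = seed, restarts = restarts)
  subject_labels <- subject_centers <- vector("list", length(subject_samples))
  names(subject_labels) <- names(subject_centers) <- names(subject_samples)
  for (s in seq_along(subject_samples)) {
    x <- as.matrix(subject_samples[[s]])
    if (nrow(x) < k) {
      message(sprintf("subject %s has %d < k samples; nearest-center labels only",
                      names(subject_samples)[s], nrow(x)))
      subject_labels[[s]] <- assign_nearest(cross_corr_dist(x, group$centers))
      subject_centers[[s]] <- group$centers
      next
    }
    fit <- lloyd(x, group$centers)
    mt <- match_states(fit$centers, group$centers)
    subject_labels[[s]] <- mt$permutation[fit$labels]
    centers_matched <- fit$centers
    centers_matched[mt$permutation, ] <- fit$centers
    subject_centers[[s]] <- centers_matched
  }
  list(group = group, subject_labels = subject_labels,
       subject_centers = subject_centers,
       pooled_index = rep(names(subject_samples),
                          vapply(subject_samples, nrow, integer(1))))
}

#' Match two sets of metastate centers
#'
#' Optimal bijection between equal-sized sets of cluster centers minimizing
#' the summed correlation distance (Hungarian assignment), e.g. to align
#' states across two independently clustered scans.
#'
#' @param centersA,centersB k x region matrices.
#' @return List with `permutation` (`permutation[a]` is the state of B
#'   matched to state a of A), `matched_distances` (per matched pair) and
#'   `total_distance`.
#' @export
match_states <- function(centersA, centersB) {
  centersA <- as.matrix(centersA); centersB <- as.matrix(centersB)
  if (nrow(centersA) != nrow(centersB))
    stopf("center sets differ in size (%d vs %d)",
          nrow(centersA), nrow(centersB))
  cost <- cross_corr_dist(centersA, centersB)
  perm <- solve_assignment(cost)
  d <- cost[cbind(seq_len(nrow(cost)), perm)]
  list(permutation = perm, matched_distances = d, total_distance = sum(d))
}

# Hungarian algorithm (potentials + shortest augmenting path, O(k^3)) for
# the minimum-cost assignment; cross-checked against exhaustive permutation
# search in the test suite.
#' @noRd
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 1) return(1L)
  # slot j + 1 holds column j; slot 1 is the virtual column 0
  u <- rep(0, n); v <- rep(0, n + 1)
  p <- rep(0L, n + 1); way <- rep(0L, n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) perm[p[j + 1]] <- j
  perm
}

#' Metastate centers from samples and labels
#'
#' The node-centrality pattern of a metastate is the arithmetic mean of all
#' vectors assigned to that cluster.
#'
#' @param samples Sample matrix (windows x regions).
#' @param labels Per-sample state index in `1..k`.
#' @param k Number of states (default `max(labels)`).
#' @return k x region matrix of state patterns.
#' @export
metastate_centers <- function(samples, labels, k = max(labels)) {
  samples <- as.matrix(samples)
  if (length(labels) != nrow(samples)) stopf("labels/sample mismatch")
  centers <- matrix(NA_real_, k, ncol(samples),
                    dimnames = list(paste0("S", seq_len(k)),
                                    colnames(samples)))
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (!length(members)) stopf("state %d has no members", j)
    centers[j, ] <- colMeans(samples[members, , drop = FALSE])
  }
  centers
}
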