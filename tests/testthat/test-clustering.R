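# k-means++ under correlation distance, elbow selection, two-stage fitting
# and cross-scan state matching.

test_that("correlation distance matches hand-computed values", {
  u <- c(1, 2, 3)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u + 10), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(correlation_distance(u, c(1, 1, 1)), "constant")
})

test_that("k-means++ handles degenerate instances exactly", {
  one <- matrix(rep(c(1, 2, 5, 3), 6), 6, 4, byrow = TRUE)
  fit <- kmeans_pp(one, 1, seed = 1)
  expect_equal(unname(fit$centers[1, ]), c(1, 2, 5, 3))
  expect_equal(fit$inertia, 0)

  five <- withr_seed(3, matrix(rnorm(5 * 8), 5, 8))
  fit5 <- suppressMessages(kmeans_pp(five, 5, seed = 2))
  expect_equal(fit5$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(unique(fit5$labels)), 1:5)
})

test_that("two anticorrelated planted patterns are partitioned exactly", {
  tpl <- rbind(c(rep(1, 8), rep(-1, 8)), c(rep(-1, 8), rep(1, 8)))
  ps <- planted_samples(25, tpl, noise_sd = 0.2, seed = 21)
  fit <- kmeans_pp(ps$samples, 2, seed = 9, restarts = 5)
  # brute-force assignment check: every sample nearer its own state center
  centers <- metastate_centers(ps$samples, ps$labels)
  d <- 1 - cor(t(ps$samples), t(centers))
  expect_equal(apply(d, 1, which.min), ps$labels)
  agreement <- max(mean(fit$labels == ps$labels),
                   mean(3 - fit$labels == ps$labels))  # label switching
  expect_equal(agreement, 1)
})

test_that("same seed gives a bitwise-identical fit", {
  x <- planted_samples(15, block_templates(3, 12), 0.5, seed = 5)$samples
  a <- kmeans_pp(x, 3, seed = 77, restarts = 3)
  b <- kmeans_pp(x, 3, seed = 77, restarts = 3)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
  expect_identical(a$inertia, b$inertia)
})

test_that("on tiny instances the fit reaches the exhaustive-search optimum", {
  exhaustive_best <- function(samples, k) {
    n <- nrow(samples)
    best <- Inf
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    for (r in seq_len(nrow(grid))) {
      lab <- grid[r, ]
      if (length(unique(lab)) < k) next
      centers <- metastate_centers(samples, lab, k)
      d <- 1 - cor(t(samples), t(centers))
      # evaluate the k-means objective: distance to the assigned center
      best <- min(best, sum(d[cbind(seq_len(n), lab)]))
    }
    best
  }
  for (s in 1:6) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- withr_seed(300 + s, zscore_rows(matrix(rnorm(n * 10), n, 10)))
    fit <- suppressMessages(kmeans_pp(x, k, seed = 400 + s, restarts = 10))
    expect_lte(fit$inertia, exhaustive_best(x, k) + 1e-9)
  }
})

test_that("elbow selection recovers five planted states and needs >= 3 candidates", {
  tpl <- block_templates(5, 30)
  ps <- planted_samples(60, tpl, noise_sd = 0.2, seed = 31)
  sel <- elbow_select_k(ps$samples, c(2, 8), seed = 13, restarts = 5)
  expect_equal(sel$k, 5)
  expect_true(all(diff(sel$validity$inertia) <= 1e-9))  # inertia non-increasing in k

  # duplicating every sample leaves the selection unchanged
  sel2 <- elbow_select_k(ps$samples[rep(seq_len(nrow(ps$samples)), 2), ],
                         c(2, 8), seed = 13, restarts = 5)
  expect_equal(sel2$k, 5)

  expect_error(elbow_select_k(ps$samples, c(2, 3), seed = 1), "3 candidate")
})

test_that("a single Gaussian blob yields low silhouettes everywhere", {
  x <- withr_seed(41, zscore_rows(matrix(rnorm(120 * 20), 120, 20)))
  sel <- suppressMessages(elbow_select_k(x, c(2, 6), seed = 15, restarts = 3))
  expect_true(all(sel$validity$silhouette < 0.3))
})

test_that("two-stage fitting reports subject labels in group indexing", {
  tpl <- block_templates(3, 12)
  ps <- planted_samples(20, tpl, noise_sd = 0.25, seed = 51)
  # one subject owning the pooled data reproduces the group labels
  fit <- two_stage_fit(list(all = ps$samples), 3, seed = 19)
  expect_equal(unname(fit$subject_labels$all), fit$group$labels)

  # a subject sitting at cluster centers: duplicated samples share a label,
  # distinct samples get distinct labels, and refinement moves nothing
  # (the refined centers are the three center vectors themselves)
  at_centers <- fit$group$centers[c(1, 2, 3, 1), ]
  fit2 <- two_stage_fit(list(a = ps$samples, b = at_centers), 3, seed = 19)
  lab_b <- fit2$subject_labels$b
  expect_equal(lab_b[1], lab_b[4])
  expect_length(unique(lab_b[1:3]), 3)
  expect_equal(match_states(fit2$subject_centers$b,
                            fit$group$centers)$total_distance,
               0, tolerance = 1e-10)
})

test_that("per-subject planted state sequences are recovered almost perfectly", {
  tpl <- block_templates(4, 24)   # pairwise correlation distance >= 1
  expect_true(all((1 - cor(t(tpl)))[upper.tri(diag(4))] >= 1))
  subj <- lapply(1:5, function(s)
    planted_samples(30, tpl, noise_sd = 0.3, seed = 600 + s))
  fit <- two_stage_fit(lapply(subj, `[[`, "samples"), 4, seed = 23)
  mt <- match_states(tpl, fit$group$centers)
  acc <- vapply(seq_along(subj), function(s) {
    truth <- mt$permutation[subj[[s]]$labels]
    mean(fit$subject_labels[[s]] == truth)
  }, numeric(1))
  expect_gt(mean(acc), 0.95)
})

test_that("state matching finds the optimal bijection", {
  A <- block_templates(5, 20) + withr_seed(61, matrix(rnorm(100, sd = 0.1), 5))
  self <- match_states(A, A)
  expect_equal(self$permutation, 1:5)
  expect_equal(self$total_distance, 0, tolerance = 1e-12)

  p <- c(3, 5, 1, 2, 4)
  B <- A[order(p), ]   # row i of B is state order(p)[i] of A
  mt <- match_states(A, B)
  expect_equal(mt$permutation, p)

  # optimality against every one of the 5! bijections
  cost <- 1 - cor(t(A), t(B))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(q) !anyDuplicated(q)), ]
  totals <- apply(perms, 1, function(q) sum(cost[cbind(1:5, q)]))
  expect_equal(mt$total_distance, min(totals), tolerance = 1e-12)
  expect_lte(mt$total_distance, sum(diag(cost)))  # beats identity pairing

  expect_equal(match_states(A[1, , drop = FALSE],
                            A[1, , drop = FALSE])$permutation, 1L)
  expect_error(match_states(A, A[1:3, ]), "differ in size")
})

test_that("metastate centers are member means and empty states error", {
  x <- withr_seed(71, matrix(rnorm(6 * 5), 6, 5))
  lab <- c(1, 1, 2, 2, 2, 3)
  centers <- metastate_centers(x, lab)
  expect_equal(unname(centers[2, ]), colMeans(x[3:5, ]))
  expect_equal(unname(centers[3, ]), x[6, ])
  v <- x[1, ]; mid <- rbind(v, -v + 2 * mean(v))
  expect_equal(unname(metastate_centers(mid, c(1, 1))[1, ]),
               unname(colMeans(mid)))
  expect_error(metastate_centers(x, lab, k = 4), "no members")
})
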