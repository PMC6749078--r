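# Dwell/transition features and the pooled-moment ICC.

test_that("dwell time counts windows and scales by TR", {
  d <- dwell_time(c(1, 1, 2, 2, 2), tr_s = 2.5)
  expect_equal(d$windows, c(2, 3))
  expect_equal(d$seconds, c(5, 7.5))

  d1 <- dwell_time(rep(2, 10), tr_s = 2, k = 3)
  expect_equal(d1$windows, c(0, 10, 0))

  lab <- withr_seed(1, sample(1:5, 227, replace = TRUE))
  expect_equal(sum(dwell_time(lab)$windows), 227)
})

test_that("transition counts ignore self-pairs and transpose under reversal", {
  tm <- transition_matrix(c(1, 2, 1, 2))
  expect_equal(unname(tm), matrix(c(0, 1, 2, 0), 2))
  expect_equal(unname(transition_matrix(rep(3, 6))), matrix(0, 3, 3))
  lab <- withr_seed(2, sample(1:4, 50, replace = TRUE))
  expect_equal(transition_matrix(rev(lab)), t(transition_matrix(lab)))
})

test_that("dwell and transition identities hold on fuzzed label sequences", {
  withr_seed(3, {
    for (case in 1:1000) {
      k <- sample(2:6, 1)
      n <- sample(1:120, 1)
      lab <- sample(seq_len(k), n, replace = TRUE)
      dyn <- state_dynamics(lab, k = k)
      expect_identical(sum(dyn$dwell$windows), n)
      expect_identical(sum(dyn$transitions), sum(diff(lab) != 0))
      expect_true(all(diag(dyn$transitions) == 0))
    }
  })
})

test_that("ICC of a duplicated measurement is exactly 1; a reversal scores -1", {
  x <- withr_seed(4, rnorm(23))
  expect_equal(icc(x, x)$value, 1)
  expect_equal(icc(c(1, 2, 3), c(3, 2, 1))$value, -1)
  expect_error(icc(rep(2, 5), rep(2, 5)), "constant")
  expect_error(icc(1:2, 1:2), "n >= 3")
})

test_that("ICC is symmetric and invariant to a common affine shift", {
  withr_seed(5, {
    x1 <- rnorm(15); x2 <- 0.6 * x1 + rnorm(15, sd = 0.5)
    expect_equal(icc(x1, x2)$value, icc(x2, x1)$value)
    expect_equal(icc(3 * x1 + 7, 3 * x2 + 7)$value, icc(x1, x2)$value,
                 tolerance = 1e-12)
  })
})

test_that("independent test-retest noise gives mean ICC near 0, below 0.4", {
  vals <- withr_seed(6,
                     replicate(200, icc(rnorm(23), rnorm(23))$value))
  expect_lt(mean(vals), 0.4)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("ICC diagnostics report Bartlett and KS p-values", {
  r <- withr_seed(7, icc(rnorm(20), rnorm(20, sd = 1)))
  expect_true(r$bartlett_p > 0 && r$bartlett_p <= 1)
  expect_true(r$ks_p > 0 && r$ks_p <= 1)
})

test_that("the ICC matrix is 1 on reproduced sessions and NA on constants", {
  labsA <- withr_seed(8, lapply(1:6, function(s)
    sample(1:3, 40, replace = TRUE)))
  dynA <- lapply(labsA, state_dynamics, k = 3)
  m <- suppressMessages(icc_matrix(dynA, dynA, k = 3))
  expect_true(all(is.na(m) | abs(m - 1) < 1e-12))

  # dwell on window counts equals dwell on seconds (shared scale)
  dynS <- lapply(labsA, function(l) {
    d <- state_dynamics(l, tr_s = 2.5, k = 3)
    d$dwell$windows <- d$dwell$seconds
    d
  })
  labsB <- withr_seed(9, lapply(1:6, function(s)
    sample(1:3, 40, replace = TRUE)))
  dynB <- lapply(labsB, state_dynamics, k = 3)
  dynBS <- lapply(labsB, function(l) {
    d <- state_dynamics(l, tr_s = 2.5, k = 3)
    d$dwell$windows <- d$dwell$seconds
    d
  })
  m1 <- suppressMessages(icc_matrix(dynA, dynB, k = 3))
  m2 <- suppressMessages(icc_matrix(dynS, dynBS, k = 3))
  expect_equal(diag(m1), diag(m2), tolerance = 1e-12)

  # a feature constant across subjects is undefined
  const <- lapply(1:5, function(s) state_dynamics(rep(1L, 10), k = 2))
  mc <- suppressMessages(icc_matrix(const, const, k = 2))
  expect_true(all(is.na(mc)))
})

test_that("independent random dynamics give ICC entries centered on 0", {
  withr_seed(10, {
    means <- replicate(40, {
      dA <- lapply(1:23, function(s) state_dynamics(sample(1:3, 60, TRUE), k = 3))
      dB <- lapply(1:23, function(s) state_dynamics(sample(1:3, 60, TRUE), k = 3))
      mean(suppressMessages(icc_matrix(dA, dB, k = 3)), na.rm = TRUE)
    })
    expect_lt(abs(mean(means)), 0.1)
  })
})

test_that("planted retest reliability orders the mean dwell ICC", {
  mean_icc <- function(rho, reps = 60) {
    mean(vapply(seq_len(reps), function(r) {
      sp <- synthetic_spec(n_subjects = 23, windows_per_session = 200,
                           retest_rho = rho, seed = 5000 + r)
      labs <- generate_state_sequence(sp)
      dA <- lapply(labs$I, state_dynamics, k = 5)
      dB <- lapply(labs$II, state_dynamics, k = 5)
      mean(diag(suppressMessages(icc_matrix(dA, dB, 5))), na.rm = TRUE)
    }, numeric(1)))
  }
  i0 <- mean_icc(0); i5 <- mean_icc(0.5); i9 <- mean_icc(0.9)
  expect_lt(i0, i5)
  expect_lt(i5, i9)
})

test_that("dwell-time group tests behave under identity, planted effect and null", {
  dw <- withr_seed(11, matrix(rpois(23 * 4, 40), 23, 4))
  same <- group_difference_test(dw, dw)
  expect_equal(same$paired$p, rep(1, 4))

  # one state with half the mean dwell of the others: huge ANOVA effect
  dwA <- withr_seed(12, cbind(matrix(rpois(23 * 4, 50), 23, 4),
                              rpois(23, 25)))
  dwB <- withr_seed(13, cbind(matrix(rpois(23 * 4, 50), 23, 4),
                              rpois(23, 25)))
  res <- group_difference_test(dwA, dwB)
  expect_true(all(res$anova$p < 0.001))

  # exchangeable states: ANOVA p roughly uniform across replicates
  ps <- withr_seed(14, replicate(100, {
    d <- matrix(rpois(23 * 5, 40), 23, 5)
    group_difference_test(d, d)$anova$p[1]
  }))
  expect_gt(mean(ps > 0.05), 0.75)
  expect_error(group_difference_test(dw[1:2, ], dw[1:2, ]), "n >= 3")
})
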