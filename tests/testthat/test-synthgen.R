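# The synthetic-data generators and their planted ground truth.

test_that("synthetic_spec validates its fields and builds default hub sets", {
  sp <- synthetic_spec(seed = 1)
  expect_equal(sp$n_subjects, 23L)
  expect_equal(sp$n_states, 5L)
  expect_equal(sp$n_regions, 90L)
  expect_equal(sp$windows_per_session, 200L)
  expect_equal(sp$snr, 5)
  expect_length(sp$hub_sets, 5)
  expect_false(anyDuplicated(vapply(sp$hub_sets, paste, collapse = ",",
                                    character(1))) > 0)
  expect_error(synthetic_spec(mean_dwell = 0.5), "mean_dwell")
  expect_error(synthetic_spec(retest_rho = 1.2), "retest_rho")
  expect_error(synthetic_spec(hub_sets = list(1:3, 1:3), n_states = 2),
               "distinct")
})

test_that("state sequences have geometric dwell with the requested mean", {
  sp <- synthetic_spec(n_subjects = 10, windows_per_session = 1000,
                       mean_dwell = 10, seed = 2)
  labs <- generate_state_sequence(sp)
  runs <- unlist(lapply(c(labs$I, labs$II), function(l) rle(l)$lengths))
  # drop truncated final runs; the rest are iid geometric draws
  expect_equal(mean(runs), 10, tolerance = 0.05 * 10)
  expect_true(all(unlist(labs$I) %in% 1:5))
  expect_true(all(vapply(labs$I, length, integer(1)) == 1000))
  # every state appears at the default scale
  expect_setequal(unique(unlist(labs$I)), 1:5)
})

test_that("mean_dwell at the session length gives near-constant sequences", {
  sp <- synthetic_spec(n_subjects = 8, windows_per_session = 50,
                       mean_dwell = 50, seed = 3)
  labs <- generate_state_sequence(sp)
  switches <- vapply(labs$I, function(l) sum(diff(l) != 0), numeric(1))
  expect_lt(mean(switches), 2)
})

test_that("retest_rho = 1 reuses the per-subject propensities across sessions", {
  sp1 <- synthetic_spec(n_subjects = 12, windows_per_session = 2000,
                        retest_rho = 1, seed = 4)
  sp0 <- synthetic_spec(n_subjects = 12, windows_per_session = 2000,
                        retest_rho = 0, seed = 4)
  p1 <- attr(generate_state_sequence(sp1), "propensities")
  expect_identical(p1$I, p1$II)   # construction: shared latent, no fresh noise
  p0 <- attr(generate_state_sequence(sp0), "propensities")
  expect_false(identical(p0$I, p0$II))

  # behavioral consequence: occupancies reproduce better under rho = 1
  occ_cor <- function(labs) {
    oA <- t(vapply(labs$I, function(l) tabulate(l, 5) / length(l), numeric(5)))
    oB <- t(vapply(labs$II, function(l) tabulate(l, 5) / length(l), numeric(5)))
    mean(vapply(seq_len(nrow(oA)), function(s) cor(oA[s, ], oB[s, ]),
                numeric(1)))
  }
  c1 <- occ_cor(generate_state_sequence(sp1))
  c0 <- occ_cor(generate_state_sequence(sp0))
  expect_gt(c1, c0)
})

test_that("centrality series carry the planted hub structure", {
  sp <- synthetic_spec(n_subjects = 3, n_states = 3, n_regions = 30,
                       windows_per_session = 40, snr = 1e9, seed = 5)
  gen <- generate_centrality_series(sp)
  tpl <- gen$templates
  # noiseless limit: each window equals its (z-scored) state template
  zt <- zscore_rows(tpl)
  for (s in 1:3) {
    labs <- gen$labels$I[[s]]
    expect_equal(unname(gen$samples$I[[s]]),
                 unname(zt[labs, , drop = FALSE]), tolerance = 1e-3)
  }
  # hub detection on a noiseless template recovers exactly the planted set
  for (st in 1:3) {
    hubs <- detect_hubs(tpl[st, ], multiplier = 1)
    expect_setequal(match(hubs$members, colnames(tpl)), sp$hub_sets[[st]])
  }
})

test_that("state recovery from centrality series degrades as snr falls", {
  acc_at <- function(snr) {
    sp <- synthetic_spec(n_subjects = 4, n_states = 3, n_regions = 30,
                         windows_per_session = 60, snr = snr, seed = 6)
    gen <- generate_centrality_series(sp)
    fit <- suppressMessages(
      two_stage_fit(gen$samples$I, 3, seed = 7))
    mt <- match_states(metastate:::state_templates(sp), fit$group$centers)
    mean(unlist(Map(function(pred, truth)
      mean(pred == mt$permutation[truth]),
      fit$subject_labels, gen$labels$I)))
  }
  a5 <- acc_at(5); a1 <- acc_at(1); a02 <- acc_at(0.2)
  expect_gt(a5, 0.95)
  expect_gte(a5, a1)
  expect_gte(a1, a02)
})

test_that("ROI time series re-expose planted states through the full pipeline", {
  sp <- synthetic_spec(n_subjects = 4, n_states = 3, n_regions = 40,
                       windows_per_session = 40, seed = 9)  # default snr
  gen <- generate_roi_timeseries(sp, width_volumes = 24)

  # hub regions co-fluctuate within their windows
  ts1 <- gen$timeseries$I[[1]]
  labs1 <- gen$labels$I[[1]]
  hub_cors <- bg_cors <- c()
  for (w in seq_len(min(100, length(labs1)))) {
    rows <- ((w - 1) * 24 + 1):(w * 24)
    cc <- cor(ts1$signal[rows, ])
    h <- sp$hub_sets[[labs1[w]]]
    hub_cors <- c(hub_cors, mean(cc[h, h][upper.tri(cc[h, h])]))
    b <- setdiff(seq_len(40), h)[1:10]
    bg_cors <- c(bg_cors, mean(cc[b, b][upper.tri(cc[b, b])]))
  }
  expect_gt(mean(hub_cors), mean(bg_cors) + 0.2)

  # windowed networks -> centrality -> clustering recovers the labels
  subj <- lapply(gen$timeseries$I, function(ts) {
    wseq <- sliding_window_fc(ts, 24, 24)
    centrality_sequence(wseq, "eigenvector", density = 0.40)$scores
  })
  fit <- suppressMessages(two_stage_fit(subj, 3, seed = 10))
  mt <- match_states(metastate:::state_templates(sp), fit$group$centers)
  acc <- mean(unlist(Map(function(pred, truth)
    mean(pred == mt$permutation[truth]),
    fit$subject_labels, gen$labels$I)))
  expect_gt(acc, 0.8)

  # determinism: same spec and seed, identical series
  gen2 <- generate_roi_timeseries(sp, width_volumes = 24)
  expect_identical(gen$timeseries$I[[2]]$signal, gen2$timeseries$I[[2]]$signal)
})

test_that("core-periphery networks put the core on top and are reproducible", {
  W <- generate_core_periphery_network(30, 6, seed = 20)
  s <- rowSums(W)
  expect_setequal(order(-s)[1:6], 1:6)
  expect_equal(W, generate_core_periphery_network(30, 6, seed = 20))
  expect_false(identical(W, generate_core_periphery_network(30, 6, seed = 21)))
  # every peripheral node is attached
  expect_true(all(rowSums(W != 0) >= 1))
  expect_error(generate_core_periphery_network(5, 5), "core_size")
})
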