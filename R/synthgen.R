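# Synthetic multi-subject, two-session datasets with planted metastates so
# every pipeline stage can be validated against known ground truth: Markov
# state sequences with controllable test-retest reliability, z-scored
# centrality patterns with state-specific hub sets, ROI BOLD series whose
# windowed networks re-expose the planted states, and core-periphery
# structural networks for rich-club analysis.

#' Specification of a synthetic metastate dataset
#'
#' Defaults mirror the reference study conditions: 23 subjects scanned in
#' two sessions, 5 metastates over 90 regions, 200 windows per session at
#' TR 2.5 s. Hub sets default to disjoint blocks of `floor(n_regions /
#' (n_states + 1))` regions.
#'
#' @param n_subjects Number of subjects.
#' @param n_states Number of planted metastates K.
#' @param n_regions Number of regions.
#' @param hub_sets Optional list of K distinct, nonempty region-index
#'   vectors (the planted hubs of each state).
#' @param windows_per_session Windows generated per subject and session.
#' @param mean_dwell Mean dwell length in windows (geometric dwell model).
#' @param snr Signal-to-noise ratio: template amplitude 1 against N(0, 1)
#'   noise scaled by 1/snr. `snr = 0` yields pure noise (unrecoverable).
#' @param retest_rho Test-retest correlation of per-subject state
#'   propensities across sessions, in `[0, 1]`.
#' @param tr_s Repetition time in seconds.
#' @param seed Integer master seed; all generators derive sub-streams.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 23, n_states = 5, n_regions = 90,
                           hub_sets = NULL, windows_per_session = 200,
                           mean_dwell = 10, snr = 5, retest_rho = 0.8,
                           tr_s = 2.5, seed = 1L) {
  stopifnot(is_count(n_subjects), n_subjects >= 1,
            is_count(n_states), n_states >= 1,
            is_count(n_regions), n_regions >= 2,
            is_count(windows_per_session), windows_per_session >= 1)
  if (mean_dwell < 1) stopf("mean_dwell must be >= 1 window")
  if (snr < 0) stopf("snr must be >= 0")
  if (retest_rho < 0 || retest_rho > 1) stopf("retest_rho must lie in [0, 1]")
  if (is.null(hub_sets)) {
    block <- max(2L, n_regions %/% (n_states + 1L))
    if (block * n_states > n_regions)
      stopf("n_regions too small for %d disjoint hub sets", n_states)
    hub_sets <- lapply(seq_len(n_states),
                       function(s) ((s - 1L) * block + 1L):(s * block))
  }
  if (length(hub_sets) != n_states) stopf("need one hub set per state")
  if (any(vapply(hub_sets, length, integer(1)) == 0))
    stopf("hub sets must be nonempty")
  if (anyDuplicated(vapply(hub_sets, function(h)
    paste(sort(h), collapse = ","), character(1))))
    stopf("hub sets must be pairwise distinct")
  if (any(unlist(hub_sets) < 1 | unlist(hub_sets) > n_regions))
    stopf("hub indices out of range")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_states = as.integer(n_states),
                 n_regions = as.integer(n_regions),
                 hub_sets = lapply(hub_sets, as.integer),
                 windows_per_session = as.integer(windows_per_session),
                 mean_dwell = mean_dwell, snr = snr,
                 retest_rho = retest_rho, tr_s = tr_s,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Planted state-label sequences for two sessions
#'
#' Markov chains with geometric dwell (mean `mean_dwell` windows). Each
#' subject carries a per-state Gaussian propensity that tilts the
#' off-diagonal transition weights (softmax with gain 0.8), creating
#' between-subject variability in dwell/transition features; session II's
#' propensities are `rho * latent + sqrt(1 - rho^2) * fresh noise`, so
#' `retest_rho` controls test-retest reliability and `retest_rho = 1` makes
#' the two sessions' propensities identical.
#'
#' @param spec A [synthetic_spec()].
#' @return List of two sessions (`I`, `II`), each a list of per-subject
#'   integer label vectors in `1..K`.
#' @export
generate_state_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_states
  nw <- spec$windows_per_session
  p_leave <- if (spec$mean_dwell <= 1) 1 else 1 / spec$mean_dwell
  gain <- 0.8
  with_seed(sub_seed(spec$seed, 1L), {
    latent <- matrix(stats::rnorm(spec$n_subjects * K), spec$n_subjects, K)
    fresh <- matrix(stats::rnorm(spec$n_subjects * K), spec$n_subjects, K)
    prop <- list(I = latent,
                 II = spec$retest_rho * latent +
                   sqrt(1 - spec$retest_rho^2) * fresh)
    out <- lapply(prop, function(pm) {
      lapply(seq_len(spec$n_subjects), function(s) {
        w <- exp(gain * pm[s, ])
        labs <- integer(0)
        state <- sample.int(K, 1, prob = w)
        while (length(labs) < nw) {
          run <- 1L + stats::rgeom(1, p_leave)
          labs <- c(labs, rep(state, run))
          if (K > 1) {
            w_next <- w
            w_next[state] <- 0
            state <- sample.int(K, 1, prob = w_next)
          }
        }
        labs[seq_len(nw)]
      })
    })
    # per-subject-per-state propensities, retrievable for validation
    attr(out, "propensities") <- prop
    out
  })
}

#' @noRd
state_templates <- function(spec) {
  tpl <- matrix(0, spec$n_states, spec$n_regions,
                dimnames = list(paste0("S", seq_len(spec$n_states)),
                                sprintf("R%03d", seq_len(spec$n_regions))))
  for (s in seq_len(spec$n_states)) {
    h <- spec$hub_sets[[s]]
    tpl[s, h] <- 1
    tpl[s, -h] <- -length(h) / (spec$n_regions - length(h))
  }
  tpl
}

#' Synthetic z-scored centrality sequences
#'
#' Each window's vector is its state's template (hubs at +1, non-hubs at a
#' negative level making the template zero-mean) plus N(0, 1) noise scaled
#' by `1/snr`, then z-normalized across regions — the same shape the real
#' pipeline feeds to clustering. At high snr, [detect_hubs()] on a state
#' template recovers exactly the planted hub set.
#'
#' @param spec A [synthetic_spec()].
#' @param labels Label sequences from [generate_state_sequence()] (generated
#'   if omitted).
#' @return List with `samples` (sessions -> subjects -> window x region
#'   matrix), `labels`, `templates` (K x region matrix).
#' @export
generate_centrality_series <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(labels)) labels <- generate_state_sequence(spec)
  tpl <- state_templates(spec)
  noise_sd <- if (spec$snr == 0) 1 else 1 / spec$snr
  signal_scale <- if (spec$snr == 0) 0 else 1
  samples <- with_seed(sub_seed(spec$seed, 2L), {
    lapply(labels, function(session) {
      lapply(session, function(labs) {
        x <- signal_scale * tpl[labs, , drop = FALSE] +
          matrix(stats::rnorm(length(labs) * spec$n_regions, sd = noise_sd),
                 length(labs), spec$n_regions)
        t(apply(x, 1, function(row) (row - mean(row)) / stats::sd(row)))
      })
    })
  })
  for (sess in names(samples))
    for (s in seq_along(samples[[sess]]))
      colnames(samples[[sess]][[s]]) <- colnames(tpl)
  list(samples = samples, labels = labels, templates = tpl)
}

#' Synthetic ROI BOLD time series with planted network states
#'
#' For each non-overlapping window of `width` volumes, draws multivariate
#' Gaussian signal with a state-specific single-factor covariance: hub
#' regions of the active state load on a shared factor with loading
#' `sqrt(0.3 * snr)` (hub-hub correlation ~0.6 at snr 5), other regions are
#' independent noise. Windowing the concatenated series at the generator's
#' width (step = width) re-exposes the planted states.
#'
#' @param spec A [synthetic_spec()].
#' @param labels Label sequences from [generate_state_sequence()] (generated
#'   if omitted).
#' @param width_volumes Volumes per window (default 24, i.e. 60 s at TR
#'   2.5 s).
#' @return List with `timeseries` (sessions -> subjects ->
#'   [roi_timeseries()]), `labels`, `width_volumes`.
#' @export
generate_roi_timeseries <- function(spec, labels = NULL, width_volumes = 24) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(labels)) labels <- generate_state_sequence(spec)
  a_hub <- sqrt(0.3 * spec$snr)
  N <- spec$n_regions
  region_names <- sprintf("R%03d", seq_len(N))
  ts_out <- with_seed(sub_seed(spec$seed, 3L), {
    lapply(labels, function(session) {
      lapply(session, function(labs) {
        sig <- matrix(0, length(labs) * width_volumes, N)
        for (w in seq_along(labs)) {
          rows <- ((w - 1) * width_volumes + 1):(w * width_volumes)
          f <- stats::rnorm(width_volumes)
          eps <- matrix(stats::rnorm(width_volumes * N), width_volumes, N)
          load <- rep(0, N)
          load[spec$hub_sets[[labs[w]]]] <- a_hub
          sig[rows, ] <- f %o% load + eps
        }
        roi_timeseries(sig, tr_s = spec$tr_s, labels = region_names)
      })
    })
  })
  list(timeseries = ts_out, labels = labels,
       width_volumes = as.integer(width_volumes))
}

#' Synthetic core-periphery weighted network
#'
#' A complete high-weight core (weights U(0.8, 1.0)) embedded in a sparse
#' low-weight periphery (pairwise density 0.15, weights U(0.05, 0.2)); every
#' peripheral node attaches to at least one core node, so core nodes occupy
#' the top strength ranks and the network carries a planted rich club.
#'
#' @param n Total nodes.
#' @param core_size Core nodes (< n).
#' @param seed Integer seed.
#' @return Square symmetric labeled weight matrix with zero diagonal.
#' @export
generate_core_periphery_network <- function(n = 30, core_size = 6, seed = 1L) {
  stopifnot(is_count(n), is_count(core_size))
  if (core_size >= n) stopf("core_size must be < n")
  labs <- sprintf("N%02d", seq_len(n))
  with_seed(seed, {
    W <- matrix(0, n, n, dimnames = list(labs, labs))
    core <- seq_len(core_size)
    for (i in core) for (j in core) if (j > i)
      W[i, j] <- W[j, i] <- stats::runif(1, 0.8, 1.0)
    periph <- setdiff(seq_len(n), core)
    for (i in periph) {
      anchor <- sample(core, 1)
      W[i, anchor] <- W[anchor, i] <- stats::runif(1, 0.05, 0.2)
    }
    for (i in periph) for (j in seq_len(n)) if (j > i && W[i, j] == 0)
      if (stats::runif(1) < 0.15)
        W[i, j] <- W[j, i] <- stats::runif(1, 0.05, 0.2)
    W
  })
}

#' Write a complete synthetic two-session dataset to disk
#'
#' Materializes the `simulate` CLI subcommand: per subject and session a TSV
#' ROI time-series file and an all-zero FD vector, plus a `truth.json` with
#' the planted labels, templates and hub sets.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param width_volumes Window width used by the time-series generator.
#' @return Invisibly, a manifest data frame (subject, session, paths).
#' @export
write_synthetic_dataset <- function(spec, dir, width_volumes = 24) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_roi_timeseries(spec, width_volumes = width_volumes)
  manifest <- NULL
  for (sess in names(gen$timeseries)) {
    for (s in seq_along(gen$timeseries[[sess]])) {
      ts <- gen$timeseries[[sess]][[s]]
      base <- sprintf("sub%02d_ses%s", s, sess)
      ts_path <- file.path(dir, paste0(base, "_bold.tsv"))
      utils::write.table(
        stats::setNames(as.data.frame(ts$signal), ts$labels),
        ts_path, sep = "\t", quote = FALSE, row.names = FALSE)
      fd_path <- file.path(dir, paste0(base, "_fd.txt"))
      writeLines(format(rep(0, ts$n_volumes)), fd_path)
      manifest <- rbind(manifest,
                        data.frame(subject = sprintf("sub%02d", s),
                                   session = sess, timeseries = ts_path,
                                   fd = fd_path))
    }
  }
  truth <- list(labels = gen$labels,
                templates = state_templates(spec),
                hub_sets = spec$hub_sets,
                width_volumes = gen$width_volumes,
                tr_s = spec$tr_s, seed = spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
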