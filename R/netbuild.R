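# Construction of static and sliding-window functional connectivity:
# Fisher-z transformed Pearson correlation, motion censoring, proportional
# density thresholding, and the group positive-connection mask.

#' Censor high-motion volumes
#'
#' Removes volumes whose framewise displacement exceeds the threshold.
#' Windows are later defined on the concatenated post-censoring series:
#' censored volumes are deleted, never interpolated. Subjects left with
#' fewer than `min_volumes` usable volumes are flagged excluded.
#'
#' @param ts A [roi_timeseries()] object.
#' @param fd Per-volume framewise displacement (mm), same length as the
#'   number of volumes.
#' @param fd_threshold Censoring threshold in mm (volumes with FD strictly
#'   above it are removed).
#' @param min_volumes Minimum remaining volumes before exclusion.
#' @return A list with `ts` (censored series or `NULL` if excluded),
#'   `excluded` (logical), `kept` (indices of retained volumes) and
#'   `n_censored`.
#' @export
censor_volumes <- function(ts, fd, fd_threshold = 0.3, min_volumes = 200) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (length(fd) != ts$n_volumes)
    stopf("FD length (%d) does not match volume count (%d)",
          length(fd), ts$n_volumes)
  keep <- which(fd <= fd_threshold)
  excluded <- length(keep) < min_volumes
  out_ts <- NULL
  if (!excluded)
    out_ts <- roi_timeseries(ts$signal[keep, , drop = FALSE], ts$tr_s,
                             labels = ts$labels)
  list(ts = out_ts, excluded = excluded, kept = keep,
       n_censored = ts$n_volumes - length(keep))
}

#' @noRd
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' @noRd
fc_matrix <- function(signal, labels) {
  sds <- apply(signal, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance region(s): %s",
          paste(labels[sds == 0], collapse = ", "))
  z <- fisher_z(stats::cor(signal))
  diag(z) <- 0
  dimnames(z) <- list(labels, labels)
  z
}

#' Static Fisher-z functional connectivity
#'
#' Pearson correlation across all volumes, Fisher z-transformed
#' (`atanh`, with |r| clamped at 1 - 1e-7 so degenerate pairs stay finite),
#' zero diagonal.
#'
#' @param ts A [roi_timeseries()] object with at least 3 volumes.
#' @return Square symmetric labeled matrix in Fisher-z units.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ts$n_volumes < 3) stopf("need >= 3 volumes for a correlation")
  fc_matrix(ts$signal, ts$labels)
}

#' Sliding-window functional connectivity sequence
#'
#' Rectangular windows of `width_volumes` volumes stepped by `step_volumes`;
#' window w covers volumes `[start, start + width)` of the (post-censoring)
#' series, and each window yields the Fisher-z FC of that slice. The number
#' of windows is `floor((T - width) / step) + 1`.
#'
#' @param ts A [roi_timeseries()] object.
#' @param width_volumes Window width in volumes (>= 2).
#' @param step_volumes Step between consecutive window starts, in volumes.
#' @return An object of class `"windowed_networks"`: list with `matrices`
#'   (list of region x region Fisher-z matrices), `width_volumes`,
#'   `step_volumes`, `window_starts` (0-based volume indices), `tr_s`,
#'   `labels`.
#' @export
sliding_window_fc <- function(ts, width_volumes, step_volumes = 1) {
  stopifnot(inherits(ts, "roi_timeseries"))
  T_ <- ts$n_volumes
  if (!is_count(width_volumes) || width_volumes < 2)
    stopf("window width must be an integer >= 2")
  if (width_volumes > T_)
    stopf("window width (%d) exceeds usable volumes (%d)", width_volumes, T_)
  if (!is_count(step_volumes) || step_volumes < 1)
    stopf("step must be a positive integer")
  starts <- seq(0L, T_ - width_volumes, by = step_volumes)
  mats <- lapply(starts, function(s) {
    sl <- ts$signal[(s + 1):(s + width_volumes), , drop = FALSE]
    fc_matrix(sl, ts$labels)
  })
  structure(list(matrices = mats,
                 width_volumes = as.integer(width_volumes),
                 step_volumes = as.integer(step_volumes),
                 window_starts = as.integer(starts),
                 tr_s = ts$tr_s, labels = ts$labels),
            class = "windowed_networks")
}

#' @export
print.windowed_networks <- function(x, ...) {
  cat(sprintf("<windowed_networks> %d windows (%d volumes wide, step %d) x %d regions\n",
              length(x$matrices), x$width_volumes, x$step_volumes,
              length(x$labels)))
  invisible(x)
}

#' Proportional density thresholding
#'
#' Retains exactly `round(density * M)` of the strongest off-diagonal edges
#' (M = N(N-1)/2, ranked by signed weight, descending — the analysis focuses
#' on positive connections) with their original weights; all other edges are
#' set to zero. Ties across the cut are broken by (row, column) order with a
#' warning.
#'
#' @param fc Square symmetric labeled matrix.
#' @param density Fraction of edges to retain, in (0, 1].
#' @return Sparse weighted matrix of the same shape, symmetric, zero diagonal.
#' @export
proportional_threshold <- function(fc, density) {
  assert_square_symmetric(fc, "fc")
  if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
  n <- nrow(fc)
  ut <- upper.tri(fc)
  w <- fc[ut]
  m_edges <- length(w)
  keep_n <- as.integer(floor(abs(density * m_edges) + 0.5))  # round half away from zero
  if (keep_n >= m_edges) return(fc)
  ord <- order(w, decreasing = TRUE)
  if (keep_n > 0 && keep_n < m_edges && w[ord[keep_n]] == w[ord[keep_n + 1]])
    warnf("ties at the density cut; broken by (row, col) order")
  keep <- logical(m_edges)
  keep[ord[seq_len(keep_n)]] <- TRUE
  w[!keep] <- 0
  out <- matrix(0, n, n, dimnames = dimnames(fc))
  out[ut] <- w
  out <- out + t(out)
  out
}

#' Group positive-connection mask
#'
#' Guidance for choosing the proportional density: per-edge one-sided
#' one-sample t-test of the subjects' Fisher-z values against zero,
#' Benjamini-Hochberg corrected over all edges; returns the binary mask of
#' significantly positive connections and its edge density.
#'
#' @param static_fcs List of >= 3 square symmetric Fisher-z matrices with
#'   identical labels.
#' @param q FDR level (default 0.05).
#' @return List with `mask` (binary symmetric matrix) and `density`
#'   (fraction of significant edges).
#' @export
group_positive_mask <- function(static_fcs, q = 0.05) {
  if (length(static_fcs) < 3) stopf("need >= 3 subjects for a group t-test")
  labs <- rownames(static_fcs[[1]])
  for (m in static_fcs) {
    assert_square_symmetric(m, "static FC")
    if (!identical(rownames(m), labs))
      stopf("mismatched region labels across subjects")
  }
  n <- nrow(static_fcs[[1]])
  ut <- which(upper.tri(static_fcs[[1]]))
  vals <- vapply(static_fcs, function(m) m[ut], numeric(length(ut)))
  pv <- apply(vals, 1, function(x) {
    if (stats::sd(x) == 0) return(if (mean(x) > 0) 0 else 1)
    stats::t.test(x, alternative = "greater")$p.value
  })
  sig <- stats::p.adjust(pv, method = "BH") < q
  mask <- matrix(0, n, n, dimnames = list(labs, labs))
  mask[ut[sig]] <- 1
  mask <- mask + t(mask)
  list(mask = mask, density = mean(sig))
}
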