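# Temporal dynamics of metastates (dwell time, transition counts) and the
# pooled-moment intraclass correlation coefficient used for test-retest
# reliability across two scanning sessions.

#' Dwell time per metastate
#'
#' Total occupancy of each state over a label sequence: number of windows
#' assigned to the state, and that count multiplied by the TR in seconds.
#'
#' @param labels Integer state sequence (values in `1..k`).
#' @param tr_s Repetition time in seconds.
#' @param k Number of states (default `max(labels)`).
#' @return Data frame with columns `state`, `windows`, `seconds`.
#' @export
dwell_time <- function(labels, tr_s = 2.5, k = max(labels)) {
  if (!length(labels)) stopf("empty label sequence")
  counts <- tabulate(labels, nbins = k)
  data.frame(state = seq_len(k), windows = counts, seconds = counts * tr_s)
}

#' Transition-count matrix
#'
#' Entry (a, b), a != b, counts consecutive-window switches from state a to
#' state b; self-pairs (no switch) are not counted, so the diagonal is zero.
#' Columns of a state collect the switches into that state, rows the
#' switches out of it.
#'
#' @inheritParams dwell_time
#' @return k x k integer matrix of transition counts.
#' @export
transition_matrix <- function(labels, k = max(labels)) {
  if (!length(labels)) stopf("empty label sequence")
  tm <- matrix(0L, k, k,
               dimnames = list(paste0("S", seq_len(k)), paste0("S", seq_len(k))))
  if (length(labels) > 1) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    sw <- from != to
    if (any(sw)) {
      tab <- table(factor(from[sw], levels = seq_len(k)),
                   factor(to[sw], levels = seq_len(k)))
      tm <- tm + unclass(tab)
      dimnames(tm) <- list(paste0("S", seq_len(k)), paste0("S", seq_len(k)))
    }
  }
  tm
}

#' Intraclass correlation coefficient (pooled-moment form)
#'
#' Test-retest reliability of a per-subject feature measured in two
#' sessions:
#' \deqn{ICC = \frac{\sum_i (x_{1i} - \bar x)(x_{2i} - \bar x)}{(n-1) s_x^2}}
#' where \eqn{\bar x} is the mean of all 2n observations and the pooled
#' variance uses divisor \eqn{2(n-1)}, so a perfectly reproduced measurement
#' scores exactly 1. Values near 0 mean no reliability; by convention
#' ICC < 0.4 is poor and > 0.75 good. The value is reported raw (it can be
#' negative; no clamping). Bartlett (equal variances across sessions) and
#' Kolmogorov-Smirnov (normality of pooled standardized values) diagnostics
#' are attached.
#'
#' @param x1,x2 Per-subject feature values for sessions I and II (equal
#'   length, n >= 3).
#' @return Object of class `"icc_result"`: list with `value`, `n`,
#'   `bartlett_p`, `ks_p`.
#' @export
icc <- function(x1, x2) {
  if (length(x1) != length(x2)) stopf("sessions differ in length")
  n <- length(x1)
  if (n < 3) stopf("need n >= 3 subjects for ICC")
  xbar <- mean(c(x1, x2))
  ss <- sum((c(x1, x2) - xbar)^2)
  if (ss == 0) stopf("reliability undefined for constant feature")
  s2 <- ss / (2 * (n - 1))
  value <- sum((x1 - xbar) * (x2 - xbar)) / ((n - 1) * s2)
  bart <- tryCatch(
    stats::bartlett.test(list(x1, x2))$p.value, error = function(e) NA_real_)
  pooled <- (c(x1, x2) - xbar) / sqrt(s2)
  ks <- tryCatch(
    suppressWarnings(stats::ks.test(pooled, "pnorm")$p.value),
    error = function(e) NA_real_)
  structure(list(value = value, n = n, bartlett_p = bart, ks_p = ks),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (n = %d; Bartlett p = %.3g, KS p = %.3g)\n",
              x$value, x$n, x$bartlett_p, x$ks_p))
  invisible(x)
}

#' Per-subject state dynamics
#'
#' Convenience wrapper bundling dwell and transition features of one label
#' sequence.
#'
#' @inheritParams dwell_time
#' @return List with `dwell` (data frame), `transitions` (k x k counts),
#'   `n_windows`.
#' @export
state_dynamics <- function(labels, tr_s = 2.5, k = max(labels)) {
  list(dwell = dwell_time(labels, tr_s, k),
       transitions = transition_matrix(labels, k),
       n_windows = length(labels))
}

#' Test-retest ICC matrix of dwell and transition features
#'
#' Diagonal entry (s, s) is the ICC of state s dwell time (window counts;
#' ICC is invariant to the common TR scale); off-diagonal (a, b) is the ICC
#' of the a -> b transition count. States must already be matched across
#' sessions (see [match_states()]). Features constant across subjects have
#' an undefined ICC and are reported as `NA`.
#'
#' @param dynamicsA,dynamicsB Lists of per-subject [state_dynamics()]
#'   results for sessions I and II (same subject order).
#' @param k Number of states.
#' @return k x k numeric matrix with `NA` for undefined entries.
#' @export
icc_matrix <- function(dynamicsA, dynamicsB, k) {
  if (length(dynamicsA) != length(dynamicsB))
    stopf("sessions differ in subject count")
  n <- length(dynamicsA)
  feat <- function(dyn, a, b) {
    vapply(dyn, function(d) {
      if (a == b) as.numeric(d$dwell$windows[a]) else as.numeric(d$transitions[a, b])
    }, numeric(1))
  }
  out <- matrix(NA_real_, k, k,
                dimnames = list(paste0("S", seq_len(k)), paste0("S", seq_len(k))))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    xa <- feat(dynamicsA, a, b)
    xb <- feat(dynamicsB, a, b)
    if (stats::sd(c(xa, xb)) == 0) {
      message(sprintf("feature (%d,%d) constant across subjects; ICC undefined", a, b))
      next
    }
    out[a, b] <- icc(xa, xb)$value
  }
  out
}

#' Session and state effects on dwell time
#'
#' Paired t-test per state between sessions (FDR-adjusted across states) and
#' a one-way ANOVA across states within each session.
#'
#' @param dwellA,dwellB Subject x state matrices of dwell times for
#'   sessions I and II.
#' @return List with `paired` (data frame: state, t, p, p_fdr) and `anova`
#'   (data frame: session, F, p).
#' @export
group_difference_test <- function(dwellA, dwellB) {
  dwellA <- as.matrix(dwellA); dwellB <- as.matrix(dwellB)
  if (!all(dim(dwellA) == dim(dwellB))) stopf("session matrices differ in shape")
  if (nrow(dwellA) < 3) stopf("need n >= 3 subjects")
  k <- ncol(dwellA)
  paired <- data.frame(state = seq_len(k), t = NA_real_, p = NA_real_)
  for (s in seq_len(k)) {
    d <- dwellA[, s] - dwellB[, s]
    if (stats::sd(d) == 0) {
      paired$t[s] <- 0
      paired$p[s] <- 1  # zero differences: no evidence of change, by convention
    } else {
      tt <- stats::t.test(dwellA[, s], dwellB[, s], paired = TRUE)
      paired$t[s] <- unname(tt$statistic)
      paired$p[s] <- tt$p.value
    }
  }
  paired$p_fdr <- stats::p.adjust(paired$p, method = "BH")
  anova_one <- function(dw, session) {
    long <- data.frame(dwell = as.vector(dw),
                       state = factor(rep(seq_len(k), each = nrow(dw))))
    fit <- stats::aov(dwell ~ state, data = long)
    sm <- summary(fit)[[1]]
    data.frame(session = session, F = sm$`F value`[1], p = sm$`Pr(>F)`[1])
  }
  list(paired = paired,
       anova = rbind(anova_one(dwellA, "I"), anova_one(dwellB, "II")))
}
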