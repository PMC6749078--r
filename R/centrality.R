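# Node centrality of weighted windowed networks. Degree centrality is the
# weighted strength sum(A[i, j], j != i); eigenvector centrality is the
# leading eigenvector of the (nonnegative) weighted adjacency matrix, so a
# node is central when it connects to central nodes.

#' Degree centrality (weighted strength)
#'
#' @param W Square symmetric weighted matrix with zero diagonal.
#' @return Named numeric vector of per-region strengths.
#' @export
degree_centrality <- function(W) {
  assert_square_symmetric(W, "W")
  out <- rowSums(W)
  names(out) <- rownames(W)
  out
}

#' Eigenvector centrality
#'
#' The leading eigenvector of `W` (eigenvalue lambda_1), sign-fixed
#' nonnegative and normalized to unit Euclidean norm, satisfying
#' `CE = (1/lambda_1) W CE`. Negative weights (Fisher-z of negative
#' correlations surviving the threshold) are zeroed first so the
#' Perron-Frobenius leading eigenvector is nonnegative. For disconnected
#' graphs the leading eigenvector of the full matrix is used (mass
#' concentrates on the dominant component) and isolated nodes are reported
#' in a warning.
#'
#' @param W Square symmetric weighted matrix.
#' @return Named nonnegative numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(W) {
  assert_square_symmetric(W, "W")
  W <- pmax(W, 0)
  diag(W) <- 0
  if (all(W == 0)) stopf("centrality undefined for an all-zero matrix")
  iso <- which(rowSums(W) == 0)
  if (length(iso))
    warnf("isolated node(s) in eigenvector centrality: %s",
          paste(if (is.null(rownames(W))) iso else rownames(W)[iso],
                collapse = ", "))
  n <- nrow(W)
  if (n <= 256) {
    es <- eigen(W, symmetric = TRUE)
    if (n >= 2 && abs(es$values[1] - es$values[2]) <=
        1e-12 * max(1, abs(es$values[1])))
      stopf("degenerate leading eigenvalue; centrality not unique")
    v <- es$vectors[, 1]
  } else {
    v <- power_iteration(W)
  }
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  names(v) <- rownames(W)
  v
}

#' @noRd
power_iteration <- function(W, tol = 1e-10, max_iter = 10000L) {
  v <- rep(1 / sqrt(nrow(W)), nrow(W))
  for (i in seq_len(max_iter)) {
    nv <- as.numeric(W %*% v)
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) stopf("power iteration collapsed to zero")
    nv <- nv / nrm
    if (max(abs(nv - v)) < tol) return(nv)
    v <- nv
  }
  warnf("power iteration did not converge in %d iterations", max_iter)
  v
}

#' @noRd
row_zscore <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)            # sample SD, divisor n - 1
  if (s == 0) return(list(z = rep(0, length(x)), constant = TRUE))
  list(z = (x - mu) / s, constant = FALSE)
}

#' Windowed centrality sequence
#'
#' For each window: threshold the Fisher-z matrix at `density`, compute the
#' requested centrality, then z-normalize across regions (sample SD) so each
#' window's pattern is comparable — these rows are the clustering samples.
#' Constant raw rows (degenerate windows) become all-zero rows and are
#' flagged.
#'
#' @param wseq A `"windowed_networks"` object from [sliding_window_fc()].
#' @param kind `"eigenvector"` (default) or `"degree"`.
#' @param density Proportional threshold applied per window before the
#'   centrality computation.
#' @return Object of class `"centrality_sequence"`: list with `scores`
#'   (window x region matrix of z-scores), `kind`, `density`,
#'   `constant_windows` (indices flagged all-zero), `tr_s`, `labels`.
#' @export
centrality_sequence <- function(wseq, kind = c("eigenvector", "degree"),
                                density = 0.40) {
  stopifnot(inherits(wseq, "windowed_networks"))
  kind <- match.arg(kind)
  fun <- switch(kind, eigenvector = eigenvector_centrality,
                degree = degree_centrality)
  n_win <- length(wseq$matrices)
  scores <- matrix(NA_real_, n_win, length(wseq$labels),
                   dimnames = list(NULL, wseq$labels))
  constant <- integer(0)
  for (w in seq_len(n_win)) {
    thr <- proportional_threshold(wseq$matrices[[w]], density)
    raw <- tryCatch(suppressWarnings(fun(thr)),
                    error = function(e)
                      stopf("window %d: %s", w, conditionMessage(e)))
    zs <- row_zscore(raw)
    if (zs$constant) constant <- c(constant, w)
    scores[w, ] <- zs$z
  }
  structure(list(scores = scores, kind = kind, density = density,
                 constant_windows = constant, tr_s = wseq$tr_s,
                 labels = wseq$labels),
            class = "centrality_sequence")
}

#' @export
print.centrality_sequence <- function(x, ...) {
  cat(sprintf("<centrality_sequence> %d windows x %d regions (%s, density %.2f)\n",
              nrow(x$scores), ncol(x$scores), x$kind, x$density))
  invisible(x)
}
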