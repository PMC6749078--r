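# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that seeded package
#' functions are pure in (inputs, seed) without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Deterministic sub-stream seed derived from a master seed
#'
#' Lehmer-style mixing keeps derived seeds inside the 32-bit integer range so
#' independent pipeline stages can be regenerated in isolation.
#' @noRd
sub_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(stream %% 7 + 1)) s <- (s * 48271) %% 2147483647
  as.integer((s + 1103515245 * (stream %% 1024)) %% 2147483647)
}

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

#' @noRd
assert_square_symmetric <- function(values, what = "matrix", tol = 1e-8) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stopf("%s must be square (got %d x %d)", what,
          NROW(values), NCOL(values))
  if (max(abs(values - t(values))) > tol)
    stopf("%s must be symmetric (max asymmetry %.3g)", what,
          max(abs(values - t(values))))
  invisible(TRUE)
}

#' One log line per pipeline stage, to stderr (and optionally a file)
#' @noRd
log_stage <- function(stage, ..., logfile = NULL) {
  kv <- list(...)
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste(names(kv), unlist(lapply(kv, format)),
                       sep = "=", collapse = " "))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(msg)
}
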