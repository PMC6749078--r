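#' Analysis configuration
#'
#' Bundles every tunable parameter of the metastate pipeline with the
#' defaults used throughout: a 60 s rectangular sliding window stepped by
#' 1 TR (TR = 2.5 s), 40% proportional edge density, framewise-displacement
#' censoring at 0.3 mm with subjects excluded below 200 remaining volumes,
#' candidate cluster numbers 2..10, correlation distance, 1000 null networks
#' for rich-club normalization, and a hub threshold of mean + 1 SD.
#'
#' @param window_length_s Sliding-window length in seconds. Must correspond
#'   to an integer number of volumes (>= 2) at `tr_s`.
#' @param window_step_volumes Window step in volumes (TRs).
#' @param tr_s Repetition time in seconds.
#' @param density Fraction of strongest edges retained by proportional
#'   thresholding, in (0, 1].
#' @param k_range Inclusive integer range of candidate cluster numbers
#'   scanned by the elbow criterion (lower bound >= 2).
#' @param k_fixed Optional fixed number of clusters; overrides `k_range`.
#' @param distance Clustering distance identifier; only `"correlation"`
#'   (1 - Pearson r) is implemented.
#' @param n_null Number of degree-preserving null networks for rich-club
#'   normalization.
#' @param hub_sd_multiplier Hubs are regions scoring above
#'   mean + `hub_sd_multiplier` * SD of a centrality pattern.
#' @param fd_threshold_mm Framewise-displacement censoring threshold (mm).
#' @param min_volumes Minimum post-censoring volumes; below this a subject
#'   is flagged excluded.
#' @param seed Integer seed controlling all randomized stages.
#' @return A validated list of class `"metastate_config"`.
#' @examples
#' cfg <- analysis_config(seed = 17)
#' cfg$window_width_volumes  # 24 volumes = 60 s at TR 2.5 s
#' @export
analysis_config <- function(window_length_s = 60,
                            window_step_volumes = 1,
                            tr_s = 2.5,
                            density = 0.40,
                            k_range = c(2L, 10L),
                            k_fixed = NULL,
                            distance = "correlation",
                            n_null = 1000,
                            hub_sd_multiplier = 1,
                            fd_threshold_mm = 0.3,
                            min_volumes = 200,
                            seed = 1L) {
  if (!is.numeric(tr_s) || tr_s <= 0) stopf("tr_s must be positive")
  width <- window_length_s / tr_s
  if (abs(width - round(width)) > 1e-8)
    stopf("window_length_s (%g s) is not an integer number of volumes at TR %g s",
          window_length_s, tr_s)
  width <- as.integer(round(width))
  if (width < 2) stopf("window must span at least 2 volumes (got %d)", width)
  if (!is_count(window_step_volumes) || window_step_volumes < 1)
    stopf("window_step_volumes must be a positive count")
  if (!is.numeric(density) || density <= 0 || density > 1)
    stopf("density must lie in (0, 1]")
  k_range <- as.integer(range(k_range))
  if (k_range[1] < 2) stopf("k_range lower bound must be >= 2")
  if (!is.null(k_fixed)) {
    if (!is_count(k_fixed) || k_fixed < 1) stopf("k_fixed must be a positive count")
    k_fixed <- as.integer(k_fixed)
  }
  distance <- match.arg(distance, "correlation")
  if (!is_count(n_null) || n_null < 1) stopf("n_null must be >= 1")
  if (!is.numeric(hub_sd_multiplier) || length(hub_sd_multiplier) != 1)
    stopf("hub_sd_multiplier must be a single number")
  if (!is.numeric(fd_threshold_mm) || fd_threshold_mm < 0)
    stopf("fd_threshold_mm must be non-negative")
  if (!is_count(min_volumes)) stopf("min_volumes must be a count")

  structure(list(
    window_length_s = window_length_s,
    window_width_volumes = width,
    window_step_volumes = as.integer(window_step_volumes),
    tr_s = tr_s,
    density = density,
    k_range = k_range,
    k_fixed = k_fixed,
    distance = distance,
    n_null = as.integer(n_null),
    hub_sd_multiplier = hub_sd_multiplier,
    fd_threshold_mm = fd_threshold_mm,
    min_volumes = as.integer(min_volumes),
    seed = as.integer(seed)
  ), class = "metastate_config")
}

#' Read / write an analysis configuration as YAML
#'
#' All fields of [analysis_config()] can be overridden from a YAML file;
#' unspecified keys keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return `read_config()` returns a `metastate_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config A `metastate_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "metastate_config"))
  out <- config[setdiff(names(config), "window_width_volumes")]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.metastate_config <- function(x, ...) {
  cat("<metastate_config>\n")
  cat(sprintf("  window %g s (%d volumes), step %d, TR %g s\n",
              x$window_length_s, x$window_width_volumes,
              x$window_step_volumes, x$tr_s))
  cat(sprintf("  density %.2f | k %s | distance %s | n_null %d\n",
              x$density,
              if (is.null(x$k_fixed)) paste(x$k_range, collapse = "..")
              else x$k_fixed,
              x$distance, x$n_null))
  cat(sprintf("  hub mean + %g SD | FD > %g mm, min %d volumes | seed %d\n",
              x$hub_sd_multiplier, x$fd_threshold_mm, x$min_volumes, x$seed))
  invisible(x)
}
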