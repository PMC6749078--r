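# End-to-end orchestration: ROI time series -> censoring -> sliding-window
# FC -> windowed eigenvector centrality -> two-stage clustering ->
# dwell/transition dynamics -> (two sessions) state matching and ICC.
# Every stage is also an exported library function; the pipeline only
# chains them and writes TSV/JSON results, so CLI output is a pure function
# of (inputs, config, seed).

#' Run the metastate pipeline on a set of subject-session files
#'
#' @param manifest Data frame with columns `subject`, `session`,
#'   `timeseries` (paths) and optionally `fd` (framewise-displacement
#'   paths). One or two sessions are supported; the test-retest ICC stage
#'   needs two.
#' @param config An [analysis_config()].
#' @param out_dir Output directory for result tables (created if missing).
#' @param icc `NULL` (run the ICC stage when two sessions are present),
#'   `TRUE` (require it; error with a single session) or `FALSE` (skip).
#' @return Invisibly, a list with per-session centrality sequences, fitted
#'   models, per-subject dynamics, the cross-session state matching and the
#'   ICC matrix (when computed).
#' @export
run_pipeline <- function(manifest, config = analysis_config(),
                         out_dir = "metastate_results", icc = NULL) {
  stopifnot(is.data.frame(manifest),
            all(c("subject", "session", "timeseries") %in% names(manifest)))
  sessions <- unique(manifest$session)
  if (isTRUE(icc) && length(sessions) < 2)
    stopf("two sessions required for the ICC stage (got %d)", length(sessions))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = logfile)
  cfg <- config
  log_stage("config", width = cfg$window_width_volumes,
            step = cfg$window_step_volumes, density = cfg$density,
            seed = cfg$seed, logfile = logfile)

  # --- censor + window + centrality, per subject-session ------------------
  labels_ref <- NULL
  cent <- list()
  excluded <- character(0)
  for (r in seq_len(nrow(manifest))) {
    sub <- manifest$subject[r]; sess <- as.character(manifest$session[r])
    ts <- read_timeseries(manifest$timeseries[r], tr_s = cfg$tr_s)
    if (is.null(labels_ref)) labels_ref <- ts$labels
    else if (!identical(ts$labels, labels_ref))
      stopf("region labels of %s/%s do not match the first subject's", sub, sess)
    if (!is.null(manifest$fd) && !is.na(manifest$fd[r]) &&
        nzchar(manifest$fd[r])) {
      cs <- censor_volumes(ts, read_fd(manifest$fd[r]),
                           fd_threshold = cfg$fd_threshold_mm,
                           min_volumes = cfg$min_volumes)
      if (cs$excluded) {
        log_stage("exclude", subject = sub, session = sess,
                  remaining = length(cs$kept), logfile = logfile)
        excluded <- c(excluded, paste0(sub, "/", sess))
        next
      }
      ts <- cs$ts
    }
    wseq <- sliding_window_fc(ts, cfg$window_width_volumes,
                              cfg$window_step_volumes)
    cs <- centrality_sequence(wseq, kind = "eigenvector",
                              density = cfg$density)
    cent[[sess]][[sub]] <- cs$scores
    log_stage("centrality", subject = sub, session = sess,
              windows = nrow(cs$scores), logfile = logfile)
  }
  if (!length(cent)) stopf("all subjects excluded; nothing to cluster")

  # --- clustering, per session independently ------------------------------
  fits <- list()
  for (sess in names(cent)) {
    pooled <- do.call(rbind, cent[[sess]])
    k <- cfg$k_fixed
    validity <- NULL
    if (is.null(k)) {
      sel <- elbow_select_k(pooled, cfg$k_range,
                            seed = sub_seed(cfg$seed, 10L))
      k <- sel$k
      validity <- sel$validity
      utils::write.table(validity,
                         file.path(out_dir, sprintf("validity_%s.tsv", sess)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    fit <- two_stage_fit(cent[[sess]], k, seed = sub_seed(cfg$seed, 20L))
    fit$validity <- validity
    fits[[sess]] <- fit
    log_stage("cluster", session = sess, k = k,
              inertia = round(fit$group$inertia, 4), logfile = logfile)
  }

  # --- align session II states to session I -------------------------------
  matching <- NULL
  if (length(fits) >= 2) {
    a <- names(fits)[1]; b <- names(fits)[2]
    matching <- match_states(fits[[b]]$group$centers, fits[[a]]$group$centers)
    fits[[b]]$subject_labels <- lapply(fits[[b]]$subject_labels,
                                       function(l) matching$permutation[l])
    log_stage("match", total_distance = round(matching$total_distance, 4),
              logfile = logfile)
  }

  # --- dynamics + outputs -------------------------------------------------
  k_used <- fits[[1]]$group$k
  dynamics <- list()
  for (sess in names(fits)) {
    dynamics[[sess]] <- lapply(fits[[sess]]$subject_labels, state_dynamics,
                               tr_s = cfg$tr_s, k = k_used)
    dw <- t(vapply(dynamics[[sess]], function(d) d$dwell$windows,
                   numeric(k_used)))
    colnames(dw) <- paste0("S", seq_len(k_used))
    utils::write.table(cbind(subject = rownames(dw), as.data.frame(dw)),
                       file.path(out_dir, sprintf("dwell_%s.tsv", sess)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix(Reduce(`+`, lapply(dynamics[[sess]], `[[`, "transitions")),
                 file.path(out_dir, sprintf("transitions_%s.tsv", sess)))
    centers <- fits[[sess]]$group$centers
    rownames(centers) <- paste0("S", seq_len(nrow(centers)))
    write_matrix(centers, file.path(out_dir, sprintf("centers_%s.tsv", sess)))
    model <- fits[[sess]]$group
    jsonlite::write_json(
      list(k = model$k, seed = model$seed, distance = model$distance,
           inertia = model$inertia, centers = model$centers,
           labels = fits[[sess]]$subject_labels),
      file.path(out_dir, sprintf("model_%s.json", sess)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sub in names(fits[[sess]]$subject_labels)) {
      lab <- fits[[sess]]$subject_labels[[sub]]
      utils::write.table(data.frame(window = seq_along(lab), state = lab),
                         file.path(out_dir,
                                   sprintf("labels_%s_%s.tsv", sub, sess)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  icc_mat <- NULL
  run_icc <- if (is.null(icc)) length(fits) >= 2 else icc
  if (run_icc) {
    if (length(fits) < 2) stopf("two sessions required for the ICC stage")
    a <- names(fits)[1]; b <- names(fits)[2]
    shared <- intersect(names(dynamics[[a]]), names(dynamics[[b]]))
    if (length(shared) < 3 && !isTRUE(icc)) {
      log_stage("icc", skipped = "fewer than 3 shared subjects",
                logfile = logfile)
      run_icc <- FALSE
    }
  }
  if (run_icc) {
    icc_mat <- icc_matrix(dynamics[[a]][shared], dynamics[[b]][shared],
                          k = k_used)
    write_matrix(icc_mat, file.path(out_dir, "icc_matrix.tsv"))
    log_stage("icc", subjects = length(shared),
              mean_defined = round(mean(icc_mat, na.rm = TRUE), 4),
              logfile = logfile)
  }

  invisible(list(centrality = cent, fits = fits, dynamics = dynamics,
                 matching = matching, icc_matrix = icc_mat,
                 excluded = excluded, config = cfg, out_dir = out_dir))
}
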