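# File I/O for ROI time series and labeled matrices. Everything is
# tab-separated text with region labels, so results stay diffable and
# language-agnostic.

#' Construct an ROI time-series object
#'
#' @param signal Numeric matrix, volumes (rows) by regions (columns), with
#'   region labels as column names.
#' @param tr_s Repetition time in seconds.
#' @param labels Optional region labels; defaults to `colnames(signal)`.
#' @return An object of class `"roi_timeseries"` with fields `signal`,
#'   `tr_s`, `labels` and `n_volumes`.
#' @export
roi_timeseries <- function(signal, tr_s, labels = colnames(signal)) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("signal must be a numeric matrix (volumes x regions)")
  if (is.null(labels)) stopf("region labels are required")
  if (length(labels) != ncol(signal))
    stopf("label count (%d) does not match region count (%d)",
          length(labels), ncol(signal))
  if (ncol(signal) < 2)
    stopf("at least 2 regions are required; a network is undefined with %d",
          ncol(signal))
  if (anyNA(signal)) {
    idx <- which(is.na(signal), arr.ind = TRUE)[1, ]
    stopf("signal contains NA at volume %d, region '%s'",
          idx[1], labels[idx[2]])
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1 || tr_s <= 0)
    stopf("tr_s must be a positive scalar")
  colnames(signal) <- labels
  structure(list(signal = signal, tr_s = tr_s, labels = as.character(labels),
                 n_volumes = nrow(signal)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d volumes x %d regions, TR %g s\n",
              x$n_volumes, length(x$labels), x$tr_s))
  invisible(x)
}

#' Read an ROI-by-time BOLD matrix from delimited text
#'
#' Expects a header row of region labels and one row per acquired volume.
#' Non-numeric or missing cells are rejected with their location.
#'
#' @param path Path to a TSV/CSV file (delimiter auto-detected from the
#'   header line).
#' @param tr_s Repetition time in seconds.
#' @return A [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, tr_s) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stopf("empty file: %s", path)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- trimws(header)
  if (any(header == "") || !anyNA(suppressWarnings(as.numeric(header))) )
    stopf("missing header row of region labels in %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = list(NULL, colnames(df))))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric or missing value at row %d, column '%s' of %s",
          idx[1], colnames(df)[idx[2]], path)
  }
  roi_timeseries(m, tr_s = tr_s, labels = colnames(df))
}

#' Read a single-column framewise-displacement vector
#'
#' @param path Text file with one FD value (mm) per volume; an optional
#'   header line is skipped.
#' @return Numeric vector of per-volume FD in millimeters.
#' @export
read_fd <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty FD file: %s", path)
  if (is.na(suppressWarnings(as.numeric(lines[1])))) lines <- lines[-1]
  fd <- suppressWarnings(as.numeric(lines))
  if (anyNA(fd)) stopf("non-numeric FD value at line %d of %s",
                       which(is.na(fd))[1], path)
  if (any(fd < 0)) stopf("negative FD value in %s", path)
  fd
}

#' Write / read a labeled numeric matrix as TSV
#'
#' Values are printed with 15 significant digits so a write/read round trip
#' is value-identical well past 10 significant digits. Connectivity matrices
#' are square, symmetric, zero-diagonal; `read_matrix(square = TRUE)`
#' enforces that contract.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` a
#'   labeled numeric matrix.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("m must be a numeric matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  out <- cbind(label = rownames(m),
               matrix(formatC(m, digits = 15, format = "g"),
                      nrow = nrow(m), dimnames = list(NULL, colnames(m))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param square Require a square symmetric matrix (connectivity contract).
#' @export
read_matrix <- function(path, square = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("empty file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stopf("no data columns in %s", path)
  rn <- df[[1]]
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df),
           dimnames = list(rn, colnames(df)[-1])))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric value at row '%s', column '%s' of %s",
          rn[idx[1]], colnames(m)[idx[2]], path)
  }
  if (square) {
    if (nrow(m) != ncol(m))
      stopf("expected a square matrix in %s (got %d x %d)",
            path, nrow(m), ncol(m))
    assert_square_symmetric(m, what = sprintf("matrix in %s", path))
  }
  m
}

#' Read a structural connectivity matrix
#'
#' Accepts either a square labeled TSV (as written by [write_matrix()]) or a
#' 3-column edge list `i<TAB>j<TAB>weight` with region names.
#'
#' @param path Input path.
#' @return Square symmetric labeled matrix with zero diagonal.
#' @export
read_structural <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  if (length(first) == 3 &&
      !is.na(suppressWarnings(as.numeric(first[3]))) &&
      is.na(suppressWarnings(as.numeric(first[1])))) {
    el <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("i", "j", "w"),
                            colClasses = c("character", "character", "numeric"))
    labs <- sort(unique(c(el$i, el$j)))
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (r in seq_len(nrow(el))) {
      m[el$i[r], el$j[r]] <- el$w[r]
      m[el$j[r], el$i[r]] <- el$w[r]
    }
    diag(m) <- 0
    return(m)
  }
  m <- read_matrix(path, square = TRUE)
  diag(m) <- 0
  m
}
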