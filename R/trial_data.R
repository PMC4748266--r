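#' Construct a trial matrix of spike counts
#'
#' A trial matrix holds the spike counts of `N` repeated presentations of the
#' same stimulus, binned into `T` time bins: rows are trials, columns are
#' bins. It is the raw input to every reliability and performance metric in
#' this package.
#'
#' @param counts numeric matrix, `N` trials x `T` bins of non-negative
#'   integer spike counts. A data frame or a vector (one trial) is coerced.
#' @param bin_width width of one time bin in seconds (default 0.005, i.e.
#'   5 ms, a common choice for cortical spike trains).
#' @return an object of class `trial_matrix`: the integer count matrix with
#'   a `bin_width` attribute.
#' @examples
#' tm <- trial_matrix(rbind(c(0, 2, 1), c(1, 1, 0)))
#' compute_psth(tm)
#' @export
trial_matrix <- function(counts, bin_width = 0.005) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.vector(counts) && is.numeric(counts)) counts <- matrix(counts, nrow = 1)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (trials x bins)", call. = FALSE)
  }
  if (nrow(counts) < 1) stop("need at least one trial", call. = FALSE)
  if (ncol(counts) < 2) stop("need at least two time bins", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral spike counts", call. = FALSE)
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("'bin_width' must be a single positive number of seconds", call. = FALSE)
  }
  structure(round(counts), bin_width = as.numeric(bin_width),
            dimnames = NULL, class = c("trial_matrix", "matrix"))
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("Trial matrix: %d trials x %d bins (bin width %g s)\n",
              nrow(x), ncol(x), attr(x, "bin_width")))
  cat(sprintf("Total spikes: %d; mean count/bin: %.4g\n", sum(x), mean(x)))
  invisible(x)
}

#' Construct a firing-rate series
#'
#' A rate series is a length-`T` real vector on the same time grid as a
#' trial matrix. It is used both for the trial-averaged response (the PSTH
#' `y`) and for a model prediction `y_hat`. Values are mean spike counts per
#' bin; divide by `bin_width` for spikes/s (the metrics are invariant to
#' this scaling).
#'
#' @param values finite numeric vector, length >= 2.
#' @param bin_width bin width in seconds.
#' @return object of class `rate_series` (numeric vector with `bin_width`).
#' @export
rate_series <- function(values, bin_width = 0.005) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a rate series needs at least two bins", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("rate values must be finite", call. = FALSE)
  }
  structure(values, bin_width = as.numeric(bin_width), class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("Rate series: %d bins (bin width %g s), mean %.4g counts/bin\n",
              length(x), attr(x, "bin_width"), mean(unclass(x))))
  invisible(x)
}

# strip class/attrs for arithmetic
as_numeric_rate <- function(x) as.numeric(unclass(x))

#' Peri-stimulus time histogram (PSTH)
#'
#' Averages the trial matrix over trials: element `t` of the result is the
#' mean spike count in bin `t` across the `N` trials. The PSTH is the target
#' signal `y` that a model prediction is scored against; with finitely many
#' trials it is only a noisy estimate of the true underlying firing rate,
#' which is exactly why the noise-ceiling corrections in this package exist.
#'
#' @param trials a [trial_matrix()].
#' @return a [rate_series()] of length `T` (mean counts per bin).
#' @export
compute_psth <- function(trials) {
  trials <- as_trial_matrix(trials)
  rate_series(colMeans(trials), bin_width = attr(trials, "bin_width"))
}

as_trial_matrix <- function(x) {
  if (inherits(x, "trial_matrix")) return(x)
  trial_matrix(x)
}

#' Bin a spike-time table into a trial matrix
#'
#' Converts a table of (trial id, spike time) records into spike counts per
#' time bin. Bins are half-open `[start, end)` with 0-based starts, so a
#' spike exactly on a bin boundary is counted in the later bin. A trailing
#' partial bin (when `duration` is not a multiple of `bin_width`) is dropped
#' with a warning, since a short bin would distort the variance over bins.
#'
#' @param spikes data frame with columns `trial` (integer in 1..n_trials)
#'   and `time_s` (spike time in seconds, `0 <= time < duration`).
#' @param n_trials number of trials recorded (trials without spikes yield
#'   all-zero rows).
#' @param duration stimulus duration in seconds.
#' @param bin_width bin width in seconds (default 5 ms).
#' @return a [trial_matrix()] of size `n_trials x floor(duration/bin_width)`.
#' @export
bin_spikes <- function(spikes, n_trials, duration, bin_width = 0.005) {
  stopifnot(is.data.frame(spikes))
  if (!all(c("trial", "time_s") %in% names(spikes))) {
    stop("'spikes' needs columns 'trial' and 'time_s'", call. = FALSE)
  }
  n_bins <- floor(duration / bin_width + 1e-9)
  if (n_bins < 2) stop("duration/bin_width must give at least 2 bins", call. = FALSE)
  if (abs(n_bins * bin_width - duration) > 1e-9 * max(1, duration)) {
    warning(sprintf("dropping partial final bin: %g s not a multiple of %g s",
                    duration, bin_width))
  }
  tr <- spikes$trial
  tt <- spikes$time_s
  if (length(tr) > 0) {
    if (any(tt < 0)) stop("negative spike time", call. = FALSE)
    if (any(tr < 1 | tr > n_trials | tr != round(tr))) {
      stop(sprintf("trial id outside 1..%d", n_trials), call. = FALSE)
    }
  }
  counts <- matrix(0L, nrow = n_trials, ncol = n_bins)
  bin <- floor(tt / bin_width + 1e-9)      # 0-based; boundary spike -> later bin
  keep <- bin < n_bins                      # spikes past the last full bin dropped
  if (any(keep)) {
    idx <- cbind(tr[keep], bin[keep] + 1)
    for (i in seq_len(nrow(idx))) {
      counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1L
    }
  }
  trial_matrix(counts, bin_width = bin_width)
}

# ---- file I/O -------------------------------------------------------------

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read and write trial matrices and rate series
#'
#' Plain-text interchange: a trial matrix is a CSV/TSV file with one row per
#' trial and one column per bin; a rate series is a one-row or one-column
#' CSV. A header row is auto-detected (non-numeric first row is skipped).
#' Writing then reading reproduces integer counts exactly.
#'
#' @param path file path. The delimiter (comma or tab) is sniffed from the
#'   first line.
#' @param bin_width bin width in seconds to attach to the result.
#' @return `read_trial_matrix` a [trial_matrix()]; `read_rate_series` a
#'   [rate_series()].
#' @export
read_trial_matrix <- function(path, bin_width = 0.005) {
  tab <- read_numeric_table(path, what = "trial matrix")
  if (any(tab < 0)) {
    bad <- which(tab < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  trial_matrix(tab, bin_width = bin_width)
}

#' @rdname read_trial_matrix
#' @param trials a [trial_matrix()] to write.
#' @param sep field separator, `","` or `"\t"`.
#' @export
write_trial_matrix <- function(trials, path, sep = ",") {
  trials <- as_trial_matrix(trials)
  utils::write.table(unclass(trials), path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_trial_matrix
#' @export
read_rate_series <- function(path, bin_width = 0.005) {
  tab <- read_numeric_table(path, what = "rate series")
  if (nrow(tab) != 1 && ncol(tab) != 1) {
    stop("a rate series file must be a single row or a single column",
         call. = FALSE)
  }
  rate_series(as.numeric(t(tab)), bin_width = bin_width)
}

#' @rdname read_trial_matrix
#' @param rates a [rate_series()] to write (one row).
#' @export
write_rate_series <- function(rates, path, sep = ",") {
  cat(paste(format(as_numeric_rate(rates), trim = TRUE, digits = 15),
            collapse = sep), "\n", sep = "", file = path)
  invisible(path)
}

#' Read a spike-time table (columns trial, time_s)
#' @rdname read_trial_matrix
#' @export
read_spike_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- detect_sep(first)
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("trial", "time_s") %in% names(df))) {
    stop("spike table must have columns 'trial' and 'time_s'", call. = FALSE)
  }
  df
}

read_numeric_table <- function(path, what = "table") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty %s file: %s", what, path), call. = FALSE)
  sep <- detect_sep(lines[[1]])
  cells <- strsplit(lines, sep, fixed = TRUE)
  # header: first row where any cell is non-numeric
  first <- suppressWarnings(as.numeric(trimws(cells[[1]])))
  if (anyNA(first)) {
    cells <- cells[-1]
    if (length(cells) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged rows in %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  parse_row <- function(i) {
    v <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   i, which(is.na(v))[1], path), call. = FALSE)
    }
    v
  }
  do.call(rbind, lapply(seq_along(cells), parse_row))
}
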