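#' Multichannel SSVEP epoch container
#'
#' An `ssvep_epochs` object holds a four-way array of EEG epochs indexed
#' (stimulus class, trial/block, channel, sample) together with the sampling
#' metadata every downstream stage needs: the sampling rate, channel labels
#' (10-20 names), the stimulation frequency of each class, and the time of
#' the first retained sample relative to stimulus onset.
#'
#' @param data numeric 4-way array, dimensions (class, trial, channel, sample).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names, one per
#'   channel.
#' @param stim_freqs strictly increasing stimulation frequencies in Hz, one
#'   per class.
#' @param t0 time in seconds of the first sample relative to stimulus onset.
#' @param log character vector of preprocessing steps already applied
#'   (append-only; serialized with the data).
#' @return an object of class `ssvep_epochs`.
#' @export
ssvep_epochs <- function(data, fs, channel_labels, stim_freqs, t0 = 0,
                         log = character()) {
  x <- structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         stim_freqs = as.numeric(stim_freqs), t0 = t0,
         log = as.character(log)),
    class = "ssvep_epochs")
  validate_epochs(x)
  x
}

validate_epochs <- function(x) {
  if (!is.array(x$data) || length(dim(x$data)) != 4L)
    stop("'data' must be a 4-way array (class, trial, channel, sample)")
  d <- dim(x$data)
  if (any(d < 1L)) stop("all four dimensions must be >= 1")
  if (!all(is.finite(x$data))) stop("'data' contains non-finite values")
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0)
    stop("'fs' must be a single positive number")
  if (length(x$stim_freqs) != d[1L])
    stop(sprintf("length of 'stim_freqs' (%d) must equal the class dimension (%d)",
                 length(x$stim_freqs), d[1L]))
  if (d[1L] > 1L && any(diff(x$stim_freqs) <= 0))
    stop("'stim_freqs' must be strictly increasing")
  if (length(x$channel_labels) != d[3L])
    stop(sprintf("length of 'channel_labels' (%d) must equal the channel dimension (%d)",
                 length(x$channel_labels), d[3L]))
  if (anyDuplicated(x$channel_labels))
    stop("'channel_labels' must be unique")
  invisible(x)
}

n_classes  <- function(x) dim(x$data)[1L]
n_trials   <- function(x) dim(x$data)[2L]
n_channels <- function(x) dim(x$data)[3L]
n_samples  <- function(x) dim(x$data)[4L]

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("SSVEP epochs:", d[1L], "classes x", d[2L], "trials x",
      d[3L], "channels x", d[4L], "samples\n")
  cat(sprintf("  fs = %g Hz, duration = %.3f s, t0 = %.3f s\n",
              x$fs, d[4L] / x$fs, x$t0))
  cat(sprintf("  stimulus frequencies: %g-%g Hz\n",
              min(x$stim_freqs), max(x$stim_freqs)))
  if (length(x$log))
    cat("  preprocessing:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Extract one trial as a channel-by-sample matrix
#' @param epochs an `ssvep_epochs` object.
#' @param class_idx,trial_idx indices of the class and trial.
#' @return numeric matrix (channels x samples).
#' @export
get_trial <- function(epochs, class_idx, trial_idx) {
  m <- epochs$data[class_idx, trial_idx, , , drop = FALSE]
  dim(m) <- dim(epochs$data)[3:4]
  m
}

#' Drop one or more trials (blocks) from every class
#' @param epochs an `ssvep_epochs` object.
#' @param trials trial indices to keep.
#' @return an `ssvep_epochs` object with the trial axis subset.
#' @export
subset_trials <- function(epochs, trials) {
  epochs$data <- epochs$data[, trials, , , drop = FALSE]
  epochs
}

EPOCHS_FORMAT <- "ssvep-epochs"
EPOCHS_VERSION <- 1L

#' Write an epoch container to a single self-describing file
#'
#' The on-disk container is a single uncompressed serialized payload holding
#' the 4-way array plus its attributes (`fs`, `channel_labels`, `stim_freqs`,
#' `t0`, preprocessing log). Writing is atomic (write to a temporary file in
#' the same directory, then rename), and rewriting the same object yields a
#' byte-identical file.
#'
#' @param epochs an `ssvep_epochs` object.
#' @param path destination file path.
#' @return the path, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path) {
  validate_epochs(epochs)
  payload <- list(format = EPOCHS_FORMAT, version = EPOCHS_VERSION,
                  data = epochs$data, fs = epochs$fs,
                  channel_labels = epochs$channel_labels,
                  stim_freqs = epochs$stim_freqs, t0 = epochs$t0,
                  log = epochs$log)
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({
    suppressWarnings(saveRDS(payload, tmp, compress = FALSE))
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write epoch container to '%s': %s",
                 path, conditionMessage(e)))
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop(sprintf("cannot write epoch container to '%s'", path))
  }
  invisible(path)
}

#' Read an epoch container written by [write_epochs()]
#'
#' @param path file path.
#' @return an `ssvep_epochs` object; round-trips bit-exactly with
#'   [write_epochs()].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  payload <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("'%s' is not a readable epoch container: %s",
                 path, conditionMessage(e))))
  if (!is.list(payload) || !identical(payload$format, EPOCHS_FORMAT))
    stop(sprintf("'%s' is not an '%s' container", path, EPOCHS_FORMAT))
  for (f in c("data", "fs", "channel_labels", "stim_freqs", "t0")) {
    if (is.null(payload[[f]]))
      stop(sprintf("epoch container '%s' is missing required field '%s'",
                   path, f))
  }
  ssvep_epochs(payload$data, payload$fs, payload$channel_labels,
               payload$stim_freqs, payload$t0,
               if (is.null(payload$log)) character() else payload$log)
}

#' Adapt a benchmark-style 4-way recording to the package layout
#'
#' Public SSVEP benchmark matrices ship one 4-way array per subject, most
#' commonly in (channel, sample, class, block) order. This adapter permutes
#' the axes to the package's (class, trial, channel, sample) order, attaches
#' the stimulus-frequency table, and reorders classes so frequencies are
#' strictly increasing. The axis order is never guessed: it must be declared
#' by the caller.
#'
#' @param raw numeric 4-way array.
#' @param axis_order character(4): names of `raw`'s axes, a permutation of
#'   `c("channel", "sample", "class", "trial")`.
#' @param fs sampling rate declared by the file (trusted over any nominal
#'   acquisition rate).
#' @param channel_labels channel names matching the channel axis.
#' @param stim_freqs stimulation frequency of each class in the order of the
#'   raw class axis (for the 40-target benchmark speller: an 8.0 + 0.2(k-1) Hz
#'   grid arranged per its stimulus table).
#' @param t0 time of the first sample relative to stimulus onset (seconds).
#' @return an `ssvep_epochs` object, classes sorted by frequency.
#' @export
adapt_benchmark_record <- function(raw, axis_order, fs, channel_labels,
                                   stim_freqs, t0 = 0) {
  want <- c("class", "trial", "channel", "sample")
  if (length(dim(raw)) != 4L) stop("'raw' must be a 4-way array")
  if (length(axis_order) != 4L || !setequal(axis_order, want))
    stop("unknown axis order: 'axis_order' must name each of ",
         paste(sQuote(want), collapse = ", "), " exactly once")
  perm <- match(want, axis_order)
  arr <- aperm(raw, perm)
  ord <- order(stim_freqs)
  arr <- arr[ord, , , , drop = FALSE]
  ssvep_epochs(arr, fs, channel_labels, stim_freqs[ord], t0,
               log = sprintf("adapted from axis order (%s); classes reordered by frequency",
                             paste(axis_order, collapse = ", ")))
}
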