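#' Zero-phase Chebyshev Type I band-pass filtering
#'
#' Filters every channel of every trial independently with a Chebyshev
#' Type I IIR band-pass. With `zero_phase = TRUE` (the default) the filter is
#' applied forward and backward, giving zero group delay at the cost of
#' doubling the effective order. Filtering is intended to run on the full
#' epoch, before window extraction, so start-up transients stay outside the
#' analysis window.
#'
#' @param epochs an `ssvep_epochs` object.
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order filter order per direction (default 4).
#' @param ripple_db passband ripple in dB (default 1).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return the filtered `ssvep_epochs`, with the operation appended to the
#'   preprocessing log.
#' @export
bandpass <- function(epochs, low_hz = 7, high_hz = 90, order = 4,
                     ripple_db = 1, zero_phase = TRUE) {
  fs <- epochs$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop(sprintf("invalid passband [%g, %g] Hz for fs = %g Hz (need 0 < low < high < fs/2)",
                 low_hz, high_hz, fs))
  flt <- signal::cheby1(order, ripple_db, c(low_hz, high_hz) / (fs / 2),
                        type = "pass")
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1L])) for (t in seq_len(d[2L])) for (ch in seq_len(d[3L])) {
    x <- epochs$data[i, t, ch, ]
    out[i, t, ch, ] <- if (zero_phase) signal::filtfilt(flt, x)
                       else as.numeric(signal::filter(flt, x))
  }
  epochs$data <- out
  epochs$log <- c(epochs$log,
                  sprintf("bandpass cheby1 [%g, %g] Hz order %d ripple %g dB%s",
                          low_hz, high_hz, order, ripple_db,
                          if (zero_phase) " zero-phase" else ""))
  epochs
}

# Same filter applied to a single channels x samples matrix (used when
# decomposing a test trial into sub-bands at prediction time).
bandpass_matrix <- function(mat, fs, low_hz, high_hz, order = 4,
                            ripple_db = 1) {
  flt <- signal::cheby1(order, ripple_db, c(low_hz, high_hz) / (fs / 2),
                        type = "pass")
  t(apply(mat, 1L, function(x) signal::filtfilt(flt, x)))
}

#' Latency-aware analysis-window extraction
#'
#' Keeps the samples in the half-open index range
#' `[round(latency_s * fs), round(latency_s * fs) + round(tw_s * fs))`
#' (0-based), i.e. a window of `round(tw_s * fs)` samples starting
#' `latency_s` seconds into the epoch. The default latency of 0.64 s accounts
#' for the visual-system delay between stimulus onset and the steady-state
#' response. `t0` is updated so window positions remain auditable.
#'
#' @param epochs an `ssvep_epochs` object.
#' @param tw_s window length in seconds (the decision time window).
#' @param latency_s offset from the first sample in seconds (default 0.64).
#' @return an `ssvep_epochs` with the sample axis reduced to the window.
#' @export
extract_window <- function(epochs, tw_s, latency_s = 0.64) {
  fs <- epochs$fs
  if (latency_s < 0) stop("'latency_s' must be >= 0")
  if (tw_s <= 0) stop("'tw_s' must be > 0")
  start <- round(latency_s * fs)
  len <- round(tw_s * fs)
  if (len < 2L) stop("window must span at least 2 samples")
  ns <- n_samples(epochs)
  if (start + len > ns)
    stop(sprintf("window [%d, %d) exceeds epoch length: requested %d samples from index %d, %d available",
                 start, start + len, len, start, ns))
  epochs$data <- epochs$data[, , , (start + 1L):(start + len), drop = FALSE]
  epochs$t0 <- epochs$t0 + start / fs
  epochs$log <- c(epochs$log,
                  sprintf("window latency %g s, length %g s (%d samples)",
                          latency_s, tw_s, len))
  epochs
}

#' Select and reorder channels by label
#'
#' @param epochs an `ssvep_epochs` object.
#' @param labels channel labels to keep, in the desired order; duplicates are
#'   rejected.
#' @return an `ssvep_epochs` with the channel axis reduced and reordered.
#' @export
select_channels <- function(epochs, labels) {
  if (anyDuplicated(labels))
    stop("duplicate channel labels requested: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  idx <- match(labels, epochs$channel_labels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  epochs$data <- epochs$data[, , idx, , drop = FALSE]
  epochs$channel_labels <- epochs$channel_labels[idx]
  epochs$log <- c(epochs$log,
                  sprintf("channels selected: %s", paste(labels, collapse = ",")))
  epochs
}

#' The nine occipito-parietal channels conventionally used for SSVEP decoding
#' @return character(9).
#' @export
occipital_channels <- function() {
  c("Pz", "PO5", "PO3", "POz", "PO4", "PO6", "O1", "Oz", "O2")
}
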