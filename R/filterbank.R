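#' Sub-band weight of the filter-bank combination
#'
#' The b-th sub-band's contribution is weighted by `s_b = b^-a + c`
#' (defaults a = 1.25, c = 0.25), compensating for the falling SNR of higher
#' SSVEP harmonics.
#'
#' @param b sub-band index (>= 1).
#' @param a decay exponent (default 1.25).
#' @param c additive offset (default 0.25).
#' @return numeric weight(s); strictly decreasing in `b` for `a > 0`.
#' @export
subband_weight <- function(b, a = 1.25, c = 0.25) {
  if (any(b < 1)) stop("sub-band index must be >= 1")
  b^(-a) + c
}

# Band edges of the M3 sub-band scheme: band b spans [b * low_base, high] Hz.
fb_band_edges <- function(n_bands, low_base_hz = 8, high_hz = 90, fs = Inf) {
  if (n_bands < 1L) stop("'n_bands' must be >= 1")
  hi <- min(high_hz, 0.999 * fs / 2)
  lows <- low_base_hz * seq_len(n_bands)
  bad <- which(lows >= hi)
  if (length(bad))
    stop(sprintf("sub-band %d is infeasible: low edge %g Hz >= high edge %g Hz",
                 bad[1L], lows[bad[1L]], hi))
  cbind(low = lows, high = rep(hi, n_bands))
}

#' M3 filter-bank decomposition of an epoch set
#'
#' Band b is the zero-phase Chebyshev Type I band-pass of the input on
#' `[b * 8, 90]` Hz (the upper edge is capped just below Nyquist when
#' necessary), so band 1 coincides with the standard preprocessing band up to
#' filter-design differences while higher bands isolate the harmonic content.
#'
#' @param epochs an `ssvep_epochs` object.
#' @param n_bands number of sub-bands Nb.
#' @param low_base_hz base low edge (default 8 Hz).
#' @param high_hz common high edge (default 90 Hz).
#' @param order,ripple_db Chebyshev design parameters per direction.
#' @return list of `n_bands` `ssvep_epochs` objects, shapes and metadata
#'   preserved.
#' @export
fb_decompose <- function(epochs, n_bands, low_base_hz = 8, high_hz = 90,
                         order = 4, ripple_db = 1) {
  edges <- fb_band_edges(n_bands, low_base_hz, high_hz, epochs$fs)
  lapply(seq_len(n_bands), function(b)
    bandpass(epochs, edges[b, "low"], edges[b, "high"],
             order = order, ripple_db = ripple_db))
}

# Fuse per-band base-method scores: sum_b s_b * sign(r_b) * r_b^2 per class.
# The signed square keeps the combination monotone in each band's score, so
# a single band with unit weight ranks identically to the base method.
fb_fuse_scores <- function(per_band, weights) {
  if (nrow(per_band) != length(weights))
    stop("number of score rows must match the number of band weights")
  drop(crossprod(weights, sign(per_band) * per_band^2))
}
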