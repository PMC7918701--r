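#' Simulate one subject's SSVEP recording
#'
#' Generates an epoch set with the structure of a frequency-coded speller
#' experiment: for class i the noise-free source is a harmonic series
#' `sum_h decay^(h-1) sin(2 pi h f_i t + h phi_i)` whose phase `phi_i` is
#' drawn once per subject and class and then *frozen across trials* — the
#' time-locking that makes trial-average templates and inter-trial
#' reproducibility (the quantity TRCA maximizes) informative. The source is
#' projected to the channels by one fixed random unit mixing vector per
#' subject.
#'
#' The noise emulates volume-conducted background EEG: `n_channels`
#' independent background sources (pink, i.e. 1/f, temporal spectrum by
#' default) are mixed into the channels through a per-subject random mixing
#' matrix that is fixed across trials, plus a small spatially white sensor
#' floor (`sensor_noise_frac` of the noise power). The spatial correlation
#' this induces is what spatial filters exploit; unstructured sensor noise
#' alone would make spatial filtering pointless. Noise is drawn
#' independently per trial and scaled so that the ratio of signal to noise
#' power *within the analysis band* (`snr_band`, default 7-90 Hz, measured
#' channel-averaged via the periodogram) equals `snr_db` for every trial.
#' Fully reproducible from `seed`.
#'
#' @param n_classes number of stimulus frequencies Nf (default 8).
#' @param freqs_hz stimulation frequencies (default an 8 Hz + 0.2 Hz grid,
#'   the speller convention).
#' @param n_trials number of blocks/trials per class (default 6).
#' @param n_channels number of channels (default 9; labelled with the
#'   occipito-parietal montage when 9).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s analysis duration per epoch in seconds (default 1.5).
#' @param latency_pad_s extra leading signal emulating the pre-window
#'   latency period (default 0.64); total epoch length is
#'   `duration_s + latency_pad_s`.
#' @param n_harmonics harmonics in the source (default 3).
#' @param harmonic_decay amplitude ratio between successive harmonics
#'   (default 0.5).
#' @param snr_db sensor-level in-band SNR in dB; `Inf` means noise-free.
#' @param noise `"pink"` (1/f, the EEG convention, default) or `"white"`
#'   temporal spectrum of the background sources.
#' @param sensor_noise_frac fraction of noise power that is spatially white
#'   sensor noise rather than mixed background activity (default 0.1).
#' @param snr_band band (Hz) over which the SNR is defined (default
#'   `c(7, 90)`, the standard preprocessing band).
#' @param phase_jitter_sd per-trial phase jitter in radians (default 0,
#'   i.e. perfectly time-locked; positive values stress-test the methods).
#' @param seed integer seed governing mixing, phases and noise.
#' @param return_parts attach the noise-free signal and the noise arrays as
#'   attributes `"signal"` and `"noise"` (for SNR audits).
#' @return an `ssvep_epochs` object.
#' @export
simulate_subject <- function(n_classes = 8,
                             freqs_hz = seq(8, by = 0.2,
                                            length.out = n_classes),
                             n_trials = 6, n_channels = 9, fs = 250,
                             duration_s = 1.5, latency_pad_s = 0.64,
                             n_harmonics = 3, harmonic_decay = 0.5,
                             snr_db = 0, noise = c("pink", "white"),
                             sensor_noise_frac = 0.1, snr_band = c(7, 90),
                             phase_jitter_sd = 0, seed = 1,
                             return_parts = FALSE) {
  noise <- match.arg(noise)
  if (length(freqs_hz) != n_classes)
    stop("'freqs_hz' must have length 'n_classes'")
  if (max(freqs_hz) * n_harmonics >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz is at/above Nyquist (fs = %g)",
                 n_harmonics, max(freqs_hz), fs))
  if (is.na(snr_db) || (!is.finite(snr_db) && snr_db < 0))
    stop("'snr_db' must be finite or +Inf")
  ns <- round((duration_s + latency_pad_s) * fs)
  tt <- seq_len(ns) / fs
  set.seed(seed)
  mixing <- stats::rnorm(n_channels)
  mixing <- mixing / sqrt(sum(mixing^2))
  bg_mix <- matrix(stats::rnorm(n_channels * n_channels),
                   n_channels, n_channels)
  phases <- stats::runif(n_classes, 0, 2 * pi)
  sig <- array(0, c(n_classes, n_trials, n_channels, ns))
  nse <- array(0, c(n_classes, n_trials, n_channels, ns))
  for (i in seq_len(n_classes)) {
    src0 <- harmonic_source(freqs_hz[i], phases[i], n_harmonics,
                            harmonic_decay, tt)
    for (t in seq_len(n_trials)) {
      src <- if (phase_jitter_sd > 0)
        harmonic_source(freqs_hz[i],
                        phases[i] + stats::rnorm(1, 0, phase_jitter_sd),
                        n_harmonics, harmonic_decay, tt)
      else src0
      sig[i, t, , ] <- outer(mixing, src)
      if (is.finite(snr_db)) {
        bg <- bg_mix %*% switch(noise,
          pink = pink_noise(n_channels, ns),
          white = matrix(stats::rnorm(n_channels * ns), n_channels, ns))
        sens <- matrix(stats::rnorm(n_channels * ns), n_channels, ns)
        bg <- bg * sqrt((1 - sensor_noise_frac) / mean(bg^2))
        sens <- sens * sqrt(sensor_noise_frac / mean(sens^2))
        e <- bg + sens
        p_sig <- band_power(sig[i, t, , ], fs, snr_band[1], snr_band[2])
        p_e <- band_power(e, fs, snr_band[1], snr_band[2])
        nse[i, t, , ] <- e * sqrt(p_sig / (p_e * 10^(snr_db / 10)))
      }
    }
  }
  out <- ssvep_epochs(sig + nse, fs,
                      channel_labels = if (n_channels == 9) occipital_channels()
                                       else sprintf("Ch%02d", seq_len(n_channels)),
                      stim_freqs = freqs_hz, t0 = 0,
                      log = sprintf("simulated subject (seed %d, snr %g dB, %s noise)",
                                    seed, snr_db, noise))
  if (return_parts) {
    attr(out, "signal") <- sig
    attr(out, "noise") <- nse
  }
  out
}

harmonic_source <- function(f_hz, phase, n_harmonics, decay, tt) {
  src <- 0
  for (h in seq_len(n_harmonics))
    src <- src + decay^(h - 1) * sin(2 * pi * h * f_hz * tt + h * phase)
  src
}

#' Channel-averaged signal power within a frequency band
#'
#' Mean periodogram power of the rows of `x` over the bins falling in
#' `[low_hz, high_hz]`; the in-band power measure used to calibrate the
#' generator's SNR.
#'
#' @param x channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz band edges in Hz.
#' @return a single nonnegative number.
#' @export
band_power <- function(x, fs, low_hz, high_hz) {
  x <- as.matrix(x)
  ns <- ncol(x)
  freqs <- (seq_len(ns) - 1L) * fs / ns
  keep <- freqs >= low_hz & freqs <= high_hz
  p <- 0
  for (r in seq_len(nrow(x))) {
    X <- stats::fft(x[r, ])
    p <- p + sum(Mod(X[keep])^2) / ns^2
  }
  p / nrow(x)
}

# 1/f ("pink") noise rows via spectral shaping of white noise: amplitude
# proportional to f^{-1/2} so the power spectrum falls as 1/f.
pink_noise <- function(n_rows, n_samples) {
  out <- matrix(0, n_rows, n_samples)
  freqs <- seq_len(n_samples %/% 2)
  amp <- 1 / sqrt(freqs)
  for (r in seq_len(n_rows)) {
    spec <- complex(real = stats::rnorm(length(freqs)),
                    imaginary = stats::rnorm(length(freqs))) * amp
    full <- complex(length.out = n_samples)
    full[2:(length(freqs) + 1L)] <- spec
    full[n_samples:(n_samples - length(freqs) + 2L)] <-
      Conj(spec[seq_len(length(freqs) - 1L)])
    x <- Re(stats::fft(full, inverse = TRUE)) / n_samples
    out[r, ] <- x / stats::sd(x)
  }
  out
}

#' Simulate a cohort of independent subjects
#'
#' Each subject gets an independent mixing vector, class phases and noise,
#' with per-subject seeds derived deterministically from `base_seed`.
#'
#' @param n_subjects number of subjects.
#' @param base_seed integer; subject s uses seed `base_seed + 7919 * (s - 1)`.
#' @param ... passed to [simulate_subject()] (everything except `seed`).
#' @return list of `ssvep_epochs` objects.
#' @export
simulate_cohort <- function(n_subjects, base_seed = 0, ...) {
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  lapply(seq_len(n_subjects), function(s)
    simulate_subject(..., seed = base_seed + 7919L * (s - 1L)))
}

#' Randomly permute trials across class labels
#'
#' Destroys the class/trial correspondence by shuffling all Nf x Nt trials
#' uniformly over the (class, trial) grid, for chance-level controls.
#'
#' @param epochs an `ssvep_epochs` object.
#' @param seed integer seed for the permutation.
#' @return an `ssvep_epochs` object with permuted trials.
#' @export
scramble_labels <- function(epochs, seed = 1) {
  nf <- n_classes(epochs); nt <- n_trials(epochs)
  set.seed(seed)
  perm <- sample.int(nf * nt)
  d <- dim(epochs$data)
  flat <- array(epochs$data, c(nf * nt, d[3L], d[4L]))  # class varies fastest
  flat <- flat[perm, , , drop = FALSE]
  epochs$data <- array(flat, d)
  epochs$log <- c(epochs$log, sprintf("labels scrambled (seed %d)", seed))
  epochs
}
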