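METHOD_TAGS <- c("cca", "extcca", "trca", "tstrca", "fbtrca", "fbtstrca")

#' Fit an SSVEP frequency decoder
#'
#' The central fitting function of the package. Given a training epoch set it
#' learns whatever the chosen recognition method needs — individual templates
#' (trial averages per class), TRCA spatial filters, per-sub-band models for
#' the filter-bank variants — and returns a classed object whose
#' [predict.ssvep_decoder()] method identifies the gazed frequency of new
#' trials by the method's decision rule:
#'
#' * `"cca"`: largest canonical correlation against sinusoidal references
#'   (sin/cos harmonics); needs no training data beyond the metadata.
#' * `"extcca"`: four CCA-derived correlations against the sinusoidal
#'   reference and the individual template, fused by signed squares.
#' * `"trca"`: correlation of test and template projected through the
#'   class's own TRCA filter (`ensemble = TRUE` applies all filters jointly).
#' * `"tstrca"`: the two-step method — every class's TRCA filter plus the
#'   unfiltered correlation, fused by signed squares as an ensemble.
#' * `"fbtrca"`, `"fbtstrca"`: the base method fitted per M3 sub-band and
#'   combined with weights `s_b = b^-a + c`.
#'
#' @param train an `ssvep_epochs` object (preprocessed and windowed).
#' @param method one of `"cca"`, `"extcca"`, `"trca"`, `"tstrca"`,
#'   `"fbtrca"`, `"fbtstrca"`.
#' @param n_harmonics harmonics in the sinusoidal references (default 5).
#' @param ridge relative ridge used in all covariance solves (default 1e-8).
#' @param ensemble for `"trca"`/`"fbtrca"`: use all filters jointly.
#' @param n_bands,fb_a,fb_b filter-bank size and weight parameters
#'   `s_b = b^-fb_a + fb_b` (defaults 5, 1.25, 0.25).
#' @param fb_low_base_hz,fb_high_hz M3 sub-band edges `[b * low, high]` Hz.
#' @return an object of class `ssvep_decoder`.
#' @examples
#' epochs <- simulate_subject(n_classes = 4, snr_db = 0, seed = 1)
#' epochs <- extract_window(epochs, tw_s = 1.0, latency_s = 0.64)
#' fit <- ssvep_decoder(subset_trials(epochs, 1:5), method = "tstrca")
#' predict(fit, get_trial(extract_window(
#'   simulate_subject(n_classes = 4, snr_db = 0, seed = 1), 1.0), 2, 6))
#' @export
ssvep_decoder <- function(train, method = c("trca", "tstrca", "cca", "extcca",
                                            "fbtrca", "fbtstrca"),
                          n_harmonics = 5, ridge = 1e-8, ensemble = FALSE,
                          n_bands = 5, fb_a = 1.25, fb_b = 0.25,
                          fb_low_base_hz = 8, fb_high_hz = 90) {
  method <- match.arg(method)
  validate_epochs(train)
  obj <- list(method = method, fs = train$fs, stim_freqs = train$stim_freqs,
              channel_labels = train$channel_labels,
              n_classes = n_classes(train), n_channels = n_channels(train),
              n_samples = n_samples(train), n_train_trials = n_trials(train),
              n_harmonics = n_harmonics, ridge = ridge, ensemble = ensemble)
  if (method %in% c("fbtrca", "fbtstrca")) {
    base <- sub("^fb", "", method)
    edges <- fb_band_edges(n_bands, fb_low_base_hz, fb_high_hz, train$fs)
    bands <- fb_decompose(train, n_bands, fb_low_base_hz, fb_high_hz)
    obj$fb <- list(n_bands = n_bands, a = fb_a, b = fb_b, edges = edges,
                   weights = subband_weight(seq_len(n_bands), fb_a, fb_b),
                   models = lapply(bands, function(bd)
                     fit_decoder_core(bd, base, n_harmonics, ridge)))
  } else {
    obj <- c(obj, fit_decoder_core(train, method, n_harmonics, ridge))
  }
  structure(obj, class = "ssvep_decoder")
}

# Method-specific training: what must be learned from data for one (sub-)band.
fit_decoder_core <- function(train, method, n_harmonics, ridge) {
  switch(method,
    cca = list(),
    extcca = list(templates = build_templates(train)),
    trca = ,
    tstrca = {
      f <- fit_trca(train, ridge = ridge)
      list(filters = f$filters, eigenvalues = f$eigenvalues,
           templates = f$templates)
    },
    stop("unknown method tag '", method, "'; valid tags: ",
         paste(METHOD_TAGS, collapse = ", ")))
}

# Sinusoidal references for all classes at a given sample count.
decoder_references <- function(object, ns) {
  lapply(object$stim_freqs, make_reference, n_harmonics = object$n_harmonics,
         n_samples = ns, fs = object$fs)
}

# Per-class decision scores of a single-band (non-FB) model for one trial.
decoder_scores_core <- function(object, model, method, test) {
  switch(method,
    cca = cca_scores(test, decoder_references(object, ncol(test)),
                     ridge = object$ridge),
    extcca = {
      refs <- decoder_references(object, ncol(test))
      vapply(seq_along(refs), function(i)
        signed_square_fuse(extcca_correlation_vector(
          test, model$templates$templates[[i]], refs[[i]],
          ridge = object$ridge)),
        numeric(1))
    },
    trca = trca_score(test, model$filters, model$templates,
                      ensemble = object$ensemble),
    tstrca = vapply(model$templates$templates, function(Y)
      tstrca_score(tstrca_beta(test, Y, model$filters)), numeric(1)))
}

#' Decision scores of a fitted decoder for one test trial
#'
#' @param object a fitted `ssvep_decoder`.
#' @param test channels x samples matrix.
#' @return numeric vector of per-class scores (the quantity whose argmax is
#'   the predicted class).
#' @export
decoder_scores <- function(object, test) {
  stopifnot(inherits(object, "ssvep_decoder"))
  test <- as.matrix(test)
  if (nrow(test) != object$n_channels)
    stop(sprintf("test trial has %d channels, decoder was fitted on %d",
                 nrow(test), object$n_channels))
  if (object$method %in% c("fbtrca", "fbtstrca")) {
    base <- sub("^fb", "", object$method)
    fb <- object$fb
    per_band <- t(vapply(seq_len(fb$n_bands), function(b) {
      bt <- bandpass_matrix(test, object$fs, fb$edges[b, "low"],
                            fb$edges[b, "high"])
      decoder_scores_core(object, fb$models[[b]], base, bt)
    }, numeric(object$n_classes)))
    fb_fuse_scores(per_band, fb$weights)
  } else {
    decoder_scores_core(object, object, object$method, test)
  }
}

#' Predict gazed stimulus frequencies from new trials
#'
#' @param object a fitted `ssvep_decoder`.
#' @param newdata a channels x samples matrix (one trial), a list of such
#'   matrices, or an `ssvep_epochs` object (every trial is classified).
#' @param type `"class"` for predicted class indices, `"freq"` for the
#'   corresponding stimulation frequencies in Hz, `"scores"` for the raw
#'   per-class decision scores.
#' @param ... unused.
#' @return for a single matrix: an index, a frequency, or a score vector.
#'   For a list: a vector (or matrix of scores, classes in columns). For an
#'   `ssvep_epochs` object: a classes x trials matrix of predictions (row =
#'   true class) or, for `type = "scores"`, a 3-way array.
#' @export
predict.ssvep_decoder <- function(object, newdata,
                                  type = c("class", "freq", "scores"), ...) {
  type <- match.arg(type)
  one <- function(m) {
    s <- decoder_scores(object, m)
    switch(type, scores = s, class = classify_scores(s),
           freq = object$stim_freqs[classify_scores(s)])
  }
  if (is.matrix(newdata)) return(one(newdata))
  if (inherits(newdata, "ssvep_epochs")) {
    nf <- n_classes(newdata); nt <- n_trials(newdata)
    if (type == "scores") {
      out <- array(NA_real_, c(nf, nt, object$n_classes))
      for (i in seq_len(nf)) for (t in seq_len(nt))
        out[i, t, ] <- one(get_trial(newdata, i, t))
    } else {
      out <- matrix(if (type == "freq") NA_real_ else NA_integer_, nf, nt)
      for (i in seq_len(nf)) for (t in seq_len(nt))
        out[i, t] <- one(get_trial(newdata, i, t))
    }
    return(out)
  }
  if (is.list(newdata)) {
    res <- lapply(newdata, one)
    return(if (type == "scores") do.call(rbind, res) else unlist(res))
  }
  stop("'newdata' must be a matrix, a list of matrices, or an 'ssvep_epochs' object")
}

#' @export
print.ssvep_decoder <- function(x, ...) {
  cat("SSVEP frequency decoder (method:", x$method, ")\n")
  cat(sprintf("  %d classes (%g-%g Hz), %d channels, %d training trials, fs = %g Hz\n",
              x$n_classes, min(x$stim_freqs), max(x$stim_freqs),
              x$n_channels, x$n_train_trials, x$fs))
  if (!is.null(x$fb))
    cat(sprintf("  filter bank: %d sub-bands [%g b, %g] Hz, weights b^-%g + %g\n",
                x$fb$n_bands, x$fb$edges[1, "low"], x$fb$edges[1, "high"],
                x$fb$a, x$fb$b))
  invisible(x)
}

#' @export
summary.ssvep_decoder <- function(object, ...) {
  print(object)
  if (!is.null(object$eigenvalues)) {
    cat("  leading TRCA eigenvalues (inter-trial reproducibility):\n")
    print(round(stats::setNames(object$eigenvalues,
                                paste0(object$stim_freqs, "Hz")), 4))
  }
  invisible(object)
}

#' Spatial filters of a fitted decoder
#'
#' @param object a fitted `ssvep_decoder`.
#' @param ... unused.
#' @return a channels x classes matrix of TRCA spatial filters, a list of
#'   such matrices (one per sub-band) for filter-bank decoders, or `NULL`
#'   for methods without learned spatial filters.
#' @export
coef.ssvep_decoder <- function(object, ...) {
  if (!is.null(object$filters)) return(object$filters)
  if (!is.null(object$fb))
    return(lapply(object$fb$models, function(m) m$filters))
  NULL
}
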