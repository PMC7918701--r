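#' Information transfer rate of an Nf-target selection system
#'
#' The standard BCI communication-rate formula: with `n_targets` equiprobable
#' targets, accuracy `P` and a selection time of `T_s` seconds (stimulation
#' window plus gaze-shift time), the rate in bits per minute is
#' `(log2 Nf + P log2 P + (1 - P) log2((1 - P) / (Nf - 1))) * 60 / T_s`,
#' with `x log2 x = 0` at `x = 0`.
#'
#' @param P classification accuracy in \[0, 1\].
#' @param n_targets number of targets (>= 2).
#' @param T_s selection time in seconds, gaze shift included.
#' @return bits per minute. Exactly 0 at chance (`P = 1/n_targets`), strictly
#'   increasing in `P` above chance.
#' @export
itr <- function(P, n_targets, T_s) {
  if (any(P < 0 | P > 1)) stop("'P' must lie in [0, 1]")
  if (n_targets < 2) stop("'n_targets' must be >= 2")
  if (any(T_s <= 0)) stop("'T_s' must be > 0")
  xlog2 <- function(x) ifelse(x == 0, 0, x * log2(x))
  bits <- log2(n_targets) + xlog2(P) +
    ifelse(P == 1, 0, (1 - P) * log2((1 - P) / (n_targets - 1)))
  bits * 60 / T_s
}

#' Macro-averaged precision, recall and F1 from a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Per-class
#' precision and recall with a zero denominator are defined as 0; F1 is the
#' per-class harmonic mean, then all three are macro-averaged (classes are
#' balanced in the block design, so macro and weighted averages coincide).
#'
#' @param confusion square matrix of nonnegative counts.
#' @return list with `precision`, `recall`, `f1` (macro averages) and the
#'   per-class vectors `by_class`.
#' @export
prf_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("'confusion' must be a square matrix of nonnegative counts")
  if (sum(confusion) == 0) stop("confusion matrix is all zero")
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       by_class = list(precision = prec, recall = rec, f1 = f1))
}

#' Leave-one-block-out cross-validated evaluation of one method
#'
#' Each of the Nt recording blocks serves once as test data: the decoder is
#' fitted on the remaining Nt - 1 blocks and classifies all Nf trials of the
#' held-out block. Accuracy is averaged over folds (equivalently, over all
#' Nf x Nt decisions, since folds are balanced); the information transfer
#' rate is computed per fold with `T = tw + gaze_shift` and then averaged,
#' matching per-block averaging conventions (which is why mean accuracy and
#' mean ITR need not jointly satisfy the ITR formula).
#'
#' @param epochs an `ssvep_epochs` object (full preprocessed epochs).
#' @param method a method tag accepted by [ssvep_decoder()].
#' @param tw_s analysis window length in seconds; if `NULL` the epochs are
#'   used as-is and the full duration counts as the window.
#' @param latency_s window offset passed to [extract_window()] when `tw_s`
#'   is given (default 0.64).
#' @param gaze_shift_s gaze-shift time added to the selection time for the
#'   ITR (default 0.5 s).
#' @param ... further arguments to [ssvep_decoder()].
#' @return an object of class `ssvep_eval`: list with `confusion`
#'   (Nf x Nf counts, rows = true class), `accuracy`, `per_fold_accuracy`,
#'   `itr_bits_per_min`, `per_fold_itr`, `precision`, `recall`, `f1`,
#'   `method`, `tw_s`, `T_s`.
#' @export
loocv <- function(epochs, method, tw_s = NULL, latency_s = 0.64,
                  gaze_shift_s = 0.5, ...) {
  validate_epochs(epochs)
  nt <- n_trials(epochs)
  if (nt < 2L) stop("leave-one-block-out needs at least 2 blocks")
  if (!is.null(tw_s)) epochs <- extract_window(epochs, tw_s, latency_s)
  nf <- n_classes(epochs)
  tw_eff <- if (is.null(tw_s)) n_samples(epochs) / epochs$fs else tw_s
  T_s <- tw_eff + gaze_shift_s
  confusion <- matrix(0L, nf, nf)
  fold_acc <- numeric(nt)
  for (t in seq_len(nt)) {
    fit <- ssvep_decoder(subset_trials(epochs, setdiff(seq_len(nt), t)),
                         method = method, ...)
    pred <- vapply(seq_len(nf), function(i)
      predict(fit, get_trial(epochs, i, t)), integer(1))
    for (i in seq_len(nf)) confusion[i, pred[i]] <- confusion[i, pred[i]] + 1L
    fold_acc[t] <- mean(pred == seq_len(nf))
  }
  fold_itr <- itr(fold_acc, max(nf, 2L), T_s)
  prf <- prf_metrics(confusion)
  structure(list(confusion = confusion, accuracy = mean(fold_acc),
                 per_fold_accuracy = fold_acc,
                 itr_bits_per_min = mean(fold_itr), per_fold_itr = fold_itr,
                 precision = prf$precision, recall = prf$recall, f1 = prf$f1,
                 method = method, tw_s = tw_eff, T_s = T_s),
            class = "ssvep_eval")
}

#' @export
print.ssvep_eval <- function(x, ...) {
  cat(sprintf("LOOCV (%s, tw = %g s): accuracy %.3f, ITR %.2f bits/min\n",
              x$method, x$tw_s, x$accuracy, x$itr_bits_per_min))
  cat(sprintf("  macro precision %.3f, recall %.3f, F1 %.3f over %d decisions\n",
              x$precision, x$recall, x$f1, sum(x$confusion)))
  invisible(x)
}

#' Sweep methods and time windows over one or more subjects
#'
#' Runs [loocv()] for every (subject, method, time window) combination and
#' collects the results in a long-format table ready for delimited-text
#' export or external statistics.
#'
#' @param epochs_list an `ssvep_epochs` object or a list of them (one per
#'   subject).
#' @param methods character vector of method tags.
#' @param tw_grid_s numeric vector of window lengths in seconds (default
#'   0.2 to 1.0 in steps of 0.1).
#' @param latency_s,gaze_shift_s see [loocv()].
#' @param ... further arguments to [ssvep_decoder()].
#' @return a data.frame with columns subject, method, tw, n_channels,
#'   accuracy, itr, precision, recall, f1.
#' @export
sweep_methods <- function(epochs_list, methods,
                          tw_grid_s = seq(0.2, 1.0, by = 0.1),
                          latency_s = 0.64, gaze_shift_s = 0.5, ...) {
  if (inherits(epochs_list, "ssvep_epochs")) epochs_list <- list(epochs_list)
  rows <- list()
  for (s in seq_along(epochs_list)) for (m in methods) for (tw in tw_grid_s) {
    ev <- loocv(epochs_list[[s]], m, tw_s = tw, latency_s = latency_s,
                gaze_shift_s = gaze_shift_s, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, method = m, tw = tw,
      n_channels = n_channels(epochs_list[[s]]),
      accuracy = ev$accuracy, itr = ev$itr_bits_per_min,
      precision = ev$precision, recall = ev$recall, f1 = ev$f1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run a full evaluation and write its artifacts to disk
#'
#' Convenience wrapper tying the pipeline together: sweeps the requested
#' methods and windows, writes the long-format results table
#' (`results.csv`), a JSON summary with mean and median accuracy/ITR per
#' (method, tw) condition (`summary.json`), and the configuration used
#' (`config.json`). Outputs contain no timestamps, so identical inputs and
#' configuration produce byte-identical files.
#'
#' @param epochs_list an `ssvep_epochs` object, a list of them, or a path /
#'   vector of paths readable by [read_epochs()].
#' @param out_dir output directory (created if missing).
#' @param methods,tw_grid_s,latency_s,gaze_shift_s see [sweep_methods()].
#' @param ... further arguments to [ssvep_decoder()].
#' @return invisibly, a list with the results data.frame and the file paths.
#' @export
run_evaluate <- function(epochs_list, out_dir, methods = c("trca", "tstrca"),
                         tw_grid_s = seq(0.2, 1.0, by = 0.1),
                         latency_s = 0.64, gaze_shift_s = 0.5, ...) {
  if (is.character(epochs_list)) epochs_list <- lapply(epochs_list, read_epochs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- sweep_methods(epochs_list, methods, tw_grid_s, latency_s,
                       gaze_shift_s, ...)
  res_path <- file.path(out_dir, "results.csv")
  utils::write.csv(res, res_path, row.names = FALSE)
  agg <- lapply(split(res, list(res$method, res$tw), drop = TRUE),
                function(g) list(method = g$method[1L], tw = g$tw[1L],
                                 mean_accuracy = mean(g$accuracy),
                                 median_accuracy = stats::median(g$accuracy),
                                 mean_itr = mean(g$itr),
                                 median_itr = stats::median(g$itr)))
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(unname(agg), sum_path, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(methods = methods, tw_grid_s = tw_grid_s,
                            latency_s = latency_s,
                            gaze_shift_s = gaze_shift_s),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, results_path = res_path,
                 summary_path = sum_path, config_path = cfg_path))
}
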