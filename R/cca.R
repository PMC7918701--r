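# Pearson correlation with a guard for degenerate (zero-variance) inputs:
# such entries are defined as 0, with a warning, so ensemble scores stay
# finite on pathological trials.
safe_cor <- function(x, y, warn = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (warn) warning("zero-variance projection; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}

# Pearson correlation of two equally-shaped matrices, defined as the
# correlation of their vectorized entries after mean removal. This single
# definition backs both the template/test correlation without a spatial
# filter and the projected-pair correlations of the extended-CCA scheme.
matrix_cor <- function(A, B, warn = TRUE) {
  safe_cor(as.vector(A), as.vector(B), warn = warn)
}

#' Sinusoidal reference matrix for one stimulation frequency
#'
#' Builds the classical 2*Nh-row reference used by CCA-based SSVEP decoding:
#' for harmonic h the rows are `sin(2 pi h f t)` and `cos(2 pi h f t)` with
#' `t = n / fs`, `n = 1..n_samples`.
#'
#' @param f_hz stimulation frequency in Hz.
#' @param n_harmonics number of harmonics Nh; the highest harmonic must lie
#'   below the Nyquist frequency.
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @return a `2 * n_harmonics` x `n_samples` matrix with attributes `f_hz`,
#'   `n_harmonics`, `fs`.
#' @export
make_reference <- function(f_hz, n_harmonics, n_samples, fs) {
  if (f_hz * n_harmonics >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz is at/above Nyquist (fs = %g Hz)",
                 n_harmonics, f_hz, fs))
  t <- seq_len(n_samples) / fs
  Z <- matrix(0, nrow = 2L * n_harmonics, ncol = n_samples)
  for (h in seq_len(n_harmonics)) {
    Z[2L * h - 1L, ] <- sin(2 * pi * h * f_hz * t)
    Z[2L * h, ]      <- cos(2 * pi * h * f_hz * t)
  }
  structure(Z, f_hz = f_hz, n_harmonics = n_harmonics, fs = fs)
}

# Inverse symmetric square root via eigendecomposition; eigenvalues below
# tol are an error unless the caller added a ridge first.
inv_sqrt_sym <- function(C, tol = 1e-12) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values, tol)))
    stop("covariance matrix is singular; enable a positive ridge")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Largest canonical correlation between two multichannel signals
#'
#' Finds the weight pair `(wx, wy)` maximizing the Pearson correlation of the
#' projections `wx' X` and `wy' Y`, solved by singular-value decomposition of
#' the whitened cross-covariance (equivalent to the classical generalized
#' eigenproblem). Rows are centered internally; a small ridge proportional to
#' `trace/dim` is added to each auto-covariance for rank safety. Weight signs
#' are canonicalized (largest-magnitude entry of `wx` positive, `wy` oriented
#' so the projection correlation is nonnegative).
#'
#' @param X numeric matrix, D1 x T.
#' @param Y numeric matrix, D2 x T (same T).
#' @param ridge relative ridge added to the auto-covariances (default 1e-8);
#'   set to 0 to disable, in which case a rank-deficient input is an error.
#' @return a list with `rho` (in \[0, 1\]), `wx`, `wy`. The projections have
#'   unit variance under the 1/T covariance normalizer.
#' @export
canonical_correlation <- function(X, Y, ridge = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of samples")
  T <- ncol(X)
  if (T <= max(nrow(X), nrow(Y)))
    stop(sprintf("need more samples (%d) than variables (%d) for CCA",
                 T, max(nrow(X), nrow(Y))))
  X <- X - rowMeans(X); Y <- Y - rowMeans(Y)
  Cxx <- tcrossprod(X) / T
  Cyy <- tcrossprod(Y) / T
  Cxy <- tcrossprod(X, Y) / T
  if (ridge > 0) {
    Cxx <- Cxx + diag(ridge * sum(diag(Cxx)) / nrow(Cxx), nrow(Cxx))
    Cyy <- Cyy + diag(ridge * sum(diag(Cyy)) / nrow(Cyy), nrow(Cyy))
  }
  Wx <- inv_sqrt_sym(Cxx)
  Wy <- inv_sqrt_sym(Cyy)
  s <- svd(Wx %*% Cxy %*% Wy)
  rho <- min(max(s$d[1L], 0), 1)
  wx <- drop(Wx %*% s$u[, 1L])
  wy <- drop(Wy %*% s$v[, 1L])
  if (wx[which.max(abs(wx))] < 0) { wx <- -wx; wy <- -wy }
  if (safe_cor(crossprod(wx, X), crossprod(wy, Y), warn = FALSE) < 0) wy <- -wy
  list(rho = rho, wx = wx, wy = wy)
}

#' Per-class individual templates (trial averages)
#'
#' The individual template of class i is the element-wise mean over that
#' class's training trials, a subject-specific reference that replaces (or
#' complements) the sinusoidal references.
#'
#' @param train an `ssvep_epochs` object of training data.
#' @return an object of class `ssvep_templates`: a list with `templates`
#'   (list of channels x samples matrices), `stim_freqs`, `n_train_trials`.
#' @export
build_templates <- function(train) {
  nf <- n_classes(train); nt <- n_trials(train)
  if (nt < 1L) stop("at least one training trial per class is required")
  templates <- vector("list", nf)
  for (i in seq_len(nf)) {
    m <- train$data[i, , , , drop = FALSE]
    dim(m) <- dim(train$data)[2:4]
    templates[[i]] <- apply(m, c(2L, 3L), mean)
  }
  structure(list(templates = templates, stim_freqs = train$stim_freqs,
                 n_train_trials = nt),
            class = "ssvep_templates")
}

#' Standard CCA decision scores for one test trial
#'
#' `scores[i]` is the largest canonical correlation between the test trial and
#' the i-th reference (a sinusoidal reference matrix or an individual
#' template).
#'
#' @param test channels x samples matrix (a single trial).
#' @param refs a list of reference matrices, or an `ssvep_templates` object.
#' @param ridge passed to [canonical_correlation()].
#' @return numeric vector of length `length(refs)`.
#' @export
cca_scores <- function(test, refs, ridge = 1e-8) {
  if (inherits(refs, "ssvep_templates")) refs <- refs$templates
  vapply(refs, function(R) {
    if (ncol(R) != ncol(test))
      stop(sprintf("reference has %d samples but test has %d",
                   ncol(R), ncol(test)))
    canonical_correlation(test, R, ridge = ridge)$rho
  }, numeric(1))
}

#' Extended-CCA correlation vector for one candidate class
#'
#' Computes the four correlations the extended CCA fuses for class i: with
#' `w_{A,B}` the A-side CCA weight of the pair (A, B), test trial `X`,
#' individual template `Y` and sinusoidal reference `Z`:
#' * r1 = the canonical correlation of (X, Z);
#' * r2 = cor(w_{XY}' X, w_{XY}' Y);
#' * r3 = cor(w_{XZ}' X, w_{XZ}' Y);
#' * r4 = cor(w_{YZ}' X, w_{YZ}' Y).
#' Degenerate (zero-variance) projections yield 0 with a warning.
#'
#' @param test channels x samples matrix.
#' @param template individual template of the candidate class (same shape).
#' @param reference sinusoidal reference matrix of the candidate class.
#' @param ridge passed to [canonical_correlation()].
#' @return numeric vector `c(r1, r2, r3, r4)`.
#' @export
extcca_correlation_vector <- function(test, template, reference,
                                      ridge = 1e-8) {
  if (ncol(template) != ncol(test) || ncol(reference) != ncol(test))
    stop("test, template and reference must share the sample count")
  cXZ <- canonical_correlation(test, reference, ridge = ridge)
  cXY <- canonical_correlation(test, template, ridge = ridge)
  cYZ <- canonical_correlation(template, reference, ridge = ridge)
  r1 <- cXZ$rho
  r2 <- safe_cor(crossprod(cXY$wx, test), crossprod(cXY$wx, template))
  r3 <- safe_cor(crossprod(cXZ$wx, test), crossprod(cXZ$wx, template))
  r4 <- safe_cor(crossprod(cYZ$wx, test), crossprod(cYZ$wx, template))
  c(r1, r2, r3, r4)
}

#' Signed-square fusion of a correlation vector
#'
#' The shared fusion kernel of the extended CCA, the two-step TRCA ensemble
#' score and the filter-bank combination: `sum(sign(v) * v^2)`. Squaring
#' emphasizes large correlations; the sign keeps anti-correlated entries
#' discriminative instead of aliasing them onto positive evidence.
#'
#' @param values numeric vector of finite correlations.
#' @return a single number.
#' @export
signed_square_fuse <- function(values) {
  if (!all(is.finite(values))) stop("non-finite values in correlation vector")
  sum(sign(values) * values^2)
}

#' Argmax target identification
#'
#' Returns the index of the maximal decision score. Ties are broken in favour
#' of the lowest index and reported via a message.
#'
#' @param scores numeric vector of finite per-class scores.
#' @return integer class index.
#' @export
classify_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  if (!all(is.finite(scores))) stop("non-finite decision score")
  top <- which(scores == max(scores))
  if (length(top) > 1L)
    message("tie among classes ", paste(top, collapse = ", "),
            "; lowest index chosen")
  top[1L]
}
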