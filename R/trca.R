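#' Inter-trial (S) and concatenated (Q) covariance matrices for TRCA
#'
#' Task-related component analysis rests on two channel-by-channel matrices
#' built from the trials of one stimulus class: `S`, the sum over all ordered
#' pairs of distinct trials of the cross-trial channel covariance, and `Q`,
#' the channel covariance of the horizontally concatenated trials. Each trial
#' is mean-centered per channel before entering either matrix, and
#' covariances divide by the number of samples (the normalizer only rescales
#' the generalized eigenproblem, so rankings are unaffected; fixing it keeps
#' results bit-reproducible).
#'
#' @param trials list of channels x samples matrices (>= 2 trials, equal
#'   shapes).
#' @return list with symmetric matrices `S` and `Q` (Q positive
#'   semi-definite).
#' @export
trca_matrices <- function(trials) {
  nt <- length(trials)
  if (nt < 2L)
    stop("TRCA needs at least 2 trials: inter-trial covariance is undefined for ",
         nt)
  d <- dim(trials[[1L]])
  for (t in seq_len(nt)) {
    if (!identical(dim(trials[[t]]), d))
      stop("all trials must have identical dimensions")
  }
  nc <- d[1L]; ns <- d[2L]
  ctr <- lapply(trials, function(x) x - rowMeans(x))
  S <- matrix(0, nc, nc)
  for (t1 in seq_len(nt - 1L)) for (t2 in (t1 + 1L):nt) {
    C <- tcrossprod(ctr[[t1]], ctr[[t2]]) / ns
    S <- S + (C + t(C))  # parenthesized so S stays exactly symmetric
  }
  Xhat <- do.call(cbind, ctr)
  Q <- tcrossprod(Xhat) / ncol(Xhat)
  list(S = S, Q = Q)
}

#' TRCA spatial filter for one stimulus class
#'
#' Maximizes the Rayleigh quotient `w' S w / w' Q w` — the inter-trial
#' reproducibility of the projected signal relative to its total variance.
#' The solution is the leading eigenvector of `Q^-1 S`, computed on the
#' Cholesky-symmetrized problem for numerical stability after adding a small
#' ridge (`ridge * trace(Q) / Nc`) to `Q`. The returned filter has unit
#' Euclidean norm and canonical sign (largest-magnitude entry positive).
#'
#' @param trials list of channels x samples matrices (>= 2).
#' @param ridge relative ridge on Q (default 1e-8); short analysis windows
#'   make Q ill-conditioned.
#' @return list with `w` (unit-norm weight vector over channels) and
#'   `lambda` (the leading generalized eigenvalue, equal to the Rayleigh
#'   quotient at `w`).
#' @export
trca_filter <- function(trials, ridge = 1e-8) {
  m <- trca_matrices(trials)
  nc <- nrow(m$Q)
  Qr <- m$Q + diag(ridge * sum(diag(m$Q)) / nc, nc)
  R <- tryCatch(chol(Qr), error = function(e)
    stop("Q is singular beyond ridge repair: ", conditionMessage(e)))
  Rinv <- backsolve(R, diag(nc))
  M <- crossprod(Rinv, m$S %*% Rinv)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  w <- drop(Rinv %*% e$vectors[, 1L])
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  list(w = w, lambda = e$values[1L])
}

#' Fit TRCA spatial filters and individual templates for every class
#'
#' The training stage shared by standard TRCA and the two-step method: one
#' spatial filter (via [trca_filter()]) and one trial-average template per
#' stimulus frequency. Deterministic given the input.
#'
#' @param train an `ssvep_epochs` object with >= 2 trials per class.
#' @param ridge passed to [trca_filter()].
#' @return list with `filters` (channels x classes matrix, one unit-norm
#'   filter per column), `eigenvalues` (leading generalized eigenvalues), and
#'   `templates` (an `ssvep_templates` object).
#' @export
fit_trca <- function(train, ridge = 1e-8) {
  nf <- n_classes(train); nt <- n_trials(train); nc <- n_channels(train)
  if (nt < 2L)
    stop("TRCA training needs at least 2 trials per class, got ", nt)
  W <- matrix(0, nc, nf)
  lambda <- numeric(nf)
  for (i in seq_len(nf)) {
    trials <- lapply(seq_len(nt), function(t) get_trial(train, i, t))
    f <- trca_filter(trials, ridge = ridge)
    W[, i] <- f$w
    lambda[i] <- f$lambda
  }
  rownames(W) <- train$channel_labels
  list(filters = W, eigenvalues = lambda, templates = build_templates(train))
}

#' Standard TRCA decision scores for one test trial
#'
#' `scores[i]` is the Pearson correlation between the test trial and the
#' class-i template, both projected through the class-i filter only (the
#' non-ensemble baseline). With `ensemble = TRUE` all filters are applied
#' jointly and the correlation is taken over the stacked projections.
#'
#' @param test channels x samples matrix.
#' @param filters channels x classes matrix of spatial filters.
#' @param templates an `ssvep_templates` object (or list of matrices).
#' @param ensemble use all filters jointly for every class (default FALSE).
#' @return numeric vector of per-class scores.
#' @export
trca_score <- function(test, filters, templates, ensemble = FALSE) {
  tmpl <- if (inherits(templates, "ssvep_templates")) templates$templates
          else templates
  nf <- length(tmpl)
  vapply(seq_len(nf), function(i) {
    if (ensemble) {
      matrix_cor(crossprod(filters, test), crossprod(filters, tmpl[[i]]))
    } else {
      safe_cor(crossprod(filters[, i], test), crossprod(filters[, i], tmpl[[i]]))
    }
  }, numeric(1))
}

#' Two-step TRCA correlation vector for one candidate class
#'
#' The second step of the two-step method scores candidate class i by
#' correlating its template with the test trial through *every* class's
#' spatial filter, plus once without any filter: `beta[1]` is the Pearson
#' correlation of the vectorized template and test trial (no filter), and
#' `beta[k + 1]` is `cor(w_k' template, w_k' test)` for k = 1..Nf. Degenerate
#' projections yield 0 with a warning.
#'
#' @param test channels x samples matrix.
#' @param template the candidate class's individual template (same shape).
#' @param filters channels x classes matrix of TRCA filters.
#' @return numeric vector of length `ncol(filters) + 1`, entries in
#'   \[-1, 1\].
#' @export
tstrca_beta <- function(test, template, filters) {
  if (!identical(dim(template), dim(test)))
    stop("test and template must have identical dimensions")
  nf <- ncol(filters)
  beta <- numeric(nf + 1L)
  beta[1L] <- matrix_cor(template, test)
  pt_tmpl <- crossprod(filters, template)  # Nf x Ns projections
  pt_test <- crossprod(filters, test)
  for (k in seq_len(nf))
    beta[k + 1L] <- safe_cor(pt_tmpl[k, ], pt_test[k, ])
  beta
}

#' Two-step TRCA ensemble score
#'
#' Fuses a candidate class's correlation vector by the signed-square sum
#' `sum(sign(beta) * beta^2)` (shared kernel [signed_square_fuse()]).
#'
#' @param beta correlation vector from [tstrca_beta()].
#' @return a single score.
#' @export
tstrca_score <- function(beta) signed_square_fuse(beta)

#' Two-step TRCA target identification for one test trial
#'
#' Scores every candidate class by [tstrca_beta()] + [tstrca_score()] and
#' returns the argmax (ties to the lowest index, as [classify_scores()]).
#'
#' @param test channels x samples matrix.
#' @param filters channels x classes matrix of TRCA filters.
#' @param templates an `ssvep_templates` object (or list of matrices).
#' @return integer class index.
#' @export
tstrca_classify <- function(test, filters, templates) {
  tmpl <- if (inherits(templates, "ssvep_templates")) templates$templates
          else templates
  scores <- vapply(tmpl, function(Y)
    tstrca_score(tstrca_beta(test, Y, filters)), numeric(1))
  classify_scores(scores)
}
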