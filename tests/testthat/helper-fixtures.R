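# Small in-code fixtures shared across the suite.

# Random epoch set for container/plumbing tests (values have no structure).
make_random_epochs <- function(nf = 2, nt = 2, nc = 3, ns = 100, fs = 250,
                               seed = 1) {
  set.seed(seed)
  ssvep_epochs(array(rnorm(nf * nt * nc * ns), c(nf, nt, nc, ns)),
               fs = fs,
               channel_labels = sprintf("C%02d", seq_len(nc)),
               stim_freqs = seq(8, by = 0.2, length.out = nf))
}

# List of random trial matrices for TRCA-level tests.
make_random_trials <- function(nt = 3, nc = 3, ns = 50, seed = 1) {
  set.seed(seed)
  lapply(seq_len(nt), function(t) matrix(rnorm(nc * ns), nc, ns))
}

# Independent naive oracle for the TRCA matrices: explicit loops over trial
# pairs and channel pairs, mean-removed covariance with a 1/ns normalizer.
naive_trca_matrices <- function(trials) {
  nt <- length(trials)
  nc <- nrow(trials[[1]]); ns <- ncol(trials[[1]])
  cov1 <- function(x, y) mean((x - mean(x)) * (y - mean(y)))
  S <- matrix(0, nc, nc)
  for (t1 in seq_len(nt)) for (t2 in seq_len(nt)) {
    if (t1 == t2) next
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc))
      S[c1, c2] <- S[c1, c2] + cov1(trials[[t1]][c1, ], trials[[t2]][c2, ])
  }
  ctr <- lapply(trials, function(x) x - rowMeans(x))
  Xhat <- do.call(cbind, ctr)
  Q <- matrix(0, nc, nc)
  for (c1 in seq_len(nc)) for (c2 in seq_len(nc))
    Q[c1, c2] <- mean(Xhat[c1, ] * Xhat[c2, ])
  list(S = S, Q = Q)
}

# Brute-force maximization of the projection correlation for 2x2 CCA over a
# fine grid of unit weight pairs (angle parameterization).
grid_search_cca <- function(X, Y, n_grid = 720) {
  th <- seq(0, pi, length.out = n_grid)
  best <- 0
  for (a in th) {
    px <- cos(a) * X[1, ] + sin(a) * X[2, ]
    for (b in th) {
      py <- cos(b) * Y[1, ] + sin(b) * Y[2, ]
      r <- abs(stats::cor(px, py))
      if (is.finite(r) && r > best) best <- r
    }
  }
  best
}
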