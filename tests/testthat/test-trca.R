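test_that("TRCA matrices match the naive quadruple-loop oracle", {
  for (nt in 2:4) for (nc in 2:4) for (ns in c(20, 60)) {
    trials <- make_random_trials(nt, nc, ns, seed = 1000 + 100 * nt + 10 * nc + ns)
    got <- trca_matrices(trials)
    want <- naive_trca_matrices(trials)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Q, want$Q, tolerance = 1e-10)
    expect_identical(got$S, t(got$S))
    expect_true(all(eigen(got$Q, symmetric = TRUE, only.values = TRUE)$values
                    > -1e-10))
  }
})

test_that("identical trials give S = Nt (Nt - 1) C", {
  x <- matrix(rnorm(3 * 50), 3)
  nt <- 4
  m <- trca_matrices(rep(list(x), nt))
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / ncol(x)
  expect_equal(m$S, nt * (nt - 1) * C, tolerance = 1e-10)
})

test_that("independent white-noise trials give near-zero S", {
  set.seed(11)
  trials <- list(matrix(rnorm(3 * 10000), 3), matrix(rnorm(3 * 10000), 3))
  expect_lt(max(abs(trca_matrices(trials)$S)), 0.05)
})

test_that("fewer than two trials is rejected", {
  expect_error(trca_matrices(make_random_trials(1)), "at least 2 trials")
  expect_error(trca_matrices(list(matrix(0, 2, 10), matrix(0, 3, 10))),
               "identical dimensions")
})

test_that("the TRCA filter concentrates on the reproducible channel", {
  set.seed(21)
  s <- sin(2 * pi * 10 * (1:500) / 250)
  sigma <- sqrt(mean(s^2))
  trials <- lapply(1:6, function(t)
    rbind(s + rnorm(500, sd = 0.1 * sigma), rnorm(500, sd = sigma)))
  f <- trca_filter(trials)
  expect_gt(abs(f$w[1]) / sqrt(sum(f$w^2)), 0.95)
})

test_that("the returned filter maximizes the Rayleigh quotient", {
  trials <- make_random_trials(4, 3, 80, seed = 31)
  m <- trca_matrices(trials)
  f <- trca_filter(trials)
  rq <- function(w) drop(crossprod(w, m$S %*% w) / crossprod(w, m$Q %*% w))
  expect_equal(rq(f$w), f$lambda, tolerance = 1e-8)
  set.seed(32)
  for (k in 1:1000) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_gte(f$lambda + 1e-8, rq(v))
  }
  expect_equal(sqrt(sum(f$w^2)), 1, tolerance = 1e-12)
})

test_that("the TRCA filter is equivariant under orthonormal channel mixing", {
  trials <- make_random_trials(3, 4, 60, seed = 41)
  set.seed(42)
  R <- qr.Q(qr(matrix(rnorm(16), 4)))
  f0 <- trca_filter(trials)
  f1 <- trca_filter(lapply(trials, function(x) R %*% x))
  expect_equal(abs(drop(crossprod(f1$w, R %*% f0$w))), 1, tolerance = 1e-6)
  expect_equal(f1$lambda, f0$lambda, tolerance = 1e-8)
})

test_that("fitting returns one filter and template per class, deterministically", {
  ep <- simulate_subject(n_classes = 3, n_trials = 4, snr_db = 0, seed = 51)
  fit1 <- fit_trca(ep)
  expect_identical(dim(fit1$filters), c(9L, 3L))
  expect_length(fit1$eigenvalues, 3L)
  expect_length(fit1$templates$templates, 3L)
  expect_identical(dim(fit1$templates$templates[[1]]), c(9L, 535L))
  expect_identical(fit_trca(ep)$filters, fit1$filters)
  ep1 <- subset_trials(ep, 1)
  expect_error(fit_trca(ep1), "at least 2 trials")
})

test_that("TRCA scores peak at the matching template and ignore filter signs", {
  ep <- simulate_subject(n_classes = 3, snr_db = 10, seed = 61)
  ep <- extract_window(ep, 1.0, 0.64)
  fit <- fit_trca(subset_trials(ep, 1:5))
  s1 <- trca_score(fit$templates$templates[[2]], fit$filters, fit$templates)
  expect_equal(s1[2], 1, tolerance = 1e-12)
  x <- get_trial(ep, 2, 6)
  s <- trca_score(x, fit$filters, fit$templates)
  expect_identical(classify_scores(s), 2L)
  Wf <- fit$filters; Wf[, 2] <- -Wf[, 2]
  expect_equal(trca_score(x, Wf, fit$templates), s, tolerance = 1e-12)
})

test_that("the two-step correlation vector matches a naive recomputation", {
  set.seed(71)
  W <- matrix(rnorm(12), 4, 3)
  test <- matrix(rnorm(4 * 50), 4)
  tmpl <- matrix(rnorm(4 * 50), 4)
  beta <- tstrca_beta(test, tmpl, W)
  expect_length(beta, 4L)
  naive <- c(cor(as.vector(tmpl), as.vector(test)),
             sapply(1:3, function(k)
               cor(drop(crossprod(W[, k], tmpl)), drop(crossprod(W[, k], test)))))
  expect_equal(beta, naive, tolerance = 1e-12)
  expect_true(all(abs(beta) <= 1 + 1e-12))
  # fixed points: self and anti-correlation
  expect_equal(tstrca_beta(tmpl, tmpl, W), rep(1, 4), tolerance = 1e-12)
  expect_equal(tstrca_beta(-tmpl, tmpl, W), rep(-1, 4), tolerance = 1e-12)
})

test_that("the ensemble score is the signed-square fusion of beta", {
  expect_identical(tstrca_score(rep(1, 4)), 4)
  expect_equal(tstrca_score(c(0.8, -0.3, 0)), 0.55, tolerance = 1e-12)
  set.seed(81)
  b <- runif(5, -1, 1)
  expect_identical(tstrca_score(b), signed_square_fuse(b))
})

test_that("two-step classification is correct and class-permutation equivariant", {
  set.seed(91)
  tmpl <- lapply(1:3, function(i) matrix(rnorm(4 * 60), 4))  # near-orthogonal
  W <- matrix(rnorm(12), 4, 3)
  for (j in 1:3)
    expect_identical(tstrca_classify(tmpl[[j]], W, tmpl), j)
  x <- matrix(rnorm(4 * 60), 4)
  perm <- c(3L, 1L, 2L)
  p0 <- tstrca_classify(x, W, tmpl)
  p1 <- tstrca_classify(x, W[, perm], tmpl[perm])
  expect_identical(perm[p1], p0)
})

test_that("restricted to its own-class filter without squaring, the two-step
           method ranks like standard TRCA", {
  ep <- simulate_subject(n_classes = 4, snr_db = -5, seed = 92)
  ep <- extract_window(ep, 0.5, 0.64)
  fit <- fit_trca(subset_trials(ep, 1:5))
  for (i in 1:4) {
    x <- get_trial(ep, i, 6)
    restricted <- sapply(1:4, function(j)
      tstrca_beta(x, fit$templates$templates[[j]], fit$filters)[j + 1L])
    expect_identical(order(restricted),
                     order(trca_score(x, fit$filters, fit$templates)))
  }
})

test_that("all decision scores are invariant to test-trial amplitude", {
  ep <- simulate_subject(n_classes = 3, snr_db = 0, seed = 93)
  ep <- extract_window(ep, 0.8, 0.64)
  fit <- fit_trca(subset_trials(ep, 1:5))
  x <- get_trial(ep, 1, 6)
  expect_equal(trca_score(3.7 * x, fit$filters, fit$templates),
               trca_score(x, fit$filters, fit$templates), tolerance = 1e-9)
  expect_equal(tstrca_beta(3.7 * x, fit$templates$templates[[2]], fit$filters),
               tstrca_beta(x, fit$templates$templates[[2]], fit$filters),
               tolerance = 1e-9)
  refs <- lapply(ep$stim_freqs, make_reference, n_harmonics = 3,
                 n_samples = ncol(x), fs = 250)
  expect_equal(cca_scores(3.7 * x, refs), cca_scores(x, refs),
               tolerance = 1e-9)
})
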