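test_that("sinusoidal references follow the sin/cos harmonic layout", {
  Z <- make_reference(10, 1, 3, 250)
  expect_equal(Z[1, ], c(0.2486899, 0.4817537, 0.6845471), tolerance = 1e-6)
  expect_equal(Z[2, ], cos(2 * pi * 10 * (1:3) / 250), tolerance = 1e-12)
  Z3 <- make_reference(10, 3, 100, 250)
  expect_identical(nrow(Z3), 6L)
  for (h in 1:3)
    expect_equal(Z3[2 * h - 1, ]^2 + Z3[2 * h, ]^2, rep(1, 100),
                 tolerance = 1e-12)
  expect_error(make_reference(30, 5, 100, 250), "Nyquist")
})

test_that("canonical correlation is exact under invertible linear relations", {
  set.seed(1)
  X <- matrix(rnorm(2 * 200), 2)
  A <- matrix(c(2, 1, -1, 3), 2)
  res <- canonical_correlation(X, A %*% X)
  expect_equal(res$rho, 1, tolerance = 1e-8)
  # projections obey the unit-variance constraint (1/T normalizer)
  px <- drop(crossprod(res$wx, X - rowMeans(X)))
  expect_equal(mean(px^2), 1, tolerance = 1e-6)
})

test_that("canonical correlation of independent noise is small", {
  set.seed(5)
  rho <- canonical_correlation(matrix(rnorm(2 * 2000), 2),
                               matrix(rnorm(2 * 2000), 2))$rho
  expect_lt(rho, 0.15)
})

test_that("canonical correlation matches a brute-force grid maximization", {
  X <- rbind(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  Y <- rbind(8:1, c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(canonical_correlation(X, Y)$rho, grid_search_cca(X, Y),
               tolerance = 1e-3)
  set.seed(7)
  X2 <- matrix(rnorm(2 * 40), 2); Y2 <- matrix(rnorm(2 * 40), 2)
  expect_equal(canonical_correlation(X2, Y2)$rho, grid_search_cca(X2, Y2),
               tolerance = 1e-3)
})

test_that("canonical correlation is symmetric and transform-invariant", {
  set.seed(3)
  for (k in 1:5) {
    X <- matrix(rnorm(2 * 80), 2); Y <- matrix(rnorm(3 * 80), 3)
    a <- canonical_correlation(X, Y)$rho
    expect_equal(a, canonical_correlation(Y, X)$rho, tolerance = 1e-10)
    A <- matrix(rnorm(4), 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    expect_equal(canonical_correlation(A %*% X, Y)$rho, a, tolerance = 1e-6)
  }
})

test_that("the whitened-SVD solver agrees with the classical solver", {
  set.seed(2)
  X <- matrix(rnorm(3 * 50), 3); Y <- matrix(rnorm(4 * 50), 4)
  expect_equal(canonical_correlation(X, Y, ridge = 0)$rho,
               stats::cancor(t(X), t(Y))$cor[1], tolerance = 1e-8)
})

test_that("degenerate inputs error without a ridge and need enough samples", {
  X <- rbind(1:20, 2 * (1:20))  # rank 1
  set.seed(4); Y <- matrix(rnorm(2 * 20), 2)
  expect_error(canonical_correlation(X, Y, ridge = 0), "singular")
  expect_silent(canonical_correlation(X, Y))
  expect_error(canonical_correlation(matrix(rnorm(8), 4, 2),
                                     matrix(rnorm(8), 4, 2)), "samples")
})

test_that("templates are exact trial means", {
  ep <- make_random_epochs(nf = 2, nt = 5, nc = 3, ns = 40, seed = 12)
  tb <- build_templates(ep)
  # identical trials: template equals the single trial
  ep1 <- ep; for (t in 1:5) ep1$data[1, t, , ] <- ep$data[1, 1, , ]
  expect_equal(build_templates(ep1)$templates[[1]], get_trial(ep, 1, 1))
  # X and -X cancel
  ep2 <- make_random_epochs(nf = 1, nt = 2, nc = 3, ns = 40, seed = 13)
  ep2$data[1, 2, , ] <- -ep2$data[1, 1, , ]
  expect_equal(max(abs(build_templates(ep2)$templates[[1]])), 0)
  # naive summation oracle
  naive <- matrix(0, 3, 40)
  for (t in 1:5) naive <- naive + get_trial(ep, 2, t)
  expect_equal(tb$templates[[2]], naive / 5, tolerance = 1e-12)
})

test_that("CCA scores rank the generating frequency first", {
  refs <- lapply(1:4, function(k) {
    set.seed(20 + k); matrix(rnorm(3 * 60), 3)
  })
  s <- cca_scores(refs[[3]], refs)
  expect_equal(s[3], 1, tolerance = 1e-6)
  expect_identical(which.max(s), 3L)
  # permutation equivariance
  perm <- c(2, 4, 1, 3)
  expect_equal(cca_scores(refs[[3]], refs[perm]), s[perm], tolerance = 1e-10)
  # a clean 10 Hz SSVEP is identified among sinusoidal references
  ep <- simulate_subject(n_classes = 3, freqs_hz = c(8, 10, 12),
                         snr_db = 20, seed = 30)
  test <- get_trial(extract_window(ep, 1.0, 0.64), 2, 1)
  zr <- lapply(c(8, 10, 12), make_reference, n_harmonics = 3,
               n_samples = ncol(test), fs = 250)
  expect_identical(classify_scores(cca_scores(test, zr)), 2L)
  expect_error(cca_scores(test, lapply(zr, function(z) z[, 1:10])),
               "samples")
})

test_that("extended-CCA correlation vector behaves at its fixed points", {
  set.seed(40)
  test <- matrix(rnorm(4 * 80), 4)
  Z <- make_reference(10, 2, 80, 250)
  r_self <- extcca_correlation_vector(test, test, Z)
  expect_equal(r_self[2], 1, tolerance = 1e-8)
  expect_equal(r_self[4], 1, tolerance = 1e-8)
  tmpl <- matrix(rnorm(4 * 80), 4)
  r <- extcca_correlation_vector(test, tmpl, Z)
  expect_identical(r[1], canonical_correlation(test, Z)$rho)
  # a noiseless trial maximizes every entry at its own class
  ep <- simulate_subject(n_classes = 3, freqs_hz = c(8, 10, 12),
                         snr_db = Inf, seed = 41)
  ep <- extract_window(ep, 1.0, 0.64)
  tb <- build_templates(subset_trials(ep, 1:5))
  x <- get_trial(ep, 2, 6)
  rs <- sapply(1:3, function(i) extcca_correlation_vector(
    x, tb$templates[[i]],
    make_reference(ep$stim_freqs[i], 3, ncol(x), 250)))
  for (k in 1:4) expect_identical(which.max(rs[k, ]), 2L)
})

test_that("with template terms zeroed, extended CCA ranks like standard CCA", {
  ep <- simulate_subject(n_classes = 4, snr_db = -5, seed = 42)
  ep <- extract_window(ep, 0.8, 0.64)
  tb <- build_templates(subset_trials(ep, 1:5))
  for (i in 1:4) {
    x <- get_trial(ep, i, 6)
    refs <- lapply(ep$stim_freqs, make_reference, n_harmonics = 3,
                   n_samples = ncol(x), fs = 250)
    r <- sapply(1:4, function(j) extcca_correlation_vector(
      x, tb$templates[[j]], refs[[j]]))
    zeroed <- sapply(1:4, function(j) signed_square_fuse(c(r[1, j], 0, 0, 0)))
    expect_identical(order(zeroed), order(cca_scores(x, refs)))
  }
})

test_that("signed-square fusion follows its arithmetic definition", {
  expect_identical(signed_square_fuse(c(1, 1, 1, 1)), 4)
  expect_identical(signed_square_fuse(c(-0.5, 0.5)), 0)
  expect_equal(signed_square_fuse(c(0.9, -0.2, 0.1)), 0.78, tolerance = 1e-12)
  expect_error(signed_square_fuse(c(0.1, NA)), "non-finite")
})

test_that("argmax classification breaks ties low and ignores score shifts", {
  expect_identical(classify_scores(c(0.1, 0.9, 0.3)), 2L)
  expect_message(tie <- classify_scores(c(0.5, 0.5, 0.5)), "tie")
  expect_identical(tie, 1L)
  s <- c(0.2, 0.7, 0.1)
  expect_identical(classify_scores(s + 10), classify_scores(s))
  expect_error(classify_scores(c(0.1, Inf)), "non-finite")
  expect_error(classify_scores(numeric(0)), "empty")
})
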