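test_that("an exact rank-1 matrix is reconstructed almost perfectly", {
  set.seed(11)
  w <- runif(8, 0.2, 1)
  h <- generate_primitive(120, 60)
  V <- outer(w, h)
  fit <- nmf_factorize(V, p = 1L, seed = 3L)
  expect_gte(fit$r_squared, 0.999)
  expect_true(all(fit$M >= 0) && all(fit$P >= 0))
})

test_that("reconstruction quality is non-decreasing in the rank", {
  set.seed(12)
  V <- matrix(runif(6 * 50), 6)
  r2 <- vapply(1:6, function(p) nmf_factorize(V, p, seed = 21L)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) > -1e-4))
  expect_gte(r2[6], r2[5])
})

test_that("the multiplicative updates monotonically decrease the objective", {
  set.seed(13)
  V <- matrix(runif(10 * 80), 10)
  fit <- nmf_factorize(V, p = 4L, seed = 5L, n_restarts = 2L)
  trace <- fit$err_trace
  idx <- seq(1L, length(trace), by = 10L)   # sampled every 10 iterations
  expect_true(all(diff(trace[idx]) <= 1e-8 * trace[1L]))
  expect_true(all(diff(trace) <= 1e-8 * trace[1L]))
})

test_that("factorization is deterministic given the seed and validates input", {
  V <- matrix(runif(5 * 30), 5)
  f1 <- nmf_factorize(V, 2L, seed = 9L)
  f2 <- nmf_factorize(V, 2L, seed = 9L)
  expect_identical(f1$M, f2$M)
  expect_identical(f1$P, f2$P)
  expect_error(nmf_factorize(-V, 2L), "nonnegative")
  expect_error(nmf_factorize(matrix(0, 4, 10), 1L), "all-zero")
  expect_error(nmf_factorize(V, 9L), "rank")
})

test_that("rank selection finds the knee of the R-squared curve", {
  # perfectly linear curve: one synergy suffices
  lin <- seq(0.5, 0.98, length.out = 13)
  expect_identical(as.integer(select_rank(lin)), 1L)

  # saturating curve, exactly linear from rank 3 onwards
  curve <- c(0.5, 0.8, 0.95 + 0.003 * (0:10))
  # brute-force oracle: regression MSE of every trailing segment
  oracle <- NA_integer_
  for (k in 1:13) {
    y <- curve[k:13]; x <- k:13
    mse <- if (length(y) < 3) 0 else mean(lm(y ~ x)$residuals^2)
    if (mse < 1e-5) { oracle <- k; break }
  }
  expect_identical(oracle, 3L)
  expect_identical(as.integer(select_rank(curve)), oracle)

  expect_warning(select_rank(c(0.9, 0.5, 0.95, rep(0.96, 10))), "decreases")
})

test_that("factor normalization moves scale onto the modules only", {
  set.seed(14)
  M <- matrix(runif(6 * 2), 6)
  P <- rbind(4 * generate_primitive(100, 40), 2 * generate_primitive(200, 50))
  nf <- normalize_factors(M, P)
  expect_equal(apply(nf$P, 1L, max), c(1, 1))
  expect_equal(nf$M[, 1L], 4 * M[, 1L])
  expect_equal(nf$M %*% nf$P, M %*% P, tolerance = 1e-10)
  # idempotence
  nf2 <- normalize_factors(nf$M, nf$P)
  expect_equal(nf2, nf, tolerance = 1e-12)
  # all-zero primitives are dropped
  expect_warning(nf0 <- normalize_factors(M, rbind(P[1L, ], 0)), "all-zero")
  expect_identical(nrow(nf0$P), 1L)
})

test_that("a noiseless three-synergy trial is recovered at rank 3", {
  gt <- default_ground_truth("SG", noise_snr = Inf, seed = 55L)
  tr <- synthesize_trial(gt)
  seg <- segment_landing(tr$grf[, 3L], tr$bodyweight)
  env <- condition_emg(tr$emg_raw, tr$rate)
  nt <- normalize_trial(env, tr$grf, seg)
  V <- normalize_amplitude(nt$emg, nt$emg)
  fit <- nmf_factorize(V, p = 3L, seed = 8L)
  expect_gte(fit$r_squared, 0.95)
  # amplitude normalization rescales the rows of V, so the planted modules
  # in analysis space are the row-rescaled ones
  M_ref <- gt$modules_true / apply(true_envelopes(gt), 1L, max)
  m <- match_synergies(fit$M, M_ref)
  expect_true(all(m$cosine > 0.95))
})

test_that("synergy matching finds the planted permutation", {
  set.seed(15)
  M <- matrix(runif(13 * 3, 0.05, 1), 13)
  perm <- c(3L, 1L, 2L)
  m <- match_synergies(M[, perm], M)
  expect_identical(m$perm, perm)
  expect_equal(m$cosine, rep(1, 3), tolerance = 1e-12)
})
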