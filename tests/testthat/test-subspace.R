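# Communication-subspace analytics against closed forms and a Monte-Carlo
# regression oracle.

make_test_cov <- function(ns = 8L, nt = 6L, rank = 2L, noise = 0.3,
                          seed = 11L) {
  # source covariance + target generated through a rank-limited map
  set.seed(seed)
  Ms <- matrix(rnorm(ns * ns), ns)
  C1 <- crossprod(Ms) / ns + diag(0.1, ns)
  A <- matrix(rnorm(ns * rank), ns) %*% matrix(rnorm(rank * nt), rank)
  C2 <- t(A) %*% C1 %*% A + diag(noise, nt)
  C3 <- C1 %*% A
  C <- rbind(cbind(C1, C3), cbind(t(C3), C2))
  list(C = C, src = seq_len(ns), tgt = ns + seq_len(nt), A = A)
}

test_that("independent target gives zero performance at all ranks", {
  f <- make_test_cov()
  C <- f$C
  C[f$src, f$tgt] <- 0
  C[f$tgt, f$src] <- 0
  res <- subspace_analysis(covariance_partition(C, f$src, f$tgt))
  expect_equal(res$performance, rep(0, length(res$performance)),
               tolerance = 1e-12)
  expect_equal(res$full_performance, 0, tolerance = 1e-12)
  expect_equal(subspace_dimensionality(res), 0L)
})

test_that("noiseless linear map gives full performance at the map rank", {
  f <- make_test_cov(rank = 2L, noise = 0)
  res <- subspace_analysis(covariance_partition(f$C, f$src, f$tgt))
  expect_equal(res$full_performance, 1, tolerance = 1e-8)
  expect_equal(subspace_dimensionality(res, "rank"), 2L)
  # performance saturates at rank 2
  expect_equal(res$performance[3L], 1, tolerance = 1e-8)
})

test_that("performance curve is nondecreasing and capped by the full value", {
  for (seed in c(1L, 5L, 9L)) {
    f <- make_test_cov(ns = 10L, nt = 7L, rank = 3L, seed = seed)
    res <- subspace_analysis(covariance_partition(f$C, f$src, f$tgt))
    expect_equal(res$performance[1L], 0)
    expect_true(all(diff(res$performance) >= -1e-12))
    expect_lte(max(res$performance), res$full_performance + 1e-12)
    expect_true(all(res$eigvals >= 0))
  }
})

test_that("rank-i error from the readout formula matches the eigen route", {
  # epsilon_i computed directly from the reduced-rank readout must satisfy
  # 1 - eps_i/eps_0 = cumulative eigenvalue performance (two code paths)
  f <- make_test_cov(ns = 9L, nt = 7L, rank = 4L, seed = 3L)
  part <- covariance_partition(f$C, f$src, f$tgt)
  res <- subspace_analysis(part)
  eps0 <- sum(diag(part$C2))
  for (i in 0:7) {
    V_i <- res$eigvecs[, seq_len(i), drop = FALSE]
    P_i <- V_i %*% t(V_i)
    B_i <- res$B_opt %*% P_i
    eps_i <- sum(diag(part$C2 + t(B_i) %*% part$C1 %*% B_i -
                        2 * t(B_i) %*% part$C3))
    expect_equal(1 - eps_i / eps0, res$performance[i + 1L],
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo regression on samples reproduces the performance", {
  f <- make_test_cov(ns = 6L, nt = 5L, rank = 2L, noise = 0.2, seed = 7L)
  part <- covariance_partition(f$C, f$src, f$tgt)
  res <- subspace_analysis(part)
  # draw Gaussian samples with covariance C and fit by least squares
  set.seed(99)
  n_draw <- 4e5
  R <- chol(f$C + diag(1e-12, nrow(f$C)))
  X <- matrix(rnorm(n_draw * nrow(f$C)), n_draw) %*% R
  s <- X[, f$src]
  t_ <- X[, f$tgt]
  B_hat <- solve(crossprod(s) / n_draw, crossprod(s, t_) / n_draw)
  pred <- s %*% B_hat
  perf_full <- 1 - sum((t_ - pred)^2) / sum(t_^2)
  expect_lt(abs(perf_full - res$full_performance), 0.01)
})

test_that("subset averaging is deterministic and reports SEM", {
  f <- make_test_cov(ns = 20L, nt = 20L, rank = 3L, seed = 13L)
  r1 <- subset_averaged_performance(f$C, f$src, f$tgt, subset_size = 8L,
                                    n_repeats = 6L, seed = 21L)
  r2 <- subset_averaged_performance(f$C, f$src, f$tgt, subset_size = 8L,
                                    n_repeats = 6L, seed = 21L)
  expect_identical(r1, r2)
  r3 <- subset_averaged_performance(f$C, f$src, f$tgt, subset_size = 8L,
                                    n_repeats = 1L, seed = 21L)
  expect_equal(r3$full_sem, 0)
  expect_error(
    subset_averaged_performance(f$C, f$src, f$tgt, subset_size = 30L),
    "population"
  )
  # within-area draws are disjoint
  rw <- subset_averaged_performance(f$C, f$src, f$src, subset_size = 10L,
                                    n_repeats = 3L, seed = 2L)
  expect_true(is.finite(rw$full_performance))
})

test_that("rank criterion equals the rank of the cross-covariance", {
  f <- make_test_cov(ns = 9L, nt = 9L, rank = 3L, noise = 0.1, seed = 17L)
  part <- covariance_partition(f$C, f$src, f$tgt)
  res <- subspace_analysis(part)
  r_c3 <- qr(part$C3)$rank
  expect_equal(subspace_dimensionality(res, "rank"), r_c3)
})

test_that("band covariance is the symmetrized real cross-spectrum", {
  circ <- small_two_area(n = 12L)
  lin <- linearize_circuit(circ, stimulus(30, 0))
  sys <- build_stochastic_system(lin)
  ch <- principal_channels(lin)
  freqs <- seq(2, 120, by = 2)
  sp <- psd(sys, freqs, ch$A)
  M <- band_covariance(sp, 40)
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_error(band_covariance(sp, 500), "grid")
  # trapezoid sum of band covariances over the full grid approximates C(0)
  C <- channel_covariance(stationary_covariance(sys), ch$A)
  freqs2 <- c(seq(0.25, 300, by = 0.25), seq(301, 5000, by = 2))
  sp2 <- psd(sys, freqs2, ch$A)
  acc <- matrix(0, nrow(C), ncol(C))
  for (k in seq_len(length(freqs2) - 1L)) {
    acc <- acc + (freqs2[k + 1L] - freqs2[k]) *
      (Re(sp2$S[, , k]) + Re(sp2$S[, , k + 1L]))
  }
  expect_lt(norm(acc - C, "F") / norm(C, "F"), 0.01)
})

test_that("partitions demand disjoint index sets", {
  expect_error(covariance_partition(diag(4), 1:2, 2:3), "disjoint")
})
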