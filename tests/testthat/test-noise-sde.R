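# Stochastic system construction, the SDE oracle, and LFP conventions.

test_that("noise spec validates its fields", {
  expect_error(noise_spec(synaptic_amp = -1), "amplitudes")
  expect_error(noise_spec(tau_noise = 0), "tau_noise")
  expect_error(noise_spec(extrinsic_corr = 2), "extrinsic_corr")
})

test_that("stochastic system has the expected structure", {
  circ <- small_two_area()
  lin <- linearize_circuit(circ, stimulus(30, 0))
  sys <- build_stochastic_system(lin, noise_spec())
  N <- n_states(circ)
  # one OU state per membrane equation
  expect_equal(dim(sys$J_aug), c(2L * N, 2L * N))
  # zero amplitudes give zero forcing
  sys0 <- build_stochastic_system(lin, noise_spec(synaptic_amp = 0,
                                                  mult_amp = 0,
                                                  extrinsic_amp = 0))
  L <- as.matrix(sys0$L_aug)
  expect_equal(max(abs(L %*% t(L))), 0)
  # at zero contrast the multiplicative rows vanish (rate-proportional)
  lin0 <- linearize_circuit(circ, stimulus(0, 0))
  sys_sp <- build_stochastic_system(lin0, noise_spec())
  mult_block <- as.matrix(sys_sp$L_aug)[seq_len(N), seq_len(N)]
  expect_lt(max(abs(mult_block)), 1e-4)  # spontaneous rates are tiny
})

test_that("scalar OU process matches its closed-form statistics", {
  tau <- 2
  sig <- 0.5
  sys <- list(J_aug = Matrix::Matrix(-1 / tau, 1, 1, sparse = TRUE),
              L_aug = Matrix::Matrix(sig, 1, 1, sparse = TRUE))
  # analytic variance sigma^2 tau / 2 via the Lyapunov solver
  v_lyap <- lyap_solve_cpp(matrix(-1 / tau, 1, 1), matrix(sig^2, 1, 1))
  expect_equal(v_lyap[1, 1], sig^2 * tau / 2, tolerance = 1e-12)
  # empirical variance within 3 standard errors
  r <- simulate_sde(sys, duration = 20000, dt = 0.01, seed = 7,
                    cov_idx = 1L, cov_thin = 20L)
  v_hat <- r$covariance[1, 1]
  n_eff <- 20000 / (2 * tau)  # decorrelation-time heuristic
  se <- sqrt(2 / n_eff) * sig^2 * tau / 2
  expect_lt(abs(v_hat - sig^2 * tau / 2), 3 * se)
  # Lorentzian spectrum S(omega) = sig^2 / (omega^2 + 1/tau^2)
  S <- psd_resolvent_cpp(matrix(-1 / tau, 1, 1), matrix(1, 1, 1),
                         q0 = sig^2, q1 = 0, omegas = c(0.1, 0.5, 1),
                         tau_n = 1)
  expect_equal(Re(S[1, 1, ]), sig^2 / (c(0.1, 0.5, 1)^2 + 1 / tau^2),
               tolerance = 1e-12)
})

test_that("identical seeds give identical paths, different seeds differ", {
  circ <- small_two_area()
  lin <- linearize_circuit(circ, stimulus(30, 0))
  sys <- build_stochastic_system(lin)
  w <- matrix(0, 1, 2L * n_states(circ))
  w[1, seq_len(16)] <- 1
  r1 <- simulate_sde(sys, duration = 50, dt = 0.02, seed = 9, record = w)
  r2 <- simulate_sde(sys, duration = 50, dt = 0.02, seed = 9, record = w)
  r3 <- simulate_sde(sys, duration = 50, dt = 0.02, seed = 10, record = w)
  expect_identical(r1$recorded, r2$recorded)
  expect_false(identical(r1$recorded, r3$recorded))
})

test_that("zero noise keeps the linearized system at rest", {
  circ <- small_two_area()
  lin <- linearize_circuit(circ, stimulus(30, 0))
  sys <- build_stochastic_system(lin, noise_spec(synaptic_amp = 0,
                                                 mult_amp = 0))
  r <- simulate_sde(sys, duration = 20, dt = 0.02,
                    record = seq_len(4L), record_every = 50L)
  expect_equal(max(abs(r$recorded)), 0)
})

test_that("oracle triangle holds on a small circuit", {
  # Lyapunov covariance vs Wiener-Khinchin integral vs SDE simulation
  circ <- small_two_area(n = 12L)
  lin <- linearize_circuit(circ, stimulus(40, 0))
  sys <- build_stochastic_system(lin)
  Cfull <- stationary_covariance(sys, full = TRUE)
  expect_lt(lyapunov_residual(sys, Cfull), 1e-10)
  C <- stationary_covariance(sys)
  # spectral integral over a wide grid reproduces selected entries
  idx <- c(principal_index(circ, "V1")[c(1L, 6L)],
           principal_index(circ, "V2")[6L])
  freqs <- c(seq(0.05, 50, by = 0.05), seq(50.2, 400, by = 0.2),
             seq(401.5, 5000, by = 1.5))
  sp <- psd(sys, freqs, idx)
  for (a in 1:3) for (b in 1:3) {
    v <- Re(sp$S[a, b, ])
    est <- 2 * sum(diff(freqs) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
    expect_lt(abs(est - C[idx[a], idx[b]]) / abs(C[idx[a], idx[b]]), 0.01)
  }
  # empirical covariance from the SDE
  r <- simulate_sde(sys, duration = 8000, dt = 0.01, seed = 2,
                    cov_thin = 10L)
  expect_lt(norm(r$covariance - C, "F") / norm(C, "F"), 0.1)
})

test_that("LFP spectrum follows the extrinsic-noise conventions", {
  circ <- small_two_area()
  lin <- linearize_circuit(circ, stimulus(30, 0))
  sys <- build_stochastic_system(lin, noise_spec(extrinsic_amp = 0.5,
                                                 extrinsic_corr = 0))
  freqs <- c(5, 20, 50)
  bare <- lfp_spectrum(sys, freqs, include_extrinsic = FALSE)
  with_ext <- lfp_spectrum(sys, freqs)
  # extrinsic_amp = 0 leaves the spectrum untouched
  sys0 <- build_stochastic_system(lin, noise_spec(extrinsic_amp = 0))
  expect_equal(lfp_spectrum(sys0, freqs)$S, bare$S, tolerance = 1e-12)
  # corr = 0: only the auto-spectra gain the flat term
  expect_equal(Re(with_ext$S[1, 1, ]) - Re(bare$S[1, 1, ]),
               rep(0.25, 3), tolerance = 1e-12)
  expect_equal(with_ext$S[1, 2, ], bare$S[1, 2, ], tolerance = 1e-12)
  # perfectly correlated extrinsic noise with no circuit noise: coherence 1
  sys1 <- build_stochastic_system(lin, noise_spec(synaptic_amp = 0,
                                                  mult_amp = 0,
                                                  extrinsic_amp = 0.5,
                                                  extrinsic_corr = 1))
  sp1 <- lfp_spectrum(sys1, freqs)
  co <- coherence(sp1, 1L, 2L)
  expect_equal(co$kappa, rep(1, 3), tolerance = 1e-10)
})
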