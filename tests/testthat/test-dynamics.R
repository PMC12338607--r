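# Rate nonlinearity, right-hand side, fixed points, Jacobian, integration.

test_that("rate nonlinearity rectifies and squares, smoothly if requested", {
  expect_equal(rate_nonlinearity(0), 0)
  expect_equal(rate_nonlinearity(-3), 0)
  expect_equal(rate_nonlinearity(2), 4)
  v <- seq(-1, 1, length.out = 101)
  r <- rate_nonlinearity(v, smoothing = 0.05)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) >= 0))
  # converges to the hard form as the width shrinks
  expect_equal(rate_nonlinearity(v, smoothing = 1e-9),
               rate_nonlinearity(v), tolerance = 1e-6)
  expect_error(rate_nonlinearity(1, smoothing = -1), "smoothing")
})

test_that("rhs at the zero state matches the printed relaxation terms", {
  circ <- small_two_area(identity_recurrent = TRUE)
  z <- drive_at(circ, 0)
  d <- circuit_rhs(circ, initial_state(circ), z)
  sig <- circ$areas$V1$params$sigma
  # q relaxes toward zero rate, u toward sigma^2/2 (per unit tau)
  expect_equal(d[state_index(circ, "V1", "q")], rep(0, 16))
  expect_equal(d[state_index(circ, "V1", "u")], rep(sig^2 / 2, 16))
  expect_equal(d[state_index(circ, "V1", "y")], rep(0, 16))
})

test_that("doubling all time constants halves the membrane relaxations", {
  # the y, u and q equations scale as 1/tau; the gain-population equation
  # carries the alpha * du/dt coupling, which scales as 1/tau^2 by
  # construction, so it is excluded here
  p2 <- area_parameters(tau_y = 2, tau_u = 2, tau_a = 2, tau_q = 2)
  c1 <- small_two_area()
  c2 <- small_two_area(params = p2)
  z <- drive_at(c1, 30)
  st <- seq(0.01, by = 0.013, length.out = n_states(c1))
  d1 <- circuit_rhs(c1, st, z)
  d2 <- circuit_rhs(c2, st, z)
  keep <- unlist(lapply(c("V1", "V2"), function(a) {
    c(state_index(c1, a, "y"), state_index(c1, a, "u"),
      state_index(c1, a, "q"))
  }))
  expect_equal(d2[keep], d1[keep] / 2, tolerance = 1e-12)
})

test_that("balanced identity circuit has the exact normalization fixed point", {
  circ <- small_two_area(identity_recurrent = TRUE)
  for (cc in c(0, 3, 12, 50, 100)) {
    z <- drive_at(circ, cc)
    fp <- solve_fixed_point(circ, z)
    expect_lt(fp$residual, 1e-12)
    oracle <- normalization_rates(circ, z)
    expect_lt(max(abs(fp$rates$V1 - oracle$V1)), 1e-10)
    expect_lt(max(abs(fp$rates$V2 - oracle$V2)), 1e-10)
    expect_true(attr(fp, "stable"))
  }
})

test_that("fixed point matches the terminal state of a long simulation", {
  circ <- small_two_area()
  z <- drive_at(circ, 50)
  fp <- solve_fixed_point(circ, z)
  traj <- simulate_circuit(circ, z, duration = 400, dt = 2)
  terminal <- as.numeric(traj[nrow(traj), -1L])
  expect_lt(max(abs(terminal - fp$state)), 1e-6)
  expect_true(all(diff(traj[, 1L]) > 0))
})

test_that("trajectories from different initial states converge", {
  circ <- small_two_area()
  z <- drive_at(circ, 25)
  t1 <- simulate_circuit(circ, z, duration = 400, dt = 2)
  x0 <- rep(c(0.3, 0.05, 0.2, 0.1), each = 16)
  x0 <- rep(x0, length.out = n_states(circ))
  t2 <- simulate_circuit(circ, z, initial_state = x0, duration = 400,
                         dt = 2)
  expect_lt(max(abs(t1[nrow(t1), -1L] - t2[nrow(t2), -1L])), 1e-5)
})

test_that("a circuit at its fixed point stays there", {
  circ <- small_two_area()
  z <- drive_at(circ, 0)
  fp <- solve_fixed_point(circ, z)
  traj <- simulate_circuit(circ, z, initial_state = fp$state,
                           duration = 50, dt = 1)
  drift <- apply(abs(sweep(traj[, -1L], 2L, fp$state)), 1L, max)
  expect_lt(max(drift), 1e-6)
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(42)
  for (gamma in c(0.5, 1)) {
    circ <- small_two_area(gamma = gamma)
    z <- drive_at(circ, 50)
    fp <- solve_fixed_point(circ, z)
    J <- jacobian_at(circ, fp$state, z, smoothing = 1e-3)
    for (k in 1:4) {
      v <- rnorm(length(fp$state))
      v <- v / sqrt(sum(v^2))
      fd <- fd_directional(circ, fp$state, z, v, smoothing = 1e-3)
      an <- as.numeric(J %*% v)
      expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-5)
    }
  }
})

test_that("Jacobian requires smoothing and decouples disconnected areas", {
  circ <- small_two_area()
  z <- drive_at(circ, 10)
  fp <- solve_fixed_point(circ, z)
  expect_error(jacobian_at(circ, fp$state, z, smoothing = 0), "smoothing")
  # zero out the inter-areal weights: block-diagonal Jacobian
  circ0 <- circ
  circ0$edges[[1L]]$W_fb <- matrix(0, 16, 16)
  fp0 <- solve_fixed_point(circ0, z)
  J0 <- jacobian_at(circ0, fp0$state, z)
  i1 <- 1:64
  i2 <- 65:128
  expect_equal(max(abs(J0[i1, i2])), 0)
  expect_equal(max(abs(J0[i2, i1])), 0)
})

test_that("raising the feedback gain never decreases the rates", {
  for (cc in c(6, 25, 50)) {
    circ_lo <- small_two_area(gamma = 1)
    circ_hi <- small_two_area(gamma = 1.1)
    z <- drive_at(circ_lo, cc)
    r_lo <- solve_fixed_point(circ_lo, z)$rates
    r_hi <- solve_fixed_point(circ_hi, z)$rates
    expect_gte(max(r_hi$V1), max(r_lo$V1) - 1e-12)
    expect_gte(max(r_hi$V2), max(r_lo$V2) - 1e-12)
  }
})

test_that("contrast response is zero at zero contrast and saturating", {
  circ <- small_two_area()
  tab <- contrast_response(circ, contrasts = c(0, 6, 12, 25, 50, 100))
  v1 <- tab$rate[tab$area == "V1"]
  v2 <- tab$rate[tab$area == "V2"]
  expect_equal(v1[1L], 0)
  expect_equal(v2[1L], 0)
  expect_true(all(diff(v1) > -1e-10))
  # the higher area may supersaturate mildly; no more than a 5% decline
  expect_true(all(v2 >= cummax(v2) * 0.95))
  # saturation: the late increments are much smaller than the early ones
  expect_lt(v1[6L] - v1[5L], (v1[3L] - v1[2L]))
})

test_that("dimension mismatches raise structural errors", {
  circ <- small_two_area()
  expect_error(circuit_rhs(circ, rep(0, 5), drive_at(circ, 10)), "state")
  expect_error(circuit_rhs(circ, initial_state(circ), rep(0, 3)), "drive")
})
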