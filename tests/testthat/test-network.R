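# Ring geometry, tuning curves, connectivity builders and input drive.

test_that("tuning curves are raised cosines with the stated support", {
  g <- ring_geometry(72)
  tc <- build_tuning_curves(g, half_width = 30)
  # peak of 1 at the preferred orientation
  expect_equal(diag(tc), rep(1, 72))
  # zero at maximal circular distance (90 degrees away)
  shifted <- vapply(seq_len(72), function(i) {
    tc[i, (i + 35L) %% 72L + 1L]
  }, numeric(1))
  expect_true(all(abs(shifted) < 1e-12))
  # circulant structure: identical row sums
  expect_lt(diff(range(rowSums(tc))), 1e-10)
  # rows are circular shifts of one another
  expect_equal(tc[2, c(2:72, 1)], tc[1, ], tolerance = 1e-12)
})

test_that("tuning curve construction validates the half width", {
  g <- ring_geometry(16)
  expect_error(build_tuning_curves(g, half_width = 0), "half_width")
  expect_error(build_tuning_curves(g, half_width = 95), "half_width")
})

test_that("recurrent weights are circulant, center-surround, unit radius", {
  for (n in c(8L, 16L, 30L, 72L)) {
    g <- ring_geometry(n)
    w <- build_recurrent_weights(g, excit_width = 20, inhib_width = 60,
                                 inhib_strength = 0.5)
    rho <- max(Mod(eigen(w, only.values = TRUE)$values))
    expect_lt(abs(rho - 1), 1e-10)
    expect_true(all(diag(w) > 0))
    # most distant connection is inhibitory
    far <- w[cbind(seq_len(n), (seq_len(n) + n %/% 2L - 1L) %% n + 1L)]
    expect_true(all(far <= 0))
    # circulant: eigenvalues equal the DFT of the first row
    ev <- sort(Re(eigen(w, only.values = TRUE)$values))
    dft <- sort(Re(stats::fft(w[1L, ])))
    expect_equal(ev, dft, tolerance = 1e-8)
  }
})

test_that("zero surround gives a single nonnegative bump", {
  g <- ring_geometry(24)
  w <- build_recurrent_weights(g, 20, 60, inhib_strength = 0)
  expect_true(all(w >= 0))
  row <- w[1L, ]
  d <- orientation_distance(g$orientations, g$orientations[1L])
  expect_true(all(diff(row[order(d)]) <= 1e-12))
})

test_that("feedback weights are symmetric, nonnegative, diagonally dominant", {
  for (n in c(8L, 16L, 30L, 72L)) {
    g <- ring_geometry(n)
    w <- build_feedback_weights(g, width = 15, diag_boost = 2)
    expect_lt(max(abs(w - t(w))), 1e-12)
    expect_gte(min(w), 0)
    excess <- diag(w) - (rowSums(w) - diag(w))
    expect_true(all(excess > 0))
    expect_equal(rowSums(w), rep(1, n), tolerance = 1e-12)
    expect_silent(validate_connectivity(list(), list(w)))
  }
})

test_that("input drive scales linearly with contrast and peaks correctly", {
  g <- ring_geometry(72)
  z0 <- input_drive(stimulus(0, 30), g)
  expect_equal(z0, rep(0, 72))
  z100 <- input_drive(stimulus(100, g$orientations[10L]), g)
  expect_equal(which.max(z100), 10L)
  expect_equal(max(z100), 1.0)
  z50 <- input_drive(stimulus(50, g$orientations[10L]), g)
  expect_equal(z50, z100 / 2, tolerance = 1e-12)
  expect_true(all(z100 >= 0))
})

test_that("stimulus orientation wraps mod 180 and shifts permute the drive", {
  g <- ring_geometry(36)
  expect_equal(stimulus(10, 190)$orientation, 10)
  z1 <- input_drive(stimulus(80, g$orientations[5L]), g)
  z2 <- input_drive(stimulus(80, g$orientations[6L]), g)
  expect_equal(z2, z1[c(36L, 1:35)], tolerance = 1e-12)
})

test_that("connectivity builders are deterministic", {
  g <- ring_geometry(30)
  expect_identical(build_recurrent_weights(g), build_recurrent_weights(g))
  expect_identical(build_feedback_weights(g), build_feedback_weights(g))
})

test_that("degenerate kernel parameters raise construction errors", {
  g <- ring_geometry(16)
  expect_error(build_recurrent_weights(g, 60, 20), "excit_width")
  expect_error(build_feedback_weights(g, width = -1), "width")
  expect_error(ring_geometry(3), "n_neurons")
})
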