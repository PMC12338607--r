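# Shared fixtures: small circuits keep the matrix algebra cheap; the
# default-size (72-neuron) circuit is reserved for the acceptance tests.

small_two_area <- function(n = 16L, gamma = 1, beta = 1,
                           identity_recurrent = FALSE, ...) {
  two_area_circuit(n_neurons = n, gamma = gamma, beta = beta,
                   identity_recurrent = identity_recurrent, ...)
}

# central finite differences of the (smoothed) right-hand side along
# random directions: the brute-force oracle for the analytic Jacobian
fd_directional <- function(circuit, state, drive, v, smoothing, h = 1e-6) {
  (circuit_rhs(circuit, state + h * v, drive, smoothing = smoothing) -
     circuit_rhs(circuit, state - h * v, drive, smoothing = smoothing)) /
    (2 * h)
}

drive_at <- function(circuit, contrast, orientation = 0) {
  input_drive(stimulus(contrast, orientation), circuit$geometry,
              circuit$half_width)
}

# independent statement of the normalization equation (the fixed-point
# oracle): rates = z^2 / (sigma^2 + pool), pool = pool_scale * sum(z^2),
# applied area by area up the hierarchy
normalization_rates <- function(circuit, drive) {
  out <- list()
  z <- drive
  for (nm in names(circuit$areas)) {
    sig <- circuit$areas[[nm]]$params$sigma
    s <- sig^2 + circuit$pool_scale * sum(z^2)
    out[[nm]] <- z^2 / s
    if (nm != names(circuit$areas)[length(circuit$areas)]) {
      e <- Filter(function(e) e$lower == nm, circuit$edges)[[1L]]
      z <- as.numeric(t(e$W_fb) %*% out[[nm]])
    }
  }
  out
}
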