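# Stochastic forcing: low-pass synaptic noise, multiplicative rate noise,
# extrinsic LFP noise; linearization and the augmented stochastic system.

#' Noise specification
#'
#' The circuit noise model has three components: (i) additive synaptic noise,
#' low-pass filtered by an Ornstein-Uhlenbeck stage with time constant
#' `tau_noise`, entering every membrane equation; (ii) multiplicative
#' Gaussian white noise on the firing-rate (principal-cell) dynamics, with
#' amplitude proportional to the fixed-point firing rate (frozen-coefficient
#' small-noise treatment); (iii) extrinsic noise that contaminates the LFP
#' observation only, correlated across areas, with negligible impact on the
#' circuit dynamics.
#'
#' @param synaptic_amp Amplitude of the synaptic noise (its low-frequency
#'   spectral density is `synaptic_amp^2` per channel).
#' @param tau_noise Time constant of the noise low-pass filter, ms.
#' @param mult_amp Coefficient of the multiplicative rate noise.
#' @param extrinsic_amp Amplitude of the extrinsic (measurement) LFP noise.
#' @param extrinsic_corr Pairwise correlation of the extrinsic noise across
#'   areas, in `[0, 1]`.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(synaptic_amp = 1.0, tau_noise = 1.0, mult_amp = 0.1,
                       extrinsic_amp = 0.05, extrinsic_corr = 0.5) {
  if (any(c(synaptic_amp, mult_amp, extrinsic_amp) < 0)) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  if (tau_noise <= 0) stop("`tau_noise` must be > 0", call. = FALSE)
  if (extrinsic_corr < 0 || extrinsic_corr > 1) {
    stop("`extrinsic_corr` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(synaptic_amp = synaptic_amp, tau_noise = tau_noise,
                 mult_amp = mult_amp, extrinsic_amp = extrinsic_amp,
                 extrinsic_corr = extrinsic_corr),
            class = "noise_spec")
}

#' Linearize a circuit around its driven operating point
#'
#' Solves the fixed point of the smoothed (Gaussian-rectification) dynamics
#' by damped Newton iteration from the analytic normalization seed, and
#' evaluates the analytic Jacobian there. The smoothed operating point
#' matters at rest: spontaneous activity sits slightly above threshold,
#' which defines the baseline spectra.
#'
#' @param circuit A `circuit`.
#' @param stim A [stimulus()] (or `NULL` together with `drive`).
#' @param drive Optional explicit drive vector (overrides `stim`).
#' @param smoothing Gaussian-rectification width.
#' @param frozen_gain If `TRUE`, sever the recurrent-gain loop in the
#'   Jacobian (normalization-removed control).
#' @return Object of class `linearized_circuit`: `J`, `state`, `drive`,
#'   `rates` (principal rates per area), `smoothing`, `circuit`.
#' @export
linearize_circuit <- function(circuit, stim = NULL, drive = NULL,
                              smoothing = 1e-3, frozen_gain = FALSE) {
  if (is.null(drive)) {
    if (is.null(stim)) stop("supply `stim` or `drive`", call. = FALSE)
    drive <- input_drive(stim, circuit$geometry, circuit$half_width)
  }
  x <- analytic_fixed_point(circuit, drive)$state
  newton <- function(x) {
    res <- circuit_rhs(circuit, x, drive, smoothing = smoothing)
    for (it in seq_len(300L)) {
      if (max(abs(res)) < 1e-12) break
      J <- jacobian_at(circuit, x, drive, smoothing = smoothing)
      step <- tryCatch(solve(J, res), error = function(e)
        solve(J + diag(1e-8, nrow(J)), res))
      lambda <- 1
      repeat {
        xn <- x - lambda * step
        resn <- circuit_rhs(circuit, xn, drive, smoothing = smoothing)
        if (max(abs(resn)) < max(abs(res)) || lambda < 1e-9) break
        lambda <- lambda / 2
      }
      x <- xn
      res <- resn
    }
    list(x = x, res = max(abs(res)))
  }
  sol <- newton(x)
  if (sol$res > 1e-8) {
    # pseudo-transient fallback: let the smoothed dynamics settle, retry
    traj <- simulate_circuit(circuit, drive, initial_state = sol$x,
                             duration = 500, dt = 10,
                             smoothing = smoothing)
    sol <- newton(as.numeric(traj[nrow(traj), -1L]))
  }
  x <- sol$x
  if (sol$res > 1e-8) {
    stop("linearization operating point did not converge (residual ",
         format(sol$res), ")", call. = FALSE)
  }
  J <- jacobian_at(circuit, x, drive, smoothing = smoothing,
                   frozen_gain = frozen_gain)
  blocks <- unpack_state(circuit, x)
  rates <- lapply(blocks, function(b) rectify(b$y, smoothing)^2)
  structure(
    list(J = J, state = x, drive = drive, rates = rates,
         smoothing = smoothing, circuit = circuit,
         frozen_gain = frozen_gain),
    class = "linearized_circuit"
  )
}

# Membrane time constant of every state row, packed like the state vector
state_taus <- function(circuit) {
  n <- circuit$geometry$n
  unlist(lapply(circuit$areas, function(ar) {
    rep(c(ar$params$tau_y, ar$params$tau_u, ar$params$tau_a,
          ar$params$tau_q), each = n)
  }), use.names = FALSE)
}

# Full-state vector of fixed-point firing rates (principal rows only; the
# multiplicative noise acts on the firing-rate dynamics)
state_rates <- function(lin) {
  circuit <- lin$circuit
  r <- numeric(n_states(circuit))
  for (nm in names(circuit$areas)) {
    r[state_index(circuit, nm, "y")] <- lin$rates[[nm]]
  }
  r
}

#' Build the augmented stochastic system around a linearization
#'
#' Augments the linearized circuit with one Ornstein-Uhlenbeck noise state
#' per membrane equation (realizing the low-pass filtered synaptic noise)
#' and adds the multiplicative rate noise as frozen-coefficient white
#' forcing on the principal-cell equations. The extrinsic noise is not part
#' of the dynamics; it only enters LFP observations (see [lfp_spectrum()]).
#'
#' @param lin A [linearize_circuit()] result.
#' @param noise A [noise_spec()].
#' @return Object of class `stochastic_system` with the circuit Jacobian
#'   `J`, augmented Jacobian `J_aug` and dispersion `L_aug` (sparse), the
#'   diagonal forcing spectra `q0` (white) and `q1` (low-pass, scaled by
#'   `1/(1 + (omega tau_noise)^2)`), and metadata.
#' @export
build_stochastic_system <- function(lin, noise = noise_spec()) {
  stopifnot(inherits(lin, "linearized_circuit"),
            inherits(noise, "noise_spec"))
  circuit <- lin$circuit
  N <- n_states(circuit)
  taus <- state_taus(circuit)
  rates <- state_rates(lin)

  ev <- eigen(lin$J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("linearized system is unstable (max Re eigenvalue ",
         format(max(Re(ev))), "); no stationary statistics exist",
         call. = FALSE)
  }

  mult_sd <- noise$mult_amp * rates / taus
  syn_in <- noise$synaptic_amp / noise$tau_noise

  J_aug <- rbind(
    cbind(lin$J, diag(1 / taus)),
    cbind(matrix(0, N, N), diag(-1 / noise$tau_noise, N))
  )
  L_aug <- rbind(
    cbind(diag(mult_sd, N), matrix(0, N, N)),
    cbind(matrix(0, N, N), diag(syn_in, N))
  )
  structure(
    list(J = lin$J, J_aug = Matrix::Matrix(J_aug, sparse = TRUE),
         L_aug = Matrix::Matrix(L_aug, sparse = TRUE),
         q0 = mult_sd^2, q1 = (noise$synaptic_amp / taus)^2,
         tau_noise = noise$tau_noise,
         lin = lin, noise = noise, n_circuit = N),
    class = "stochastic_system"
  )
}

#' @export
print.stochastic_system <- function(x, ...) {
  cat("<stochastic_system> ", x$n_circuit, " circuit states + ",
      x$n_circuit, " noise-filter states\n", sep = "")
  invisible(x)
}

#' LFP observation weights for an area
#'
#' The LFP proxy of an area is the sum of its principal-cell membrane
#' potentials. Returns the weight vector over circuit states.
#'
#' @param circuit A `circuit`.
#' @param area Area name.
#' @return Numeric vector of length `n_states(circuit)`.
#' @export
lfp_weights <- function(circuit, area) {
  if (!area %in% names(circuit$areas)) {
    stop("unknown area `", area, "`", call. = FALSE)
  }
  w <- numeric(n_states(circuit))
  w[state_index(circuit, area, "y")] <- 1
  w
}
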