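# Stationary covariance via the Lyapunov equation, and its frequency
# decomposition.

#' Stationary covariance of the stochastic circuit
#'
#' Solves `J C + C J^T = -L D L^T` for the augmented system (circuit states
#' plus noise-filter states) using the block structure: the noise-filter
#' block is an uncoupled Ornstein-Uhlenbeck process with known covariance,
#' the cross block solves a linear (Sylvester) system, and the circuit block
#' solves a dense Lyapunov equation by Bartels-Stewart on the Schur form.
#' The result is symmetrized and marginalized back to the circuit states
#' unless `full = TRUE`.
#'
#' @param system A [build_stochastic_system()] result.
#' @param full If `TRUE`, return the full augmented covariance.
#' @return Symmetric covariance matrix over the circuit states (or the
#'   augmented states).
#' @export
stationary_covariance <- function(system, full = FALSE) {
  stopifnot(inherits(system, "stochastic_system"))
  N <- system$n_circuit
  circuit <- system$lin$circuit
  taus <- state_taus(circuit)
  ns <- system$noise

  # OU block: Var(eta_i) = synaptic_amp^2 / (2 tau_noise)
  c_ou <- ns$synaptic_amp^2 / (2 * ns$tau_noise)
  # cross block: (J - I/tau_noise) C12 = -B C22, with B = diag(1/tau)
  B <- diag(1 / taus, N)
  C12 <- solve(system$J - diag(1 / ns$tau_noise, N), -B * c_ou)
  # circuit block: J C11 + C11 J^T = -(B C12^T + C12 B^T + Lm Lm^T)
  Q <- B %*% t(C12) + C12 %*% t(B) + diag(system$q0, N)
  C11 <- lyap_solve_cpp(system$J, 0.5 * (Q + t(Q)))
  if (!full) return(C11)
  rbind(cbind(C11, C12), cbind(t(C12), diag(c_ou, N)))
}

#' Residual of the Lyapunov equation (diagnostic)
#'
#' @param system A [build_stochastic_system()] result.
#' @param C_full Full augmented covariance from
#'   `stationary_covariance(system, full = TRUE)`.
#' @return Relative Frobenius residual
#'   `||J C + C J^T + L D L^T|| / ||L D L^T||`.
#' @export
lyapunov_residual <- function(system, C_full) {
  J <- as.matrix(system$J_aug)
  L <- as.matrix(system$L_aug)
  M <- L %*% t(L)
  R <- J %*% C_full + C_full %*% t(J) + M
  norm(R, "F") / norm(M, "F")
}

#' Covariance of selected channels
#'
#' @param C Covariance over circuit states.
#' @param A Channel weight matrix (e.g. from [principal_channels()]).
#' @return `A C A^T`, symmetrized.
#' @export
channel_covariance <- function(C, A) {
  out <- A %*% C %*% t(A)
  0.5 * (out + t(out))
}

#' Frequency-specific covariance
#'
#' The narrow-band filtered covariance at frequency `f_star` is proportional
#' to the real part of the cross-spectral density there; the constant
#' band-width prefactor is dropped since the subspace analytics are
#' scale-invariant.
#'
#' @param spectral A [psd()] result.
#' @param f_star Frequency in Hz; must lie on the grid (or within half a
#'   grid step).
#' @return Symmetric matrix `Re S(f_star)`.
#' @export
band_covariance <- function(spectral, f_star) {
  k <- which.min(abs(spectral$freqs - f_star))
  step <- if (length(spectral$freqs) > 1L)
    max(diff(spectral$freqs)) else Inf
  if (abs(spectral$freqs[k] - f_star) > step / 2 + 1e-9) {
    stop("`f_star` = ", f_star, " Hz is outside the frequency grid",
         call. = FALSE)
  }
  M <- Re(spectral$S[, , k])
  0.5 * (M + t(M))
}
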