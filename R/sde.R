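# Euler-Maruyama simulation: the empirical oracle for the analytic spectra
# and covariances.

#' Simulate the linearized stochastic system (Euler-Maruyama)
#'
#' Integrates `dx = J x dt + L dW` for the augmented system (deviations
#' from the fixed point), recording selected channels and accumulating the
#' empirical second moment of the circuit states. Fully reproducible given
#' `seed`.
#'
#' @param system A [build_stochastic_system()] result, or a list with
#'   elements `J_aug` and `L_aug` (any stable linear SDE, e.g. a scalar OU
#'   process for testing).
#' @param duration Duration in ms.
#' @param dt Time step in ms (should be well below the smallest time
#'   constant).
#' @param seed Integer seed for the noise stream.
#' @param record Optional channel weight matrix over the augmented states,
#'   or circuit-state indices; recorded every `record_every` steps.
#' @param record_every Recording stride in steps.
#' @param cov_idx State indices (augmented numbering) over which to
#'   accumulate the empirical covariance; defaults to all circuit states
#'   when `system` is a `stochastic_system`, else all states.
#' @param cov_thin Covariance accumulation stride in steps.
#' @param burn_in Burn-in time in ms excluded from the covariance.
#' @param x0 Initial deviation (defaults to zero).
#' @param scheme `"euler"` (default Euler-Maruyama update) or `"order2"`
#'   (weak-order-2 linear propagator; removes the O(dt) variance bias at
#'   roughly twice the cost).
#' @return List: `times`, `recorded` (channels x samples), `covariance`
#'   (second moment of `cov_idx` states), `mean`, `final_state`.
#' @export
simulate_sde <- function(system, duration, dt = 0.01, seed = 1L,
                         record = NULL, record_every = 10L,
                         cov_idx = NULL, cov_thin = 10L, burn_in = 100,
                         x0 = NULL, scheme = c("euler", "order2")) {
  scheme <- match.arg(scheme)
  J <- methods::as(methods::as(system$J_aug, "CsparseMatrix"), "generalMatrix")
  L <- methods::as(methods::as(system$L_aug, "CsparseMatrix"), "generalMatrix")
  if (scheme == "order2") {
    # weak-order-2 linear propagator: x <- (I + dt J + dt^2 J^2/2) x +
    # (I + dt J / 2) L dW, removing the O(dt) variance bias of the plain
    # Euler-Maruyama update while reusing the same stepping kernel
    L <- L + (dt / 2) * (J %*% L)
    J <- J + (dt / 2) * (J %*% J)
  }
  N <- nrow(J)
  n_steps <- as.integer(round(duration / dt))
  if (n_steps < 1L) stop("`duration` too short for `dt`", call. = FALSE)
  if (is.null(cov_idx)) {
    cov_idx <- if (inherits(system, "stochastic_system"))
      seq_len(system$n_circuit) else seq_len(N)
  }
  if (is.null(record)) {
    A <- matrix(0, 0L, N)
    record_every <- 0L
  } else if (is.matrix(record)) {
    A <- record
    if (ncol(A) == 0L) record_every <- 0L
    if (ncol(A) < N) A <- cbind(A, matrix(0, nrow(A), N - ncol(A)))
  } else {
    A <- matrix(0, length(record), N)
    A[cbind(seq_along(record), as.integer(record))] <- 1
  }
  if (is.null(x0)) x0 <- numeric(N)
  burn_steps <- as.integer(round(burn_in / dt))
  set.seed(seed)
  out <- em_simulate_cpp(J, L, x0, dt, n_steps, A,
                         as.integer(record_every), as.integer(cov_idx),
                         as.integer(cov_thin), burn_steps)
  times <- if (record_every > 0)
    dt * record_every * seq_len(ncol(out$recorded)) else numeric(0)
  list(times = times, recorded = out$recorded,
       covariance = out$moment2 - tcrossprod(out$mean), mean = out$mean,
       n_cov = out$n_cov, final_state = out$final_state)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann window and 50% overlap,
#' scaled as a two-sided density (variance per Hz) to match the analytic
#' convention of [psd()].
#'
#' @param x Numeric time series (one channel).
#' @param dt Sampling interval in ms.
#' @param n_seg Segment length in samples.
#' @return `data.frame` with `freq` (Hz) and `spec`.
#' @export
welch_psd <- function(x, dt, n_seg = 4096L) {
  n_seg <- min(n_seg, length(x))
  hop <- n_seg %/% 2L
  win <- 0.5 * (1 - cos(2 * pi * seq_len(n_seg) / (n_seg + 1)))
  norm <- sum(win^2)
  starts <- seq(1L, length(x) - n_seg + 1L, by = hop)
  acc <- numeric(n_seg)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / length(starts)
  # two-sided density in 1/Hz: multiply by dt (ms) / 1000 per sample norm
  spec <- acc * (dt / 1000) / norm
  freq <- (seq_len(n_seg) - 1L) / (n_seg * dt / 1000)
  keep <- seq_len(n_seg %/% 2L)
  data.frame(freq = freq[keep], spec = spec[keep])
}
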