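# Closed-form cross-spectral densities, coherence, normalized power and
# spectral feature extraction.

#' Cross-spectral density of selected channels
#'
#' Evaluates the resolvent formula
#' `S(omega) = A (i omega I + J)^-1 Q(omega) (-i omega I + J)^-T A^T`
#' on a frequency grid, where `Q(omega)` is the diagonal forcing spectrum of
#' the white (multiplicative) plus low-pass (synaptic) noise. The auxiliary
#' noise-filter states are folded in analytically, so only the circuit-state
#' Jacobian is inverted. Frequencies are in Hz; the returned densities are
#' two-sided (variance per Hz), so integrating `2 Re S` over positive
#' frequencies recovers the stationary covariance.
#'
#' @param system A [build_stochastic_system()] result.
#' @param freqs Frequency grid in Hz (>= 0, strictly increasing).
#' @param channels Either an integer vector of circuit-state indices or a
#'   weight matrix with one row per output channel.
#' @param channel_names Optional channel labels.
#' @return Object of class `spectral_result`: `freqs`, complex array `S`
#'   (`m x m x length(freqs)`), `channels`, and the noise metadata.
#' @export
psd <- function(system, freqs, channels, channel_names = NULL) {
  stopifnot(inherits(system, "stochastic_system"))
  if (any(freqs < 0) || is.unsorted(freqs, strictly = TRUE)) {
    stop("`freqs` must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  N <- system$n_circuit
  if (is.matrix(channels)) {
    A <- channels
    if (ncol(A) != N) stop("channel matrix must have ", N, " columns",
                           call. = FALSE)
  } else {
    A <- matrix(0, length(channels), N)
    A[cbind(seq_along(channels), as.integer(channels))] <- 1
    if (is.null(channel_names)) channel_names <- as.character(channels)
  }
  # the resolvent works in rad/ms; dividing by 1000 converts the density
  # to variance per Hz (two-sided), so that integral(2 Re S df) = C(0)
  omegas <- 2 * pi * freqs / 1000
  S <- psd_resolvent_cpp(system$J, A, system$q0, system$q1, omegas,
                         system$tau_noise) / 1000
  structure(
    list(freqs = freqs, S = S, channels = channel_names,
         noise = system$noise),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat("<spectral_result> ", dim(x$S)[1L], " channels, ",
      length(x$freqs), " frequencies (", min(x$freqs), "-", max(x$freqs),
      " Hz)\n", sep = "")
  invisible(x)
}

#' Extract one auto-spectrum from a spectral result
#'
#' @param spectral A [psd()] result.
#' @param i Channel index.
#' @return Numeric vector of power densities over `spectral$freqs`.
#' @export
auto_spectrum <- function(spectral, i = 1L) {
  Re(spectral$S[i, i, ])
}

#' Spectral coherence between two channels
#'
#' `kappa_ij(f) = |S_ij|^2 / (S_ii S_jj)`, bounded in `[0, 1]`.
#'
#' @param spectral A [psd()] result.
#' @param i,j Channel indices.
#' @return Object of class `coherence_pair`: `freqs`, `kappa`, `i`, `j`.
#' @export
coherence <- function(spectral, i, j) {
  sii <- Re(spectral$S[i, i, ])
  sjj <- Re(spectral$S[j, j, ])
  if (any(sii <= 0) || any(sjj <= 0)) {
    bad <- spectral$freqs[which(sii <= 0 | sjj <= 0)[1L]]
    stop("zero auto-spectrum at f = ", bad,
         " Hz; coherence undefined", call. = FALSE)
  }
  kappa <- Mod(spectral$S[i, j, ])^2 / (sii * sjj)
  structure(list(freqs = spectral$freqs, kappa = pmin(kappa, 1),
                 i = i, j = j),
            class = "coherence_pair")
}

#' Normalize a power spectrum against a baseline
#'
#' `(power - baseline) / (power + baseline)`, the convention in which the
#' baseline is the spontaneous spectrum at 0% contrast. Values lie in
#' `(-1, 1)` and vanish where power equals baseline.
#'
#' @param power,baseline Spectra on the same frequency grid; baseline > 0.
#' @return Numeric vector of normalized power.
#' @export
normalize_power <- function(power, baseline) {
  if (length(power) != length(baseline)) {
    stop("`power` and `baseline` are on different grids", call. = FALSE)
  }
  if (any(baseline <= 0)) stop("`baseline` must be positive", call. = FALSE)
  (power - baseline) / (power + baseline)
}

#' Locate an interior spectral peak within a band
#'
#' Finds the maximum of the spectrum restricted to `(band[1], band[2])` and
#' refines it by quadratic (3-point) interpolation. When the
#' maximum lies on the band edge (no interior peak), returns `NULL`.
#'
#' @param freqs Frequency grid, Hz.
#' @param spectrum Values on the grid (power, normalized power, coherence).
#' @param band Numeric length-2: frequency interval to search.
#' @param log_power If `TRUE` (default for positive spectra), interpolate in
#'   log power.
#' @return `list(freq, height)` or `NULL` if there is no interior peak.
#' @export
find_spectral_peak <- function(freqs, spectrum, band = c(30, 80),
                               log_power = all(spectrum > 0)) {
  sel <- which(freqs > band[1L] & freqs < band[2L])
  if (length(sel) < 3L) stop("fewer than 3 grid points in band",
                             call. = FALSE)
  k <- sel[which.max(spectrum[sel])]
  if (k == sel[1L] || k == sel[length(sel)]) return(NULL)
  y <- spectrum[(k - 1L):(k + 1L)]
  if (log_power && all(y > 0)) y <- log(y)
  denom <- y[1L] - 2 * y[2L] + y[3L]
  delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y[1L] - y[3L]) / denom
  delta <- max(-0.5, min(0.5, delta))
  f0 <- freqs[k] + delta * (freqs[k + 1L] - freqs[k])
  h <- spectrum[k] - 0.25 * (spectrum[k - 1L] - spectrum[k + 1L]) * delta
  list(freq = f0, height = h)
}

#' High-frequency power-law exponent
#'
#' Least-squares slope of log power versus log frequency over a range.
#'
#' @param freqs Frequency grid, Hz.
#' @param spectrum Positive power values.
#' @param f_range Length-2 frequency range, Hz (needs >= 10 grid points).
#' @return The fitted exponent (e.g. -4 for a `1/f^4` tail).
#' @export
highfreq_slope <- function(freqs, spectrum, f_range = c(300, 1000)) {
  sel <- which(freqs >= f_range[1L] & freqs <= f_range[2L])
  if (length(sel) < 10L) stop("need >= 10 grid points in `f_range`",
                              call. = FALSE)
  if (any(spectrum[sel] <= 0)) stop("nonpositive power in `f_range`",
                                    call. = FALSE)
  unname(stats::coef(stats::lm(log(spectrum[sel]) ~ log(freqs[sel])))[2L])
}

#' LFP spectra of the areas, including extrinsic noise
#'
#' Computes the cross-spectral matrix of the per-area LFP proxies (summed
#' principal-cell membrane potentials) and adds the extrinsic noise term: a
#' flat (white) component of density `extrinsic_amp^2` on every
#' auto-spectrum and `extrinsic_corr * extrinsic_amp^2` on every
#' cross-spectrum between areas.
#'
#' @param system A [build_stochastic_system()] result.
#' @param freqs Frequency grid, Hz.
#' @param include_extrinsic Set `FALSE` to return the bare circuit LFP
#'   spectra.
#' @return A `spectral_result` whose channels are the areas.
#' @export
lfp_spectrum <- function(system, freqs, include_extrinsic = TRUE) {
  circuit <- system$lin$circuit
  areas <- names(circuit$areas)
  A <- do.call(rbind, lapply(areas, function(a) lfp_weights(circuit, a)))
  sp <- psd(system, freqs, A, channel_names = areas)
  if (include_extrinsic) {
    ns <- system$noise
    m <- length(areas)
    ext <- matrix(ns$extrinsic_corr * ns$extrinsic_amp^2, m, m)
    diag(ext) <- ns$extrinsic_amp^2
    for (k in seq_along(freqs)) sp$S[, , k] <- sp$S[, , k] + ext
  }
  sp
}

#' Principal-cell channel matrix for spectral analyses
#'
#' Builds the weight matrix selecting the principal-cell states of the
#' given areas, optionally scaled to first-order firing-rate fluctuations
#' (`d rate = 2 |y*| d y` at the operating point), which is the signal
#' convention of the communication-subspace analyses.
#'
#' @param lin A [linearize_circuit()] result.
#' @param areas Character vector of area names (default: all).
#' @param signal `"rate"` (default) or `"membrane"`.
#' @return List with the weight matrix `A` (one row per neuron) and a
#'   `data.frame` `channels` (area, neuron).
#' @export
principal_channels <- function(lin, areas = names(lin$circuit$areas),
                               signal = c("rate", "membrane")) {
  signal <- match.arg(signal)
  circuit <- lin$circuit
  N <- n_states(circuit)
  n <- circuit$geometry$n
  rows <- list()
  info <- list()
  for (a in areas) {
    idx <- state_index(circuit, a, "y")
    w <- if (signal == "rate") {
      2 * rectify(lin$state[idx], lin$smoothing)
    } else rep(1, n)
    M <- matrix(0, n, N)
    M[cbind(seq_len(n), idx)] <- w
    rows[[a]] <- M
    info[[a]] <- data.frame(area = a, neuron = seq_len(n))
  }
  list(A = do.call(rbind, rows), channels = do.call(rbind, info))
}
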