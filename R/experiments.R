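# Scripted experiments: contrast-response functions, spectral and coherence
# sweeps, communication-subspace sweeps, and the three-area routing
# demonstration.

#' Fit a Naka-Rushton function to a contrast-response curve
#'
#' `R(c) = R_max c^n / (c50^n + c^n)`, the standard parametric form for
#' extracting the semisaturation contrast `c50` and slope exponent `n`.
#'
#' @param contrast Contrast values in percent.
#' @param rate Responses.
#' @return List with `r_max`, `c50` (percent), `n`, `rmse`.
#' @export
fit_naka_rushton <- function(contrast, rate) {
  df <- data.frame(c = contrast, r = rate)
  df <- df[df$c > 0 | df$r > 0, ]
  start <- list(rmax = max(rate), c50 = max(1, stats::median(contrast)),
                n = 2)
  fit <- minpack.lm::nlsLM(
    r ~ rmax * c^n / (c50^n + c^n), data = df, start = start,
    lower = c(rmax = 0, c50 = 1e-3, n = 0.1),
    upper = c(rmax = Inf, c50 = 500, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  list(r_max = unname(cf["rmax"]), c50 = unname(cf["c50"]),
       n = unname(cf["n"]),
       rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Contrast-response experiment
#'
#' Fixed-point firing rates over a contrast grid for every area, plus a
#' Naka-Rushton fit per area. At default parameters the higher area has a
#' lower semisaturation contrast and a steeper slope than the lower area.
#'
#' @param circuit A `circuit`.
#' @param contrasts Contrast grid, percent.
#' @param orientation Stimulus orientation, degrees.
#' @param measure `"max"` or `"mean"` neuron rate.
#' @return List: `table` (contrast_pct, area, rate), `fits` (per area).
#' @export
run_crf <- function(circuit,
                    contrasts = c(0, 1, 3, 6, 10, 12, 25, 40, 50, 75, 100),
                    orientation = 0, measure = "max") {
  tab <- contrast_response(circuit, contrasts, orientation,
                           measure = measure)
  fits <- lapply(split(tab, tab$area), function(d) {
    tryCatch(fit_naka_rushton(d$contrast_pct, d$rate),
             error = function(e) {
               warning("Naka-Rushton fit failed: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  list(table = tab, fits = fits)
}

# Linearize + spectra of the maximally driven principal neurons of the
# first two areas, plus the spontaneous baseline of the same channels.
pair_spectra <- function(circuit, contrast, freqs, noise = noise_spec(),
                         orientation = 0, frozen_gain = FALSE) {
  lin <- linearize_circuit(circuit, stimulus(contrast, orientation),
                           frozen_gain = frozen_gain)
  areas <- names(circuit$areas)[1:2]
  idx <- vapply(areas, function(a) {
    state_index(circuit, a, "y")[which.max(lin$rates[[a]])]
  }, integer(1))
  sys <- build_stochastic_system(lin, noise)
  sp <- psd(sys, freqs, idx, channel_names = areas)
  list(lin = lin, sys = sys, spectral = sp, idx = idx)
}

#' Power-spectrum sweep
#'
#' For every value of the swept variable (contrast, feedback gain `gamma`,
#' or input gain `beta`), computes the analytic power spectrum of the
#' maximally responsive principal neuron of the lower area, normalizes it
#' against the spontaneous (0% contrast) baseline of the same configuration,
#' and extracts band-restricted peaks and the high-frequency slope.
#'
#' @param circuit A `circuit` (the base configuration).
#' @param sweep `"contrast"`, `"gamma"` or `"beta"`.
#' @param values Grid of swept values (percent for contrast).
#' @param contrast Fixed contrast (percent) for gain sweeps.
#' @param freqs Frequency grid, Hz.
#' @param noise A [noise_spec()].
#' @param bands Named list of band intervals for peak extraction.
#' @return List: `spectra` (long data.frame: sweep value, freq, power,
#'   normalized), `peaks` (one row per sweep value and band),
#'   `slopes` (high-frequency exponent per sweep value).
#' @export
run_spectra_sweep <- function(circuit, sweep = c("contrast", "gamma",
                                                 "beta"),
                              values = NULL, contrast = 50,
                              freqs = seq(1, 1000, by = 1),
                              noise = noise_spec(),
                              bands = list(alpha = c(3, 20),
                                           gamma = c(30, 80),
                                           broad = c(8, 90))) {
  sweep <- match.arg(sweep)
  if (is.null(values)) {
    values <- switch(sweep,
      contrast = c(3, 6, 12, 25, 40, 50, 75, 100),
      gamma = c(0.1, 0.25, 0.5, 1.0, 1.1),
      beta = c(0.8, 1.0, 1.2, 1.5, 2.0))
  }
  rows <- peaks <- slopes <- list()
  for (v in values) {
    circ_v <- switch(sweep,
      contrast = circuit,
      gamma = set_gains(circuit, gamma = v),
      beta = set_gains(circuit, beta = v))
    cc <- if (sweep == "contrast") v else contrast
    ps <- pair_spectra(circ_v, cc, freqs, noise)
    base <- pair_spectra(circ_v, 0, freqs, noise)
    p <- auto_spectrum(ps$spectral, 1L)
    b <- auto_spectrum(base$spectral, 1L)
    np <- normalize_power(p, b)
    rows[[length(rows) + 1L]] <- data.frame(
      value = v, freq = freqs, power = p, normalized = np)
    for (bn in names(bands)) {
      pk <- find_spectral_peak(freqs, np, band = bands[[bn]],
                               log_power = FALSE)
      peaks[[length(peaks) + 1L]] <- data.frame(
        value = v, band = bn,
        peak_freq = if (is.null(pk)) NA_real_ else pk$freq,
        peak_height = if (is.null(pk)) NA_real_ else pk$height)
    }
    slopes[[length(slopes) + 1L]] <- data.frame(
      value = v, slope = highfreq_slope(freqs, p, c(300, 1000)))
  }
  list(sweep = sweep, spectra = do.call(rbind, rows),
       peaks = do.call(rbind, peaks), slopes = do.call(rbind, slopes))
}

#' Coherence sweep
#'
#' Coherence spectra between the maximally firing principal neurons of the
#' two areas, across a contrast or gain sweep, with interior-peak
#' extraction.
#'
#' @inheritParams run_spectra_sweep
#' @param peak_band Interval searched for the interior coherence peak.
#' @return List: `coherence` (long data.frame), `peaks`.
#' @export
run_coherence_sweep <- function(circuit, sweep = c("contrast", "gamma",
                                                   "beta"),
                                values = NULL, contrast = 50,
                                freqs = seq(1, 200, by = 1),
                                noise = noise_spec(),
                                peak_band = c(10, 120)) {
  sweep <- match.arg(sweep)
  if (is.null(values)) {
    values <- switch(sweep,
      contrast = c(3, 6, 12, 25, 40, 50, 75, 100),
      gamma = c(0.1, 0.25, 0.5, 1.0, 1.1),
      beta = c(0.8, 1.0, 1.2, 1.5, 2.0))
  }
  rows <- peaks <- list()
  for (v in values) {
    circ_v <- switch(sweep,
      contrast = circuit,
      gamma = set_gains(circuit, gamma = v),
      beta = set_gains(circuit, beta = v))
    cc <- if (sweep == "contrast") v else contrast
    ps <- pair_spectra(circ_v, cc, freqs, noise)
    co <- coherence(ps$spectral, 1L, 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      value = v, freq = freqs, kappa = co$kappa)
    pk <- find_spectral_peak(freqs, co$kappa, band = peak_band,
                             log_power = FALSE)
    peaks[[length(peaks) + 1L]] <- data.frame(
      value = v,
      peak_freq = if (is.null(pk)) NA_real_ else pk$freq,
      peak_height = if (is.null(pk)) NA_real_ else pk$height)
  }
  list(sweep = sweep, coherence = do.call(rbind, rows),
       peaks = do.call(rbind, peaks))
}

#' Communication-subspace experiment for a circuit condition
#'
#' Computes the stationary covariance of the firing-rate fluctuations of
#' the principal cells and runs the subset-averaged subspace analysis for
#' an inter-areal and a within-area population pair.
#'
#' @param circuit A `circuit`.
#' @param contrast Contrast, percent.
#' @param noise A [noise_spec()].
#' @param source_area,target_area Area names; equal names select the
#'   disjoint within-area protocol.
#' @param subset_size,n_repeats,seed Subset protocol.
#' @param signal `"rate"` or `"membrane"` fluctuations.
#' @return The [subset_averaged_performance()] list, plus `covariance` and
#'   channel bookkeeping in attributes.
#' @export
run_subspace <- function(circuit, contrast = 100, noise = noise_spec(),
                         source_area = "V1", target_area = "V2",
                         subset_size = 30L, n_repeats = 25L, seed = 1L,
                         signal = "rate") {
  lin <- linearize_circuit(circuit, stimulus(contrast, 0))
  sys <- build_stochastic_system(lin, noise)
  C <- stationary_covariance(sys)
  ch <- principal_channels(lin, signal = signal)
  Cr <- channel_covariance(C, ch$A)
  src <- which(ch$channels$area == source_area)
  tgt <- which(ch$channels$area == target_area)
  res <- subset_averaged_performance(Cr, src, tgt,
                                     subset_size = subset_size,
                                     n_repeats = n_repeats, seed = seed)
  attr(res, "covariance") <- Cr
  attr(res, "channels") <- ch$channels
  res
}

#' Frequency-resolved communication experiment
#'
#' @param circuit A `circuit`.
#' @param contrast Contrast, percent.
#' @param freqs Analysis frequency grid, Hz.
#' @param noise A [noise_spec()].
#' @param source_area,target_area Area names.
#' @param subset_size,n_repeats,seed Subset protocol.
#' @return `data.frame` from [frequency_resolved_communication()].
#' @export
run_frequency_communication <- function(circuit, contrast = 50,
                                        freqs = seq(2, 100, by = 2),
                                        noise = noise_spec(),
                                        source_area = "V1",
                                        target_area = "V2",
                                        subset_size = 30L,
                                        n_repeats = 25L, seed = 1L) {
  lin <- linearize_circuit(circuit, stimulus(contrast, 0))
  sys <- build_stochastic_system(lin, noise)
  ch <- principal_channels(lin, areas = unique(c(source_area, target_area)))
  sp <- psd(sys, freqs, ch$A)
  src <- which(ch$channels$area == source_area)
  tgt <- which(ch$channels$area == target_area)
  frequency_resolved_communication(sp, src, tgt, subset_size = subset_size,
                                   n_repeats = n_repeats, seed = seed)
}

#' Three-area functional-connectivity experiment
#'
#' Builds the V1-V4/V5 hierarchy with identical higher-area parameters and
#' compares V1 -> V4 against V1 -> V5 communication under the two feedback
#' gains. Stronger feedback from one higher area routes V1's communication
#' toward that area; equal gains give identical performance by symmetry.
#'
#' @param gamma_v4,gamma_v5 Feedback gains of the two edges.
#' @param contrast Contrast, percent.
#' @param noise A [noise_spec()].
#' @param subset_size,n_repeats,seed Subset protocol.
#' @param ... Passed to [three_area_circuit()].
#' @return List with the two [subset_averaged_performance()] results
#'   (`v1_to_v4`, `v1_to_v5`) and the gains used.
#' @export
run_three_area <- function(gamma_v4 = 0.5, gamma_v5 = 1.0, contrast = 100,
                           noise = noise_spec(), subset_size = 30L,
                           n_repeats = 25L, seed = 1L, ...) {
  circuit <- three_area_circuit(gamma_v4 = gamma_v4, gamma_v5 = gamma_v5,
                                ...)
  lin <- linearize_circuit(circuit, stimulus(contrast, 0))
  sys <- build_stochastic_system(lin, noise)
  C <- stationary_covariance(sys)
  ch <- principal_channels(lin)
  Cr <- channel_covariance(C, ch$A)
  src <- which(ch$channels$area == "V1")
  res <- lapply(c(v1_to_v4 = "V4", v1_to_v5 = "V5"), function(a) {
    tgt <- which(ch$channels$area == a)
    subset_averaged_performance(Cr, src, tgt, subset_size = subset_size,
                                n_repeats = n_repeats, seed = seed)
  })
  c(res, list(gamma_v4 = gamma_v4, gamma_v5 = gamma_v5))
}
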