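# YAML configuration: one nested list describing circuit, noise and
# experiment settings, with the package defaults shipped in
# inst/extdata/default_config.yaml.

#' Default configuration
#'
#' @return Nested list with `circuit`, `noise` and `experiment` settings,
#'   read from the YAML shipped with the package.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "normcircuit", mustWork = TRUE))
}

#' Load a configuration file
#'
#' @param path Path to a YAML (or JSON) configuration.
#' @return Nested configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg), !is.null(cfg$circuit))
  cfg
}

#' Build a circuit from a configuration
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param topology `"two_area"` or `"three_area"`.
#' @return A `circuit`.
#' @export
circuit_from_config <- function(cfg, topology = c("two_area",
                                                  "three_area")) {
  topology <- match.arg(topology)
  cc <- cfg$circuit
  params <- area_parameters(
    tau_y = cc$tau_y, tau_u = cc$tau_u, tau_a = cc$tau_a, tau_q = cc$tau_q,
    alpha = cc$alpha, sigma = cc$sigma)
  common <- list(
    n_neurons = cc$n_neurons, beta = cc$beta, params = params,
    half_width = cc$half_width, excit_width = cc$excit_width,
    inhib_width = cc$inhib_width, inhib_strength = cc$inhib_strength,
    feedback_width = cc$feedback_width, diag_boost = cc$diag_boost,
    pool_gain = cc$pool_gain,
    identity_recurrent = isTRUE(cc$identity_recurrent))
  if (topology == "two_area") {
    do.call(two_area_circuit, c(common, list(gamma = cc$gamma)))
  } else {
    do.call(three_area_circuit,
            c(common, list(gamma_v4 = cc$gamma_v4 %||% cc$gamma,
                           gamma_v5 = cc$gamma_v5 %||% cc$gamma)))
  }
}

#' Build a noise specification from a configuration
#'
#' @param cfg Configuration list.
#' @return A [noise_spec()].
#' @export
noise_from_config <- function(cfg) {
  ns <- cfg$noise
  noise_spec(synaptic_amp = ns$synaptic_amp, tau_noise = ns$tau_noise,
             mult_amp = ns$mult_amp, extrinsic_amp = ns$extrinsic_amp,
             extrinsic_corr = ns$extrinsic_corr)
}
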