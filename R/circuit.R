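# Circuit specification: areas, parameters, gains, hierarchy topology.

TABLE_RANGES <- list(
  gamma = c(0, 1.1),
  beta  = c(0, 2.5),
  alpha = c(7.5, 50),
  sigma = c(0.035, 0.14)
)

range_warn <- function(value, name) {
  r <- TABLE_RANGES[[name]]
  if (!is.null(r) && (any(value < r[1L]) || any(value > r[2L]))) {
    warning(sprintf("%s = %s is outside the tested stability range [%g, %g]",
                    name, paste(format(value), collapse = ", "), r[1L], r[2L]),
            call. = FALSE)
  }
  invisible(value)
}

#' Per-area intrinsic parameters
#'
#' Time constants of the four cell types, the derivative-coupling coefficient
#' of the recurrent-gain dynamics, and the semisaturation constant of the
#' normalization. Defaults are the model's baseline values (all time
#' constants 1 ms, `alpha` = 10, `sigma` = 0.07). Values outside the tested
#' stability ranges trigger a warning, not an error.
#'
#' @param tau_y,tau_u,tau_a,tau_q Membrane time constants in ms (> 0).
#' @param alpha Dimensionless coupling of `du/dt` into the recurrent-gain
#'   dynamics.
#' @param sigma Semisaturation constant (dimensionless, > 0). With the
#'   default pool scaling, `sigma` equals the contrast (as a fraction) at
#'   which the peak firing rate reaches half its maximum.
#' @return An object of class `area_parameters`.
#' @export
area_parameters <- function(tau_y = 1, tau_u = 1, tau_a = 1, tau_q = 1,
                            alpha = 10, sigma = 0.07) {
  taus <- c(tau_y = tau_y, tau_u = tau_u, tau_a = tau_a, tau_q = tau_q)
  if (any(taus <= 0)) stop("all time constants must be > 0", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  range_warn(alpha, "alpha")
  range_warn(sigma, "sigma")
  structure(list(tau_y = tau_y, tau_u = tau_u, tau_a = tau_a, tau_q = tau_q,
                 alpha = alpha, sigma = sigma),
            class = "area_parameters")
}

# Fraction of the feedback drive routed to the inhibitory gain population,
# and of the input drive routed to the modulatory excitatory population.
# Fixed constants of the model (both 0.50); they appear as the factors of
# one half in the circuit equations.
INHIBITORY_FEEDBACK_FRACTION <- 0.5
MODULATORY_INPUT_FRACTION <- 0.5

#' Two-area reciprocally connected circuit (V1 - V2)
#'
#' Builds the default hierarchy: two ring areas with center-surround
#' recurrent connectivity, a diagonally dominant feedback matrix from the
#' higher to the lower area, and a feedforward matrix equal to its transpose.
#' The lower area receives the stimulus drive; the higher area receives the
#' feedforward drive and sends feedback scaled by the feedback gain `gamma`.
#'
#' The all-ones normalization pool is scaled by the inverse squared norm of
#' the population tuning response, so that the normalization denominator at
#' contrast `c` (fraction) is exactly `sigma^2 + c^2` in the balanced
#' configuration.
#'
#' @param n_neurons Neurons per cell type per area.
#' @param gamma Feedback gain (higher -> lower area).
#' @param beta Input gain, scalar shared by the areas or length-2 vector.
#' @param params An [area_parameters()] object shared by both areas.
#' @param half_width Tuning-curve half-width, degrees.
#' @param excit_width,inhib_width,inhib_strength Recurrent-kernel parameters,
#'   see [build_recurrent_weights()].
#' @param feedback_width,diag_boost Feedback-kernel parameters, see
#'   [build_feedback_weights()].
#' @param pool_gain Dimensionless strength of the normalization pool
#'   (default 1.3; see Details in the methods vignette).
#' @param identity_recurrent If `TRUE`, replace the recurrent matrices by the
#'   identity (the configuration for which the fixed point follows the
#'   normalization equation exactly).
#' @return An object of class `circuit`.
#' @export
two_area_circuit <- function(n_neurons = 72L, gamma = 1, beta = 1,
                             params = area_parameters(),
                             half_width = 30,
                             excit_width = 3, inhib_width = 30,
                             inhib_strength = 0.003,
                             feedback_width = 15, diag_boost = 2,
                             pool_gain = 1.3,
                             identity_recurrent = FALSE) {
  geom <- ring_geometry(n_neurons)
  range_warn(gamma, "gamma")
  range_warn(beta, "beta")
  if (any(c(gamma, beta) < 0)) stop("gains must be >= 0", call. = FALSE)
  beta <- rep_len(beta, 2L)
  w_r <- if (identity_recurrent) diag(geom$n) else
    build_recurrent_weights(geom, excit_width, inhib_width, inhib_strength)
  w_fb <- build_feedback_weights(geom, feedback_width, diag_boost)
  areas <- list(
    V1 = list(name = "V1", params = params, beta = beta[1L], W_r = w_r),
    V2 = list(name = "V2", params = params, beta = beta[2L], W_r = w_r)
  )
  edges <- list(list(lower = "V1", higher = "V2", W_fb = w_fb, gamma = gamma))
  new_circuit(geom, half_width, areas, edges, pool_gain)
}

#' Three-area circuit (V1 reciprocally connected with V4 and V5)
#'
#' V1 has reciprocal connections with two higher areas that have identical
#' recurrent, feedforward and feedback connectivity and identical intrinsic
#' parameters; there is no direct connection between the two higher areas.
#' Only the two feedback gains differ, which isolates feedback strength as
#' the variable controlling functional connectivity.
#'
#' @param gamma_v4,gamma_v5 Feedback gains of the V4 -> V1 and V5 -> V1
#'   edges.
#' @inheritParams two_area_circuit
#' @return An object of class `circuit` with areas V1, V4, V5.
#' @export
three_area_circuit <- function(n_neurons = 72L, gamma_v4 = 1, gamma_v5 = 1,
                               beta = 1, params = area_parameters(),
                               half_width = 30,
                               excit_width = 3, inhib_width = 30,
                               inhib_strength = 0.003,
                               feedback_width = 15, diag_boost = 2,
                               pool_gain = 1.3,
                               identity_recurrent = FALSE) {
  geom <- ring_geometry(n_neurons)
  range_warn(c(gamma_v4, gamma_v5), "gamma")
  range_warn(beta, "beta")
  if (any(c(gamma_v4, gamma_v5, beta) < 0)) {
    stop("gains must be >= 0", call. = FALSE)
  }
  beta <- rep_len(beta, 3L)
  w_r <- if (identity_recurrent) diag(geom$n) else
    build_recurrent_weights(geom, excit_width, inhib_width, inhib_strength)
  w_fb <- build_feedback_weights(geom, feedback_width, diag_boost)
  areas <- list(
    V1 = list(name = "V1", params = params, beta = beta[1L], W_r = w_r),
    V4 = list(name = "V4", params = params, beta = beta[2L], W_r = w_r),
    V5 = list(name = "V5", params = params, beta = beta[3L], W_r = w_r)
  )
  edges <- list(
    list(lower = "V1", higher = "V4", W_fb = w_fb, gamma = gamma_v4),
    list(lower = "V1", higher = "V5", W_fb = w_fb, gamma = gamma_v5)
  )
  new_circuit(geom, half_width, areas, edges, pool_gain)
}

new_circuit <- function(geometry, half_width, areas, edges, pool_gain = 1.3) {
  # The all-ones normalization pool is scaled by pool_gain / (squared norm of
  # the population response to a full-contrast stimulus). The norm is a
  # rotation-invariant constant of the geometry (averaged over a ring period
  # to remove the sub-grid dependence); pool_gain sets how strongly the pool
  # saturates the drive and thereby the operating point of the resonances.
  probe <- seq(0, 180 / geometry$n, length.out = 8L)
  pool <- mean(vapply(
    probe,
    function(th) sum(tuning_at(geometry, th, half_width)^2),
    numeric(1)
  ))
  structure(
    list(geometry = geometry, half_width = half_width, areas = areas,
         edges = edges, pool_scale = pool_gain / pool,
         input_area = names(areas)[1L]),
    class = "circuit"
  )
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", length(x$areas), " areas (",
      paste(names(x$areas), collapse = ", "), "), ",
      x$geometry$n, " neurons per cell type\n", sep = "")
  for (e in x$edges) {
    cat("  ", e$lower, " <-> ", e$higher, "  gamma = ", format(e$gamma),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of circuit states (four cell types per area)
#' @param circuit A `circuit`.
#' @return Integer count of deterministic states.
#' @export
n_states <- function(circuit) {
  4L * circuit$geometry$n * length(circuit$areas)
}

# Index of a cell-type block in the packed state vector.
# Per-area layout: y, u, a, q, each of length n; areas in list order.
state_index <- function(circuit, area, type = c("y", "u", "a", "q")) {
  type <- match.arg(type)
  n <- circuit$geometry$n
  k <- match(area, names(circuit$areas))
  if (is.na(k)) stop("unknown area `", area, "`", call. = FALSE)
  offset <- (k - 1L) * 4L * n + (match(type, c("y", "u", "a", "q")) - 1L) * n
  offset + seq_len(n)
}

#' Indices of the principal-cell (y) states of an area
#' @param circuit A `circuit`.
#' @param area Area name (e.g. `"V1"`).
#' @return Integer vector of state indices.
#' @export
principal_index <- function(circuit, area) {
  state_index(circuit, area, "y")
}

#' Update the gains of a circuit
#'
#' Returns a copy of the circuit with new feedback and/or input gains;
#' connectivity and parameters are untouched.
#'
#' @param circuit A `circuit`.
#' @param gamma Feedback gain(s), recycled over the feedback edges
#'   (`NULL` to keep).
#' @param beta Input gain(s), recycled over the areas (`NULL` to keep).
#' @return The modified `circuit`.
#' @export
set_gains <- function(circuit, gamma = NULL, beta = NULL) {
  if (!is.null(gamma)) {
    range_warn(gamma, "gamma")
    gamma <- rep_len(gamma, length(circuit$edges))
    for (i in seq_along(circuit$edges)) circuit$edges[[i]]$gamma <- gamma[i]
  }
  if (!is.null(beta)) {
    range_warn(beta, "beta")
    beta <- rep_len(beta, length(circuit$areas))
    for (i in seq_along(circuit$areas)) circuit$areas[[i]]$beta <- beta[i]
  }
  circuit
}

`%||%` <- function(x, y) if (is.null(x)) y else x
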