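#' Ring geometry for an orientation-tuned cortical area
#'
#' Principal neurons (and the three modulator populations that share their
#' geometry) are arranged on a ring representing preferred orientation.
#' Orientation is 180-degree periodic (orientation, not direction), so the
#' circular distance between two orientations is computed with the 180-degree
#' wrap.
#'
#' @param n_neurons Number of neurons per cell type per area (>= 4).
#' @return An object of class `ring_geometry` with elements `n` and
#'   `orientations` (preferred orientations in degrees, equally spaced on
#'   `[0, 180)`).
#' @export
ring_geometry <- function(n_neurons = 72L) {
  n <- as.integer(n_neurons)
  if (is.na(n) || n < 4L) {
    stop("`n_neurons` must be an integer >= 4", call. = FALSE)
  }
  structure(
    list(n = n, orientations = seq(0, 180, length.out = n + 1L)[seq_len(n)]),
    class = "ring_geometry"
  )
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat("<ring_geometry> ", x$n, " neurons, spacing ",
      format(180 / x$n), " deg\n", sep = "")
  invisible(x)
}

#' Circular distance between orientations (180-degree wrap)
#'
#' @param a,b Orientations in degrees (vectors recycle).
#' @return Absolute circular distance in degrees, in `[0, 90]`.
#' @export
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Stimulus description
#'
#' @param contrast Contrast in percent, `[0, 100]` (values above 100 are
#'   allowed but unusual).
#' @param orientation Orientation in degrees; reduced mod 180.
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(contrast = 50, orientation = 0) {
  if (!is.numeric(contrast) || length(contrast) != 1L || is.na(contrast) ||
      contrast < 0) {
    stop("`contrast` must be a single nonnegative number (percent)",
         call. = FALSE)
  }
  structure(
    list(contrast = contrast, orientation = orientation %% 180),
    class = "stimulus"
  )
}

#' Raised-cosine orientation tuning curves
#'
#' Each row of the returned encoding matrix is the tuning curve of one
#' neuron: a raised cosine `cos^2(pi * d / (2 * half_width))` of the circular
#' orientation distance `d` to the neuron's preferred orientation, equal to 1
#' at the peak and 0 outside the half-width support. Rows are circular shifts
#' of one another.
#'
#' @param geometry A [ring_geometry()].
#' @param half_width Half-width of the tuning-curve support in degrees,
#'   in `(0, 90)`.
#' @param eval_orientations Orientations (degrees) at which to evaluate the
#'   curves; defaults to the preferred orientations themselves, giving the
#'   square encoding matrix used for the circuit.
#' @return Matrix with one row per neuron and one column per evaluation
#'   orientation.
#' @export
build_tuning_curves <- function(geometry, half_width = 30,
                                eval_orientations = geometry$orientations) {
  stopifnot(inherits(geometry, "ring_geometry"))
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      is.na(half_width) || half_width <= 0 || half_width >= 90) {
    stop("`half_width` must lie in (0, 90) degrees", call. = FALSE)
  }
  d <- outer(geometry$orientations, eval_orientations, orientation_distance)
  w <- ifelse(d < half_width, cos(pi * d / (2 * half_width))^2, 0)
  dimnames(w) <- NULL
  w
}

#' Evaluate the raised-cosine tuning of every neuron at one orientation
#' @noRd
tuning_at <- function(geometry, orientation, half_width) {
  d <- orientation_distance(geometry$orientations, orientation)
  ifelse(d < half_width, cos(pi * d / (2 * half_width))^2, 0)
}

#' Stimulus-to-input-drive mapping
#'
#' The idealized LGN stage is collapsed: the drive to principal neuron `i` is
#' `(contrast / 100) * tuning_i(orientation)`, i.e. the stimulus convolved
#' with the tuning curves at unit amplitude, scaled linearly by contrast.
#'
#' @param stim A [stimulus()].
#' @param geometry A [ring_geometry()].
#' @param half_width Tuning-curve half-width in degrees.
#' @return Nonnegative numeric vector of length `geometry$n`.
#' @export
input_drive <- function(stim, geometry, half_width = 30) {
  stopifnot(inherits(stim, "stimulus"), inherits(geometry, "ring_geometry"))
  (stim$contrast / 100) * tuning_at(geometry, stim$orientation, half_width)
}
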