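# Connectivity builders: all matrices on the ring are circulant, built from a
# kernel of circular orientation distance. Builders are deterministic.

#' Circulant matrix from a distance kernel on the ring
#' @noRd
circulant_from_kernel <- function(geometry, kernel_fun) {
  d <- outer(geometry$orientations, geometry$orientations,
             orientation_distance)
  k <- kernel_fun(d)
  dimnames(k) <- NULL
  k
}

#' Center-surround recurrent weight matrix
#'
#' Difference of two circular Gaussians of the orientation distance: a narrow
#' excitatory center minus a broad inhibitory surround, so the closest
#' recurrent connections are excitatory and the more distant ones inhibitory.
#' After construction the matrix is rescaled so that its largest-magnitude
#' eigenvalue (spectral radius) is exactly 1, the stability convention used
#' throughout.
#'
#' @param geometry A [ring_geometry()].
#' @param excit_width Standard deviation of the excitatory center, degrees.
#' @param inhib_width Standard deviation of the inhibitory surround, degrees;
#'   must exceed `excit_width`.
#' @param inhib_strength Amplitude of the surround relative to the center
#'   (dimensionless, >= 0). The default leaves the most distant weights
#'   negative.
#' @return Circulant `n x n` matrix with unit spectral radius, positive
#'   diagonal and nonpositive entries at maximal ring distance.
#' @export
build_recurrent_weights <- function(geometry, excit_width = 20,
                                    inhib_width = 60,
                                    inhib_strength = 0.5) {
  stopifnot(inherits(geometry, "ring_geometry"))
  if (!(excit_width > 0 && inhib_width > excit_width)) {
    stop("need 0 < excit_width < inhib_width", call. = FALSE)
  }
  if (inhib_strength < 0) stop("`inhib_strength` must be >= 0", call. = FALSE)
  w <- circulant_from_kernel(geometry, function(d) {
    exp(-d^2 / (2 * excit_width^2)) -
      inhib_strength * exp(-d^2 / (2 * inhib_width^2))
  })
  if (all(w <= 0)) {
    stop("recurrent kernel is nonpositive everywhere; ",
         "reduce `inhib_strength` or widen the center", call. = FALSE)
  }
  # circulant: eigenvalues are the DFT of the first row
  rho <- max(Mod(stats::fft(w[1L, ])))
  w / rho
}

#' Inter-areal feedback weight matrix
#'
#' Circular Gaussian kernel of the orientation distance, with the diagonal
#' set to `diag_boost` times the off-diagonal row mass, then normalized so
#' every row sums to 1. The result is symmetric, nonnegative, circulant and
#' row-wise diagonally dominant for any `diag_boost > 1`. The feedforward
#' matrix is the transpose and, by symmetry, identical.
#'
#' @param geometry A [ring_geometry()].
#' @param width Standard deviation of the Gaussian kernel, degrees.
#' @param diag_boost Ratio of the diagonal entry to the summed off-diagonal
#'   entries of each row; must be > 1 for diagonal dominance (default 2).
#' @return Circulant symmetric nonnegative `n x n` matrix, rows summing to 1.
#' @export
build_feedback_weights <- function(geometry, width = 15, diag_boost = 2) {
  stopifnot(inherits(geometry, "ring_geometry"))
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (diag_boost < 1) stop("`diag_boost` must be >= 1", call. = FALSE)
  w <- circulant_from_kernel(geometry, function(d) exp(-d^2 / (2 * width^2)))
  diag(w) <- 0
  off_mass <- sum(w[1L, ])
  diag(w) <- diag_boost * off_mass
  w <- w / (off_mass * (1 + diag_boost))
  bad <- which(2 * diag(w) <= rowSums(w))
  if (length(bad) > 0L) {
    stop("feedback matrix is not diagonally dominant in row ", bad[1L],
         call. = FALSE)
  }
  w
}

#' Validate the structural invariants of a set of connectivity matrices
#'
#' Checks unit spectral radius of recurrent matrices, symmetry/nonnegativity/
#' diagonal dominance of feedback matrices, and that feedforward weights are
#' the transpose of the feedback weights.
#'
#' @param recurrent List of recurrent matrices.
#' @param feedback List of feedback matrices.
#' @param tol Tolerance on the spectral radius (default 1e-10).
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_connectivity <- function(recurrent, feedback, tol = 1e-10) {
  for (w in recurrent) {
    rho <- max(Mod(eigen(w, only.values = TRUE)$values))
    if (abs(rho - 1) > tol) {
      stop("recurrent matrix spectral radius deviates from 1 by ",
           format(abs(rho - 1)), call. = FALSE)
    }
  }
  for (w in feedback) {
    if (any(w < 0)) stop("feedback matrix has negative entries", call. = FALSE)
    if (max(abs(w - t(w))) > 1e-12) {
      stop("feedback matrix is not symmetric", call. = FALSE)
    }
    if (any(2 * diag(w) <= rowSums(w))) {
      stop("feedback matrix is not diagonally dominant", call. = FALSE)
    }
  }
  invisible(TRUE)
}
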