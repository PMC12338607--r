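# Four-population circuit dynamics, normalization fixed point, Jacobian.
#
# Per area (n neurons each of principal y, modulatory excitatory u, and
# modulatory inhibitory a and q), with drive z from below and rates r+ from
# above:
#
#   tau_y dy/dt = -y + (beta/2) z + 1/(1+|a|) * ( W_r |y| + G * |q| )
#   tau_u du/dt = -u + sigma^2/2 + N (y+ * |u|)
#   tau_a da/dt = -a + H + uhat + a * uhat + alpha du/dt
#   tau_q dq/dt = -q + |y|
#
# where |v| is (smoothed) rectification, y+ = |y|^2 is the firing rate,
# uhat = sqrt(|u|/2), N is the scaled all-ones normalization pool,
# G = sum_e (gamma_e/2) W_fb,e y_higher+ is the gain-scaled feedback drive
# (gated by the q-interneuron signal in the principal-cell equation), and
# H = sum_e (1/2) W_fb,e y_higher+ is the fixed half-strength feedback onto
# the inhibitory gain population. With beta = gamma = 1 and W_r = I the fixed
# point satisfies the normalization equation y+ = z^2 / (sigma^2 + N z^2)
# exactly (see the methods vignette for the derivation).

#' Firing-rate nonlinearity (rectification followed by squaring)
#'
#' For `smoothing = 0` this is the hard rectify-then-square rate function
#' `max(v, 0)^2`. For `smoothing > 0` the rectification is replaced by its
#' Gaussian-smoothed counterpart (a Gaussian-rectification response), which
#' is everywhere differentiable and converges to the hard form as the
#' smoothing width shrinks.
#'
#' @param v Membrane potential vector.
#' @param smoothing Gaussian smoothing width (state units, >= 0).
#' @return Nonnegative firing-rate vector of the same length.
#' @export
rate_nonlinearity <- function(v, smoothing = 0) {
  if (smoothing < 0) stop("`smoothing` must be >= 0", call. = FALSE)
  rectify(v, smoothing)^2
}

# Gaussian-smoothed rectification |v| and its derivative (a probit step)
rectify <- function(v, smoothing = 0) {
  if (smoothing == 0) return(pmax(v, 0))
  x <- v / smoothing
  v * stats::pnorm(x) + smoothing * stats::dnorm(x)
}

rectify_deriv <- function(v, smoothing = 0) {
  if (smoothing == 0) return(as.numeric(v > 0))
  stats::pnorm(v / smoothing)
}

# u-cell output signal sqrt(|u|/2) with a floor that keeps the Jacobian
# finite if u is driven to zero
uhat_fun <- function(ru) sqrt(pmax(ru, 1e-12) / 2)

# Per-area decomposition of the packed state vector
unpack_state <- function(circuit, state) {
  n <- circuit$geometry$n
  out <- list()
  for (nm in names(circuit$areas)) {
    out[[nm]] <- list(
      y = state[state_index(circuit, nm, "y")],
      u = state[state_index(circuit, nm, "u")],
      a = state[state_index(circuit, nm, "a")],
      q = state[state_index(circuit, nm, "q")]
    )
  }
  out
}

pack_state <- function(blocks) {
  unlist(lapply(blocks, function(b) c(b$y, b$u, b$a, b$q)), use.names = FALSE)
}

# Feedforward drive (before the beta/2 input gain) of every area:
# the stimulus drive for the input area, W_ff y_lower+ above it
area_drives <- function(circuit, drive, rates_y) {
  z <- stats::setNames(vector("list", length(circuit$areas)),
                       names(circuit$areas))
  z[[circuit$input_area]] <- drive
  for (e in circuit$edges) {
    ff <- t(e$W_fb) %*% rates_y[[e$lower]]   # W_ff = t(W_fb)
    z[[e$higher]] <- if (is.null(z[[e$higher]])) as.numeric(ff) else
      z[[e$higher]] + as.numeric(ff)
  }
  z
}

#' Time-derivative of the circuit state
#'
#' Evaluates the right-hand side of the circuit equations for all areas.
#' The top area(s) of the hierarchy receive no feedback drive.
#'
#' @param circuit A `circuit`.
#' @param state Packed state vector (see [initial_state()] for the layout).
#' @param drive Input-drive vector for the input area (length `n`), e.g.
#'   from [input_drive()].
#' @param smoothing Rectification smoothing width (0 = hard).
#' @return Numeric vector `d state / dt` (per ms).
#' @export
circuit_rhs <- function(circuit, state, drive, smoothing = 0) {
  n <- circuit$geometry$n
  if (length(state) != n_states(circuit)) {
    stop("state has length ", length(state), ", expected ",
         n_states(circuit), call. = FALSE)
  }
  if (length(drive) != n) {
    stop("drive has length ", length(drive), ", expected ", n, call. = FALSE)
  }
  s <- unpack_state(circuit, state)
  ry <- lapply(s, function(b) rectify(b$y, smoothing))
  rates_y <- lapply(ry, function(r) r^2)
  z <- area_drives(circuit, drive, rates_y)
  gate_q <- identical(circuit$fb_gate %||% "q", "q")
  deriv_uhat <- identical(circuit$a_deriv %||% "duhat", "duhat")
  w_in <- circuit$u_input_mix %||% 0

  # feedback pools per lower area
  G <- H <- stats::setNames(rep(list(0), length(circuit$areas)),
                            names(circuit$areas))
  for (e in circuit$edges) {
    p <- as.numeric(e$W_fb %*% rates_y[[e$higher]])
    G[[e$lower]] <- G[[e$lower]] + (e$gamma / 2) * p
    H[[e$lower]] <- H[[e$lower]] + 0.5 * p
  }

  d <- list()
  for (nm in names(circuit$areas)) {
    ar <- circuit$areas[[nm]]
    p <- ar$params
    b <- s[[nm]]
    ru <- rectify(b$u, smoothing)
    ra <- rectify(b$a, smoothing)
    rq <- if (gate_q) rectify(b$q, smoothing) else ry[[nm]]
    uh <- uhat_fun(ru)
    gain <- 1 / (1 + ra)
    drive_term <- (ar$beta / 2) * z[[nm]]
    recur <- as.numeric(ar$W_r %*% ry[[nm]]) + G[[nm]] * rq
    dy <- (-b$y + drive_term + gain * recur) / p$tau_y
    du <- (-b$u + p$sigma^2 / 2 +
             (1 - w_in) * circuit$pool_scale * sum(rates_y[[nm]] * ru) +
             (w_in / 2) * circuit$pool_scale * sum(z[[nm]]^2)) / p$tau_u
    dcoup <- if (deriv_uhat) du / (4 * uh) else du
    da <- (-b$a + H[[nm]] + uh + b$a * uh + p$alpha * dcoup) / p$tau_a
    dq <- (-b$q + ry[[nm]]) / p$tau_q
    d[[nm]] <- list(y = dy, u = du, a = da, q = dq)
  }
  pack_state(d)
}

#' Analytic balanced fixed point (the normalization solution)
#'
#' Computes, area by area up the hierarchy, the steady state implied by the
#' normalization equation `y+ = z^2 / (sigma^2 + N z^2)` together with the
#' steady-state relations of the modulator populations. This is the exact
#' fixed point when all `beta` and `gamma` are 1 and the recurrent matrices
#' are the identity; otherwise it serves as the Newton seed.
#' @noRd
analytic_fixed_point <- function(circuit, drive) {
  nm_areas <- names(circuit$areas)
  y <- u <- q <- ssat <- stats::setNames(vector("list", length(nm_areas)),
                                         nm_areas)
  rates <- list()
  z <- stats::setNames(vector("list", length(nm_areas)), nm_areas)
  z[[circuit$input_area]] <- drive
  # bottom-up: y, u, q (areas are listed bottom-up by construction)
  for (nm in nm_areas) {
    p <- circuit$areas[[nm]]$params
    for (e in circuit$edges) {
      if (e$higher == nm) {
        ff <- as.numeric(t(e$W_fb) %*% rates[[e$lower]])
        z[[nm]] <- if (is.null(z[[nm]])) ff else z[[nm]] + ff
      }
    }
    s2 <- p$sigma^2 + circuit$pool_scale * sum(z[[nm]]^2)
    y[[nm]] <- z[[nm]] / sqrt(s2)
    rates[[nm]] <- y[[nm]]^2
    u[[nm]] <- s2 / 2
    q[[nm]] <- y[[nm]]
    ssat[[nm]] <- s2
  }
  # gain population needs the higher-area rates
  a <- stats::setNames(vector("list", length(nm_areas)), nm_areas)
  for (nm in nm_areas) {
    x <- sqrt(ssat[[nm]]) / 2
    h <- 0
    for (e in circuit$edges) {
      if (e$lower == nm) h <- h + 0.5 * as.numeric(e$W_fb %*% rates[[e$higher]])
    }
    a[[nm]] <- rep_len((x + h) / (1 - x), circuit$geometry$n)
  }
  blocks <- lapply(nm_areas, function(nm) {
    list(y = y[[nm]], u = rep(u[[nm]], circuit$geometry$n), a = a[[nm]],
         q = q[[nm]])
  })
  names(blocks) <- nm_areas
  list(state = pack_state(blocks), rates = rates, ssat = ssat, z = z)
}

#' Solve for the circuit fixed point
#'
#' Starts from the analytic normalization solution. If that point is not
#' already a root of the hard-rectification right-hand side (it is exact
#' only in the balanced identity-recurrence configuration), it is refined by
#' damped Newton iteration using the analytic Jacobian. Local stability is
#' always assessed and reported via the `stable` attribute.
#'
#' @param circuit A `circuit`.
#' @param drive Input-drive vector for the input area.
#' @param tol Convergence tolerance on the max-norm residual.
#' @param max_iter Maximum Newton iterations.
#' @param smoothing Smoothing width used for the Newton Jacobian and the
#'   stability check.
#' @return An object of class `fixed_point`: list with the packed `state`,
#'   per-area firing `rates` of the principal cells, the `residual`, and
#'   attributes `stable` (logical) and `max_re_eig`.
#' @export
solve_fixed_point <- function(circuit, drive, tol = 1e-12, max_iter = 200L,
                              smoothing = 1e-3) {
  seed <- analytic_fixed_point(circuit, drive)
  x <- seed$state
  res <- circuit_rhs(circuit, x, drive, smoothing = 0)
  rnorm0 <- max(abs(res))
  if (rnorm0 > tol) {
    for (it in seq_len(max_iter)) {
      jac <- jacobian_at(circuit, x, drive, smoothing = smoothing)
      step <- tryCatch(solve(jac, res), error = function(e) NULL)
      if (is.null(step)) {
        step <- solve(jac + diag(1e-8, nrow(jac)), res)
      }
      lambda <- 1
      repeat {
        xn <- x - lambda * step
        resn <- circuit_rhs(circuit, xn, drive, smoothing = 0)
        if (max(abs(resn)) < max(abs(res)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      x <- xn
      res <- resn
      if (max(abs(res)) < tol) break
    }
    if (max(abs(res)) >= tol) {
      stop("fixed-point Newton iteration did not converge; best residual ",
           format(max(abs(res))), call. = FALSE)
    }
  }
  jac <- jacobian_at(circuit, x, drive, smoothing = smoothing)
  ev <- eigen(jac, only.values = TRUE)$values
  max_re <- max(Re(ev))
  if (max_re >= 0) {
    warning("fixed point is locally unstable (max Re eigenvalue ",
            format(max_re), ")", call. = FALSE)
  }
  blocks <- unpack_state(circuit, x)
  rates <- lapply(blocks, function(b) rectify(b$y)^2)
  structure(
    list(state = x, rates = rates, residual = max(abs(res)), drive = drive),
    class = "fixed_point", stable = max_re < 0, max_re_eig = max_re
  )
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point> residual ", format(x$residual),
      ", stable: ", attr(x, "stable"), "\n", sep = "")
  for (nm in names(x$rates)) {
    cat("  ", nm, ": peak rate ", format(max(x$rates[[nm]])), "\n", sep = "")
  }
  invisible(x)
}

#' Jacobian of the circuit dynamics at a state
#'
#' Closed-form derivative of [circuit_rhs()] using the smoothed
#' rectification (required: the hard nonlinearity is not differentiable at
#' threshold).
#'
#' @param circuit A `circuit`.
#' @param state Packed state vector (typically a fixed point).
#' @param drive Input-drive vector for the input area.
#' @param smoothing Smoothing width (> 0).
#' @param frozen_gain If `TRUE`, the recurrent-gain feedback loop is severed:
#'   principal cells no longer see fluctuations of the gain population `a`
#'   (its value is frozen at the operating point). This is the
#'   normalization-removed control.
#' @return Dense square Jacobian matrix (units 1/ms).
#' @export
jacobian_at <- function(circuit, state, drive, smoothing = 1e-3,
                        frozen_gain = FALSE) {
  if (smoothing <= 0) {
    stop("`smoothing` must be > 0 for the Jacobian ",
         "(hard rectification is not differentiable at 0)", call. = FALSE)
  }
  n <- circuit$geometry$n
  nm_areas <- names(circuit$areas)
  N <- n_states(circuit)
  s <- unpack_state(circuit, state)
  J <- matrix(0, N, N)

  ry <- lapply(s, function(b) rectify(b$y, smoothing))
  dry <- lapply(s, function(b) rectify_deriv(b$y, smoothing))
  rates_y <- lapply(ry, function(r) r^2)
  drate_y <- mapply(function(r, d) 2 * r * d, ry, dry, SIMPLIFY = FALSE)
  z <- area_drives(circuit, drive, rates_y)

  G <- H <- stats::setNames(rep(list(0), length(nm_areas)), nm_areas)
  for (e in circuit$edges) {
    p <- as.numeric(e$W_fb %*% rates_y[[e$higher]])
    G[[e$lower]] <- G[[e$lower]] + (e$gamma / 2) * p
    H[[e$lower]] <- H[[e$lower]] + 0.5 * p
  }
  gate_q <- identical(circuit$fb_gate %||% "q", "q")
  deriv_uhat <- identical(circuit$a_deriv %||% "duhat", "duhat")
  w_in <- circuit$u_input_mix %||% 0

  idx <- function(area, type) state_index(circuit, area, type)

  for (nm in nm_areas) {
    ar <- circuit$areas[[nm]]
    p <- ar$params
    b <- s[[nm]]
    ru <- rectify(b$u, smoothing)
    dru <- rectify_deriv(b$u, smoothing)
    ra <- rectify(b$a, smoothing)
    dra <- rectify_deriv(b$a, smoothing)
    rq <- if (gate_q) rectify(b$q, smoothing) else ry[[nm]]
    drq <- rectify_deriv(b$q, smoothing)
    uh <- uhat_fun(ru)
    duh <- dru / (4 * uh)
    gain <- 1 / (1 + ra)
    E <- as.numeric(ar$W_r %*% ry[[nm]]) + G[[nm]] * rq

    iy <- idx(nm, "y"); iu <- idx(nm, "u"); ia <- idx(nm, "a")
    iq <- idx(nm, "q")

    # y-row
    J[iy, iy] <- (diag(-1, n) + gain * ar$W_r %*% diag(dry[[nm]])) / p$tau_y
    if (!gate_q) {
      J[iy, iy] <- J[iy, iy] + diag(gain * G[[nm]] * dry[[nm]] / p$tau_y, n)
    }
    if (!frozen_gain) {
      J[iy, ia] <- diag(-gain^2 * dra * E / p$tau_y, n)
    }
    if (gate_q) {
      J[iy, iq] <- diag(gain * G[[nm]] * drq / p$tau_y, n)
    }

    # u-row (also reused, scaled by alpha, inside the a-row)
    J_uy <- (1 - w_in) * circuit$pool_scale *
      matrix(drate_y[[nm]] * ru, n, n, byrow = TRUE) / p$tau_u
    J_uu <- (diag(-1, n) + (1 - w_in) * circuit$pool_scale *
               matrix(rates_y[[nm]] * dru, n, n, byrow = TRUE)) / p$tau_u
    J[iu, iy] <- J_uy
    J[iu, iu] <- J_uu

    # a-row; the alpha-coupling carries du/dt (or d uhat/dt = du/dt / (4
    # uhat)); away from a fixed point the uhat variant also needs the product
    # rule term through 1/(4 uhat)
    du_now <- (-b$u + p$sigma^2 / 2 +
                 (1 - w_in) * circuit$pool_scale * sum(rates_y[[nm]] * ru) +
                 (w_in / 2) * circuit$pool_scale * sum(z[[nm]]^2)) / p$tau_u
    acoef <- if (deriv_uhat) p$alpha / (4 * uh) else rep(p$alpha, n)
    J[ia, ia] <- diag(-1 + uh, n) / p$tau_a
    J[ia, iu] <- diag((1 + b$a) * duh, n) / p$tau_a + (acoef / p$tau_a) * J_uu
    if (deriv_uhat) {
      J[ia, iu] <- J[ia, iu] +
        diag(-p$alpha * du_now * duh / (4 * uh^2) / p$tau_a, n)
    }
    J[ia, iy] <- (acoef / p$tau_a) * J_uy

    # q-row
    J[iq, iy] <- diag(dry[[nm]] / p$tau_q, n)
    J[iq, iq] <- diag(-1 / p$tau_q, n)

    # inter-areal terms
    for (e in circuit$edges) {
      if (e$lower == nm) {  # feedback from e$higher into this area
        ih <- idx(e$higher, "y")
        fbmat <- e$W_fb %*% diag(drate_y[[e$higher]])
        J[iy, ih] <- J[iy, ih] +
          (gain * rq) * ((e$gamma / 2) * fbmat) / p$tau_y
        J[ia, ih] <- J[ia, ih] + 0.5 * fbmat / p$tau_a
      }
      if (e$higher == nm) {  # feedforward from e$lower into this area
        il <- idx(e$lower, "y")
        J[iy, il] <- J[iy, il] +
          (ar$beta / 2) * t(e$W_fb) %*% diag(drate_y[[e$lower]]) / p$tau_y
        if (w_in > 0) {
          # the modulatory pathway sees the squared feedforward drive
          v <- w_in * circuit$pool_scale *
            as.numeric(crossprod(e$W_fb %*% z[[nm]],
                                 diag(drate_y[[e$lower]])))
          Juyl <- matrix(v, n, n, byrow = TRUE) / p$tau_u
          J[iu, il] <- J[iu, il] + Juyl
          J[ia, il] <- J[ia, il] + (acoef / p$tau_a) * Juyl
        }
      }
    }
  }
  J
}

#' Deterministic integration of the circuit dynamics
#'
#' Integrates [circuit_rhs()] with a stiff-capable adaptive solver.
#'
#' @param circuit A `circuit`.
#' @param drive Input-drive vector.
#' @param initial_state Packed state vector; defaults to all zeros.
#' @param duration Duration in ms.
#' @param dt Output sampling interval in ms (solver steps are adaptive).
#' @param smoothing Rectification smoothing (0 = hard).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `deSolve` (matrix: time plus states).
#' @export
simulate_circuit <- function(circuit, drive, initial_state = NULL,
                             duration = 200, dt = 0.5, smoothing = 0,
                             rtol = 1e-8, atol = 1e-10) {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (is.null(initial_state)) initial_state <- rep(0, n_states(circuit))
  times <- seq(0, duration, by = dt)
  fn <- function(t, y, parms) {
    list(circuit_rhs(circuit, y, drive, smoothing = smoothing))
  }
  out <- deSolve::ode(y = initial_state, times = times, func = fn,
                      parms = NULL, method = "lsoda", rtol = rtol,
                      atol = atol)
  if (any(!is.finite(out))) {
    bad <- which(apply(out, 1L, function(r) any(!is.finite(r))))[1L]
    stop("integration produced non-finite state at t = ",
         out[bad, 1L], " ms", call. = FALSE)
  }
  out
}

#' Zero (resting) state of a circuit
#' @param circuit A `circuit`.
#' @return Packed numeric vector of zeros with the layout used by
#'   [circuit_rhs()]: per area in hierarchy order, blocks `y`, `u`, `a`, `q`
#'   of `n` neurons each.
#' @export
initial_state <- function(circuit) rep(0, n_states(circuit))

#' Contrast-response function at the fixed point
#'
#' Solves the fixed point across a contrast grid and tabulates, per area,
#' the firing rate of the maximally responsive principal neuron (default) or
#' the population mean rate.
#'
#' @param circuit A `circuit`.
#' @param contrasts Contrast grid in percent.
#' @param orientation Stimulus orientation in degrees.
#' @param measure `"max"` (maximally responsive neuron) or `"mean"`.
#' @return `data.frame` with columns `contrast_pct`, `area`, `rate`.
#' @export
contrast_response <- function(circuit, contrasts = c(0, 1, 3, 6, 10, 12, 25,
                                                     40, 50, 75, 100),
                              orientation = 0, measure = c("max", "mean")) {
  measure <- match.arg(measure)
  if (any(contrasts < 0)) stop("contrasts must be >= 0", call. = FALSE)
  rows <- list()
  for (cc in contrasts) {
    z <- input_drive(stimulus(cc, orientation), circuit$geometry,
                     circuit$half_width)
    fp <- solve_fixed_point(circuit, z)
    for (nm in names(circuit$areas)) {
      r <- fp$rates[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        contrast_pct = cc, area = nm,
        rate = if (measure == "max") max(r) else mean(r)
      )
    }
  }
  do.call(rbind, rows)
}
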