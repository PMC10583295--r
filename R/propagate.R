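#' Instantaneous heteronuclear dipolar frequency under sample rotation
#'
#' Coefficient of the secular two-spin operator 2*Iz*Sz for a crystallite
#' whose coupling-tensor symmetry axis sits at polar angles (beta, gamma) in
#' the rotor frame, with the rotor axis tilted by `rotor_tilt` from the
#' static field and turned by `rotor_phase`.  Computed geometrically:
#' the tensor axis is rotated into the laboratory frame and the second
#' Legendre polynomial of its angle theta to the field is evaluated, so that
#' the returned value is `b_eff * P2(cos(theta))` in Hz.
#'
#' At the magic angle the average over a full rotor turn vanishes — the
#' premise of dipolar recoupling.  With `rotor_tilt = 0` (no MAS tilt) and
#' `beta = 0` the static full-coupling limit `b_eff` is recovered.
#'
#' @param beta,gamma Crystallite orientation in the rotor frame (radians).
#' @param rotor_phase Rotor position angle(s) in radians (vectorized).
#' @param b_eff Effective coupling magnitude `S_CH * d_CH` in Hz.
#' @param rotor_tilt Angle between rotor axis and field; defaults to the
#'   magic angle.
#' @return Dipolar frequency (Hz), same length as `rotor_phase`.
#' @examples
#' # MAS averages the secular coupling to zero
#' ph <- seq(0, 2 * pi, length.out = 721)[-721]
#' mean(dipolar_frequency(0.7, 0.3, ph, 22000))
#' @export
dipolar_frequency <- function(beta, gamma, rotor_phase, b_eff,
                              rotor_tilt = acos(1 / sqrt(3))) {
  if (!is.finite(b_eff))
    .rpdlf_stop("b_eff must be finite", "rpdlf_value_error")
  ct <- cos(rotor_tilt) * cos(beta) -
    sin(rotor_tilt) * sin(beta) * cos(rotor_phase + gamma)
  b_eff * 0.5 * (3 * ct^2 - 1)
}

# spin-1/2 operators for the two-spin (1H = I, 13C = S) Hilbert space
.two_spin_ops <- function() {
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  sz <- diag(c(0.5, -0.5))
  e2 <- diag(2)
  list(Ix = kronecker(sx, e2), Iy = kronecker(sy, e2),
       Iz = kronecker(sz, e2), Sz = kronecker(e2, sz))
}

#' Propagate a two-spin system through a pulse schedule
#'
#' Reference density-matrix propagation of the 4x4 1H-13C system under a
#' piecewise-constant Hamiltonian: within each pulse event, each sub-step
#' uses the RF field of the event plus the dipolar coupling evaluated at the
#' sub-step midpoint rotor phase.  The initial state is Iz and the recorded
#' observable is \eqn{\langle Iz \rangle(t)} normalized to 1 at t = 0.
#'
#' This dense propagator is the slow, transparent reference used to validate
#' the compiled modulation core; [simulate_modulation()] is the fast path.
#'
#' @param schedule A `pulse_schedule` (see [r1817_schedule()]); must cover
#'   `max(sample_times)`.
#' @param cond [simulation_conditions()]; supplies the effective coupling
#'   and MAS rate.
#' @param orientation Numeric `c(beta, gamma)` crystallite orientation.
#' @param sample_times Times (s) at which to record the observable; snapped
#'   to the nearest sub-step boundary.
#' @param n_sub Sub-steps per pulse event (default 32).  The resulting step
#'   must be at most 1/20 of the shorter of (rotor period / 18) and the RF
#'   nutation period, otherwise a configuration error is raised.
#' @return An object of class `spin_trajectory`: list with `times`,
#'   `observable`, and attributes `unitarity_error` (max deviation of
#'   U U* from the identity accumulated stepwise) and `trace_error`.
#' @export
propagate <- function(schedule, cond, orientation, sample_times,
                      n_sub = 32L) {
  if (!inherits(schedule, "pulse_schedule"))
    .rpdlf_stop("schedule must be a pulse_schedule", "rpdlf_value_error")
  durations <- vapply(schedule, `[[`, 0, "duration")
  total <- sum(durations)
  if (max(sample_times) > total + 1e-12)
    .rpdlf_stop("schedule does not cover max(sample_times)", "rpdlf_config_error")

  tau_r <- attr(schedule, "tau_r")
  nu1_max <- max(vapply(schedule, `[[`, 0, "nutation_frequency"))
  shortest <- min(tau_r / 18, if (nu1_max > 0) 1 / nu1_max else Inf)
  dt_max_allowed <- shortest / 20
  if (max(durations) / n_sub > dt_max_allowed + 1e-15)
    .rpdlf_stop(sprintf(
      "time step too coarse: %g s exceeds the allowed %g s; increase n_sub",
      max(durations) / n_sub, dt_max_allowed), "rpdlf_config_error")

  ops <- .two_spin_ops()
  b_eff <- .d_eff(cond)
  beta <- orientation[1]; gamma <- orientation[2]
  mas <- attr(schedule, "mas_rate")

  rho <- ops$Iz
  norm0 <- Re(sum(diag(rho %*% ops$Iz)))
  times <- numeric(0); obs <- numeric(0)
  uerr <- 0; trerr <- 0
  tr0 <- Re(sum(diag(rho)))

  want <- sort(unique(sample_times))
  record <- function(tnow) {
    hit <- which(abs(want - tnow) <= 1e-12 + .Machine$double.eps * 100)
    if (length(hit)) {
      times <<- c(times, tnow)
      obs <<- c(obs, Re(sum(diag(rho %*% ops$Iz))) / norm0)
      want <<- want[-hit]
    }
  }
  record(0)

  tnow <- 0
  for (ev in schedule) {
    dt <- ev$duration / n_sub
    w1 <- 2 * pi * ev$nutation_frequency
    hrf <- w1 * (cos(ev$phase) * ops$Ix + sin(ev$phase) * ops$Iy) +
      2 * pi * ev$offset * ops$Iz
    for (j in seq_len(n_sub)) {
      tm <- tnow + (j - 0.5) * dt
      wd <- 2 * pi * dipolar_frequency(beta, gamma, 2 * pi * mas * tm, b_eff)
      H <- hrf + wd * 2 * (ops$Iz %*% ops$Sz)
      eg <- eigen(H, symmetric = TRUE)
      U <- eg$vectors %*% (exp(-1i * eg$values * dt) * Conj(t(eg$vectors)))
      rho <- U %*% rho %*% Conj(t(U))
      uerr <- max(uerr, max(abs(U %*% Conj(t(U)) - diag(4))))
      trerr <- max(trerr, abs(Re(sum(diag(rho))) - tr0))
      record(tnow + j * dt)
    }
    tnow <- tnow + ev$duration
  }

  structure(list(times = times, observable = obs),
            class = "spin_trajectory",
            unitarity_error = uerr, trace_error = trerr)
}

#' @export
print.spin_trajectory <- function(x, ...) {
  cat(sprintf("<spin_trajectory: %d samples, t in [0, %g] s>\n",
              length(x$times), max(x$times)))
  invisible(x)
}
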