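#' A single RF pulse event on the 1H channel
#'
#' Building block for pulse schedules: a rectangular pulse of given
#' duration, nutation frequency and phase, with a constant rotating-frame
#' offset acting throughout.
#'
#' @param duration Pulse duration in seconds (> 0).
#' @param nutation_frequency RF nutation frequency nu1 in Hz (>= 0).
#' @param phase RF phase in radians.
#' @param offset 1H rotating-frame offset in Hz active during the event.
#' @return An object of class `pulse_event`.
#' @export
pulse_event <- function(duration, nutation_frequency, phase = 0, offset = 0) {
  if (!is.numeric(duration) || duration <= 0)
    .rpdlf_stop("pulse duration must be > 0", "rpdlf_value_error")
  if (!is.numeric(nutation_frequency) || nutation_frequency < 0)
    .rpdlf_stop("nutation_frequency must be >= 0", "rpdlf_value_error")
  out <- list(duration = duration, nutation_frequency = nutation_frequency,
              phase = phase, offset = offset)
  class(out) <- "pulse_event"
  out
}

#' Construct the R18(1,7) recoupling schedule
#'
#' One R18\eqn{_1^7} block consists of 18 equal elements spanning exactly one
#' rotor period.  Each element is a pi rotation: its nominal nutation
#' frequency is 9 x MAS rate so that nu1 x duration = 1/2.  Element phases
#' alternate +70 and -70 degrees (pi x 7 / 18).  RF miscalibration is
#' modelled by scaling the nutation frequency while keeping the timing
#' rotor-synchronized, as in a real experiment where pulse lengths are set
#' by the spinning rate.
#'
#' @param mas_rate MAS rate in Hz (> 0).
#' @param rf_scale Multiplier of the nominal nutation frequency.
#' @param offset_hz 1H offset in Hz carried by every event.
#' @param n_blocks Number of R18 blocks (>= 1).
#' @param first_phase_sign +1 starts with +70 deg, -1 with -70 deg.  The two
#'   orderings are equally valid conventions for the same symmetry sequence;
#'   [simulate_modulation()] averages them by default.
#' @return A list of [pulse_event()] objects of class `pulse_schedule`, with
#'   attributes `mas_rate`, `n_blocks` and `tau_r` (rotor period, s).
#' @examples
#' sch <- r1817_schedule(5000, n_blocks = 1)
#' length(sch)                          # 18 elements
#' sch[[1]]$duration * sch[[1]]$nutation_frequency  # pi rotation: 1/2
#' @export
r1817_schedule <- function(mas_rate, rf_scale = 1, offset_hz = 0,
                           n_blocks = 1L, first_phase_sign = 1L) {
  if (!is.numeric(mas_rate) || mas_rate <= 0)
    .rpdlf_stop("mas_rate must be > 0", "rpdlf_config_error")
  if (n_blocks < 1L)
    .rpdlf_stop("n_blocks must be >= 1", "rpdlf_config_error")
  if (!first_phase_sign %in% c(-1L, 1L, -1, 1))
    .rpdlf_stop("first_phase_sign must be +1 or -1", "rpdlf_config_error")

  tau_r <- 1 / mas_rate
  el_dur <- tau_r / 18
  nu1 <- 9 * mas_rate * rf_scale
  phi0 <- 70 * pi / 180

  sch <- vector("list", 18L * n_blocks)
  for (k in seq_along(sch)) {
    sgn <- if ((k - 1L) %% 2L == 0L) first_phase_sign else -first_phase_sign
    sch[[k]] <- pulse_event(el_dur, nu1, sgn * phi0, offset_hz)
  }
  structure(sch, class = "pulse_schedule",
            mas_rate = mas_rate, n_blocks = as.integer(n_blocks),
            tau_r = tau_r)
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf("<pulse_schedule: %d events, %g s total (%d R18 blocks @ MAS %g Hz)>\n",
              length(x), sum(vapply(x, `[[`, 0, "duration")),
              attr(x, "n_blocks"), attr(x, "mas_rate")))
  invisible(x)
}
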