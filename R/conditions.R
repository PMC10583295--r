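#' Simulation conditions for one R-PDLF experiment
#'
#' Bundles all physics parameters of a single R-PDLF simulation: the C-H
#' bond order parameter magnitude, the rigid one-bond 1H-13C dipolar
#' coupling, the MAS rate, the RF amplitude scale (relative to the nominal
#' nutation frequency 9 x MAS rate demanded by R18\eqn{_1^7} symmetry), the
#' 1H chemical-shift offset and the powder scheme.
#'
#' Motional averaging is represented solely through the effective coupling
#' `s_ch * d_ch` of an axially symmetric tensor (bilayer-normal symmetry
#' axis); only the magnitude |S_CH| is meaningful.
#'
#' @param s_ch Order parameter magnitude |S_CH| in \[0, 1\].
#' @param d_ch Rigid-limit dipolar coupling magnitude in Hz (default 22000).
#' @param mas_rate MAS spinning rate in Hz (> 0).
#' @param rf_scale Multiplier of the nominal 1H nutation frequency
#'   (1 = ideally calibrated; 0 is allowed and gives no recoupling).
#' @param offset_ppm 1H chemical-shift offset in ppm.
#' @param larmor_1h 1H Larmor frequency in Hz, used for the ppm-to-Hz
#'   conversion (default 400 MHz).
#' @param powder A [powder_orientations()] scheme.
#' @return An object of class `simulation_conditions`.
#' @examples
#' cond <- simulation_conditions(s_ch = 0.1)
#' cond$mas_rate
#' @export
simulation_conditions <- function(s_ch = 0.1, d_ch = 22000, mas_rate = 5000,
                                  rf_scale = 1, offset_ppm = 0,
                                  larmor_1h = 400e6,
                                  powder = powder_orientations("zcw", 233L)) {
  if (!is.numeric(s_ch) || length(s_ch) != 1L || is.na(s_ch) ||
      s_ch < 0 || s_ch > 1)
    .rpdlf_stop("s_ch must be a single value in [0, 1]", "rpdlf_value_error")
  if (!is.numeric(mas_rate) || mas_rate <= 0)
    .rpdlf_stop("mas_rate must be > 0", "rpdlf_config_error")
  if (!is.numeric(rf_scale) || rf_scale < 0)
    .rpdlf_stop("rf_scale must be >= 0", "rpdlf_value_error")
  if (!is.numeric(d_ch) || d_ch < 0)
    .rpdlf_stop("d_ch must be >= 0", "rpdlf_value_error")
  if (!inherits(powder, "powder_scheme"))
    .rpdlf_stop("powder must be a powder_scheme (see powder_orientations())",
                "rpdlf_value_error")
  out <- list(s_ch = s_ch, d_ch = d_ch, mas_rate = mas_rate,
              rf_scale = rf_scale, offset_ppm = offset_ppm,
              larmor_1h = larmor_1h, powder = powder)
  class(out) <- "simulation_conditions"
  out
}

# 1H offset in Hz
.offset_hz <- function(cond) cond$offset_ppm * cond$larmor_1h / 1e6

# effective (motionally averaged) coupling in Hz
.d_eff <- function(cond) cond$s_ch * cond$d_ch

#' @export
print.simulation_conditions <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_conditions>\n",
    "  |S_CH| = %g, d_CH = %g Hz (effective coupling %g Hz)\n",
    "  MAS %g Hz, RF scale %g, 1H offset %g ppm @ %g MHz\n",
    "  powder: %s (%d orientations)\n"),
    x$s_ch, x$d_ch, .d_eff(x), x$mas_rate, x$rf_scale, x$offset_ppm,
    x$larmor_1h / 1e6, x$powder$scheme_name, length(x$powder$beta)))
  invisible(x)
}
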