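#' Conversion constants linking splittings to order parameters
#'
#' @param kappa Scaling factor of the recoupling sequence: ratio of the
#'   observed peak-to-peak splitting to the residual coupling
#'   `|S_CH| * d_ch`; 0.315 for R18\eqn{_1^7}.
#' @param d_ch Rigid one-bond 1H-13C dipolar coupling magnitude in Hz.
#' @param quad_splitting_const Effective constant (Hz) linking a 2H powder
#'   quadrupolar splitting to |S_CD| (126 kHz).
#' @return An object of class `conversion_constants`.
#' @export
conversion_constants <- function(kappa = 0.315, d_ch = 22000,
                                 quad_splitting_const = 126000) {
  if (any(c(kappa, d_ch, quad_splitting_const) <= 0))
    .rpdlf_stop("all conversion constants must be > 0", "rpdlf_value_error")
  structure(list(kappa = kappa, d_ch = d_ch,
                 quad_splitting_const = quad_splitting_const),
            class = "conversion_constants")
}

#' Dipolar spectrum of a time-domain modulation
#'
#' Real cosine transform of the (optionally apodized) zero-filled
#' modulation, mirrored to negative frequencies.  The modulation is
#' amplitude-modulated and real, so the cosine transform is the natural
#' spectral representation; no apodization is applied by default because
#' smoothing biases horn positions.
#'
#' The first point is half-weighted (standard for one-sided transforms).
#' The attribute `power` stores the full FFT power `sum(|F x|^2)/N` of the
#' transformed vector x, which equals `sum(x^2)` (Parseval, with x the
#' half-first-point, apodized, zero-filled signal).
#'
#' @param mod A [dipolar_modulation()].
#' @param zero_fill_factor Zero-filling multiple (>= 1; default 8).
#' @param apodization_hz Exponential apodization in Hz (default 0).
#' @return Object of class `dipolar_spectrum`: list with `freq` (Hz,
#'   symmetric about 0), `intensity`, and attributes `df` (bin width),
#'   `t1max`, `power`, `signal_power`.
#' @export
dipolar_spectrum <- function(mod, zero_fill_factor = 8L,
                             apodization_hz = 0) {
  if (zero_fill_factor < 1L)
    .rpdlf_stop("zero_fill_factor must be >= 1", "rpdlf_value_error")
  dt <- mod$t1[2] - mod$t1[1]
  n <- length(mod$t1)
  x <- mod$amplitude * exp(-pi * apodization_hz * mod$t1)
  x[1] <- x[1] / 2
  nfft <- as.integer(n * zero_fill_factor)
  x <- c(x, rep(0, nfft - n))
  ft <- fft(x)
  half <- nfft %/% 2L
  pos_f <- (0:(half - 1L)) / (nfft * dt)
  pos_i <- Re(ft)[1:half]
  freq <- c(-rev(pos_f[-1]), pos_f)
  intensity <- c(rev(pos_i[-1]), pos_i)
  structure(list(freq = freq, intensity = intensity),
            class = "dipolar_spectrum",
            df = 1 / (nfft * dt), t1max = max(mod$t1),
            power = sum(Mod(ft)^2) / nfft, signal_power = sum(x^2))
}

#' @export
print.dipolar_spectrum <- function(x, ...) {
  cat(sprintf("<dipolar_spectrum: %d points, |f| <= %.0f Hz, bin %.2f Hz>\n",
              length(x$freq), max(x$freq), attr(x, "df")))
  invisible(x)
}

#' Read off the peak-to-peak dipolar splitting
#'
#' Finds the highest local maximum at positive frequency beyond a central
#' exclusion zone (default 1.5 pre-zero-fill frequency bins, which skips
#' the inhomogeneity-induced middle peak) and returns twice its frequency
#' — the horn-to-horn splitting of the Pake-like dipolar lineshape.
#' Candidate maxima below `min_peak_frac` of the spectrum's global maximum
#' are ignored: they are truncation ringing, not horns (the first positive
#' sidelobe of a boxcar truncation sits near 13% of the main peak).
#'
#' @param spec A [dipolar_spectrum()].
#' @param exclude_hz Central exclusion half-width in Hz; default
#'   `1.5 / t1max`.
#' @param min_peak_frac Minimum horn intensity as a fraction of the global
#'   maximum (default 0.15).
#' @return Splitting in Hz.
#' @export
read_off_splitting <- function(spec, exclude_hz = NULL,
                               min_peak_frac = 0.15) {
  if (is.null(exclude_hz)) exclude_hz <- 1.5 / attr(spec, "t1max")
  f <- spec$freq; y <- spec$intensity
  floor_int <- min_peak_frac * max(y)
  pos <- which(f > 0)
  f <- f[pos]; y <- y[pos]
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  loc <- which(is_max & f > exclude_hz & y >= floor_int)
  if (!length(loc))
    .rpdlf_stop("no resolvable dipolar horn (no local maximum beyond the central peak)",
                "rpdlf_not_resolvable_error")
  2 * f[loc[which.max(y[loc])]]
}

#' Convert a dipolar splitting to |S_CH|
#'
#' `|S_CH| = splitting / (kappa * d_ch)`.
#'
#' @param delta_nu Peak-to-peak splitting in Hz (>= 0).
#' @param constants [conversion_constants()].
#' @return Order parameter magnitude.
#' @export
splitting_to_sch <- function(delta_nu, constants = conversion_constants()) {
  if (any(delta_nu < 0))
    .rpdlf_stop("delta_nu must be >= 0", "rpdlf_value_error")
  delta_nu / (constants$kappa * constants$d_ch)
}

#' Inverse of [splitting_to_sch()]
#' @param s_ch Order parameter magnitude (>= 0).
#' @param constants [conversion_constants()].
#' @return Splitting in Hz.
#' @export
sch_to_splitting <- function(s_ch, constants = conversion_constants()) {
  s_ch * constants$kappa * constants$d_ch
}

#' Convert a 2H quadrupolar splitting to |S_CD|
#'
#' `|S_CD| = splitting / 126 kHz` with the standard effective constant.
#'
#' @param delta_nu_q Quadrupolar peak-to-peak splitting in Hz (>= 0).
#' @param constants [conversion_constants()].
#' @return Order parameter magnitude.
#' @export
quad_splitting_to_scd <- function(delta_nu_q,
                                  constants = conversion_constants()) {
  if (any(delta_nu_q < 0))
    .rpdlf_stop("delta_nu_q must be >= 0", "rpdlf_value_error")
  delta_nu_q / constants$quad_splitting_const
}

#' Minimum acquisition length to resolve two close splittings
#'
#' Two components with order parameters s1, s2 produce splittings
#' `kappa * d_ch * s` whose beat period is `1 / (kappa * d_ch * |s2 - s1|)`;
#' the acquisition must exceed half of it:
#' `1 / (2 * kappa * d_ch * |s2 - s1|)`.
#'
#' @param s1,s2 Distinct order parameters.
#' @param constants [conversion_constants()].
#' @return Minimum t1max in seconds.
#' @examples
#' min_resolving_t1max(0.03, 0.04)   # about 7.2 ms
#' @export
min_resolving_t1max <- function(s1, s2, constants = conversion_constants()) {
  if (any(s1 == s2))
    .rpdlf_stop("s1 and s2 must differ (beat period undefined)",
                "rpdlf_value_error")
  1 / (2 * constants$kappa * constants$d_ch * abs(s2 - s1))
}
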