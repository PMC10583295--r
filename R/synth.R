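# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic R-PDLF dataset
#'
#' Defines the multi-component, RF-inhomogeneity-weighted, damped and noisy
#' modulation emulating a realistic low signal-to-noise experiment.  The
#' defaults reproduce the canonical two-component test scenario: equal
#' fractions of |S_CH| = 0.03 and 0.04 under the default Gaussian RF
#' profile with 5% additive noise on 16 points at 5 kHz MAS.
#'
#' @param components Data frame with columns `s` and `fraction`
#'   (fractions sum to 1).
#' @param rf_dist [rf_distribution()] weighting the simulations.
#' @param lb Exponential line broadening in Hz applied to the noiseless sum.
#' @param noise_sigma Std. dev. of additive Gaussian noise as a fraction of
#'   s(0) (>= 0).  Noise is applied to t1 > 0 points only: the t1 = 0 point
#'   is the normalization reference.
#' @param n_points Number of t1 points.
#' @param mas_rate MAS rate in Hz.
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(components = data.frame(s = c(0.03, 0.04),
                                               fraction = c(0.5, 0.5)),
                       rf_dist = gaussian_rf_distribution(),
                       lb = 0, noise_sigma = 0.05, n_points = 16L,
                       mas_rate = 5000, seed = 1L) {
  if (abs(sum(components$fraction) - 1) > 1e-9)
    .rpdlf_stop("component fractions must sum to 1", "rpdlf_validation_error")
  if (noise_sigma < 0)
    .rpdlf_stop("noise_sigma must be >= 0", "rpdlf_validation_error")
  structure(list(components = components, rf_dist = rf_dist, lb = lb,
                 noise_sigma = noise_sigma, n_points = as.integer(n_points),
                 mas_rate = mas_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic dipolar modulation
#'
#' Fraction-weighted sum of RF-inhomogeneity-integrated modulations at each
#' component's order parameter, exponentially damped, plus i.i.d. Gaussian
#' noise on the t1 > 0 points.  Bit-identical for a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @param cond_base Optional [simulation_conditions()] template (powder
#'   scheme, d_ch, offset...); its `mas_rate` is overridden by the spec.
#' @param n_sub Propagation sub-steps (see [simulate_modulation()]).
#' @return A [dipolar_modulation()] whose `meta` echoes the spec and seed.
#' @export
generate_modulation <- function(spec, cond_base = NULL, n_sub = 32L) {
  if (!inherits(spec, "synth_spec"))
    .rpdlf_stop("spec must be a synth_spec", "rpdlf_value_error")
  if (is.null(cond_base)) cond_base <- simulation_conditions()
  cond_base$mas_rate <- spec$mas_rate

  acc <- numeric(spec$n_points)
  for (k in seq_len(nrow(spec$components))) {
    cond <- cond_base
    cond$s_ch <- spec$components$s[k]
    m <- integrate_over_rf(cond, spec$rf_dist, spec$n_points, n_sub = n_sub)
    acc <- acc + spec$components$fraction[k] * m$amplitude
  }
  acc <- acc / acc[1]
  t1 <- (seq_len(spec$n_points) - 1L) / spec$mas_rate
  acc <- acc * exp(-pi * spec$lb * t1)
  if (spec$noise_sigma > 0 && spec$n_points > 1L) {
    noise <- .with_seed(spec$seed,
                        rnorm(spec$n_points - 1L, 0, spec$noise_sigma))
    acc[-1] <- acc[-1] + noise
  }
  dipolar_modulation(t1, acc, meta = list(
    components_s = spec$components$s,
    components_fraction = spec$components$fraction,
    rf_kind = spec$rf_dist$kind, rf_center = spec$rf_dist$params$center,
    rf_sigma = spec$rf_dist$params$sigma, lb = spec$lb,
    noise_sigma = spec$noise_sigma, seed = spec$seed,
    mas_rate = spec$mas_rate, noise_on_t0 = FALSE))
}

#' Analytic superposition of two recoupled Pake modulations
#'
#' Equal-weight sum of ideal first-order powder modulations (no RF
#' effects): each crystallite contributes
#' `cos(2 * pi * (kappa * s * d_ch / 2) * sin(beta)^2 * t)` — the
#' effective-Hamiltonian frequency of R18\eqn{_1^7} recoupling, whose
#' powder horns sit at half the peak-to-peak splitting `kappa * s * d_ch`.
#' This is the textbook illustration of the resolution limit for two close
#' splittings (see [min_resolving_t1max()]); it uses no spin dynamics and
#' supports arbitrary time grids.
#'
#' @param s1,s2 Component order parameters (>= 0).
#' @param n_points Number of points on the uniform grid `[0, t1max]`.
#' @param t1max Acquisition length in seconds.
#' @param constants [conversion_constants()].
#' @param n_beta Gauss-Legendre nodes for the beta average.
#' @return A [dipolar_modulation()].
#' @export
generate_two_pake_superposition <- function(s1, s2, n_points, t1max,
                                            constants = conversion_constants(),
                                            n_beta = 200L) {
  if (any(c(s1, s2) < 0))
    .rpdlf_stop("s1 and s2 must be >= 0", "rpdlf_value_error")
  t1 <- seq(0, t1max, length.out = n_points)
  # mid-point quadrature in cos(beta), uniform measure on the sphere
  u <- (seq_len(n_beta) - 0.5) / n_beta          # cos(beta) in (0, 1)
  sin2 <- 1 - u^2
  pake <- function(s) {
    fmax <- constants$kappa * s * constants$d_ch / 2
    vapply(t1, function(t) mean(cos(2 * pi * fmax * sin2 * t)), numeric(1))
  }
  amp <- 0.5 * (pake(s1) + pake(s2))
  dipolar_modulation(t1, amp / amp[1],
                     meta = list(s1 = s1, s2 = s2, kind = "two_pake"))
}
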