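#' Crystallite orientation sets for powder averaging
#'
#' Generates a deterministic set of crystallite orientations (beta, gamma)
#' with normalized weights, used to average single-orientation spin dynamics
#' over the isotropic distribution of bilayer-normal directions in a
#' multilamellar vesicle (MLV) sample.
#'
#' Schemes:
#' \describe{
#'   \item{`"single"`}{One orientation (beta = pi/2, gamma = 0), weight 1.
#'     Useful for single-crystallite diagnostics.}
#'   \item{`"zcw"`}{ZCW-style quasi-uniform set: the golden-section
#'     spherical lattice with `n` snapped to the nearest Fibonacci number.
#'     cos(beta) is stratified uniformly over \[-1, 1\] and gamma advances by
#'     the golden angle, giving equal weights and fast convergence of smooth
#'     powder averages.}
#'   \item{`"repulsion-like"`}{The golden-section lattice (any `n`) relaxed
#'     by a fixed number of deterministic electrostatic-repulsion sweeps.}
#' }
#'
#' @param scheme_name One of `"single"`, `"zcw"`, `"repulsion-like"`.
#' @param n Requested number of orientations (>= 1).  For `"zcw"` the
#'   nearest Fibonacci number is used.
#' @return An object of class `powder_scheme`: a list with elements `beta`
#'   (radians, in \[0, pi\]), `gamma` (radians, in \[0, 2*pi)), `weights`
#'   (summing to 1), `scheme_name` and `n_gamma` (number of distinct gamma
#'   values per beta where meaningful, otherwise `NA`).
#' @examples
#' p <- powder_orientations("zcw", 233)
#' sum(p$weights)
#' # spherical average of the second Legendre polynomial is zero
#' sum(p$weights * (3 * cos(p$beta)^2 - 1) / 2)
#' @export
powder_orientations <- function(scheme_name = c("zcw", "repulsion-like", "single"),
                                n = 233L) {
  if (length(scheme_name) != 1L || !scheme_name %in% c("zcw", "repulsion-like", "single"))
    .rpdlf_stop(sprintf("unknown powder scheme '%s' (use 'single', 'zcw' or 'repulsion-like')",
                        paste(scheme_name, collapse = "/")),
                "rpdlf_config_error")
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    .rpdlf_stop("n must be a positive integer", "rpdlf_config_error")

  if (scheme_name == "single") {
    out <- list(beta = pi / 2, gamma = 0, weights = 1,
                scheme_name = "single", n_gamma = 1L)
    class(out) <- "powder_scheme"
    return(out)
  }

  if (scheme_name == "zcw") {
    fib <- c(1L, 2L, 3L, 5L, 8L, 13L, 21L, 34L, 55L, 89L, 144L, 233L, 377L,
             610L, 987L, 1597L, 2584L, 4181L, 6765L)
    n <- fib[which.min(abs(fib - n))]
  }

  lat <- .golden_lattice(n)
  beta <- lat$beta
  gamma <- lat$gamma

  if (scheme_name == "repulsion-like") {
    xyz <- cbind(sin(beta) * cos(gamma), sin(beta) * sin(gamma), cos(beta))
    # a few fixed-step repulsion sweeps; deterministic, keeps points on S2
    for (it in seq_len(10L)) {
      force <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d <- sweep(xyz, 2, xyz[i, ])
        r2 <- rowSums(d^2)
        r2[i] <- Inf
        force[i, ] <- -colSums(d / (r2^1.5 + 1e-9))
      }
      xyz <- xyz + (0.2 / n) * force
      xyz <- xyz / sqrt(rowSums(xyz^2))
    }
    beta <- acos(pmin(1, pmax(-1, xyz[, 3])))
    gamma <- atan2(xyz[, 2], xyz[, 1]) %% (2 * pi)
  }

  out <- list(beta = beta, gamma = gamma, weights = rep(1 / n, n),
              scheme_name = scheme_name, n_gamma = NA_integer_)
  class(out) <- "powder_scheme"
  out
}

.golden_lattice <- function(n) {
  j <- seq_len(n) - 1L
  z <- 1 - (2 * j + 1) / n
  list(beta = acos(z),
       gamma = (2 * pi * j * ((sqrt(5) - 1) / 2)) %% (2 * pi))
}

#' @export
print.powder_scheme <- function(x, ...) {
  cat(sprintf("<powder_scheme '%s': %d orientations>\n",
              x$scheme_name, length(x$beta)))
  invisible(x)
}
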