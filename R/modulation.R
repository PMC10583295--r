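#' Indirect-dimension dipolar modulation s(t1)
#'
#' Container for the time-domain recoupled dipolar modulation: a uniform t1
#' grid starting at 0 and real amplitudes normalized to 1 at t1 = 0, plus
#' free-form metadata (acquisition conditions, provenance).
#'
#' @param t1 Time grid in seconds, strictly increasing, starting at 0.
#' @param amplitude Real amplitudes, same length as `t1`; `amplitude[1]`
#'   must be 1 within 1e-9.
#' @param meta Named list of metadata.
#' @return An object of class `dipolar_modulation`.
#' @export
dipolar_modulation <- function(t1, amplitude, meta = list()) {
  if (length(t1) != length(amplitude) || length(t1) < 2L)
    .rpdlf_stop("t1 and amplitude must have equal length >= 2",
                "rpdlf_validation_error")
  if (any(diff(t1) <= 0))
    .rpdlf_stop("t1 must be strictly increasing", "rpdlf_validation_error")
  if (abs(t1[1]) > 1e-15)
    .rpdlf_stop("t1 must start at 0", "rpdlf_validation_error")
  if (abs(amplitude[1] - 1) > 1e-9)
    .rpdlf_stop("amplitude must be normalized to 1 at t1 = 0",
                "rpdlf_validation_error")
  structure(list(t1 = as.numeric(t1), amplitude = as.numeric(amplitude),
                 meta = meta),
            class = "dipolar_modulation")
}

#' @export
print.dipolar_modulation <- function(x, ...) {
  cat(sprintf("<dipolar_modulation: %d points, t1max = %g s>\n",
              length(x$t1), max(x$t1)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dipolar_modulation <- function(x, ...) {
  data.frame(t1 = x$t1, amplitude = x$amplitude)
}
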