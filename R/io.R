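#' Write / read a dipolar modulation as two-column text
#'
#' Plain-text interchange format: `#`-prefixed `key=value` header lines
#' carrying scalar metadata, followed by whitespace-separated columns
#' (t1 in seconds, normalized amplitude) at full double precision.
#'
#' @param mod A [dipolar_modulation()].
#' @param path File path.
#' @return `save_modulation` returns `path` invisibly; `load_modulation`
#'   returns a [dipolar_modulation()].
#' @export
save_modulation <- function(mod, path) {
  meta <- mod$meta[vapply(mod$meta, function(v)
    is.atomic(v) && length(v) == 1L && !is.null(v), logical(1))]
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s=%s", k,
            if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1))
  writeLines(c(hdr, sprintf("%.17g %.17g", mod$t1, mod$amplitude)), path)
  invisible(path)
}

#' @rdname save_modulation
#' @export
load_modulation <- function(path) {
  if (!file.exists(path))
    .rpdlf_stop(sprintf("modulation file not found: %s", path),
                "rpdlf_io_error")
  lines <- readLines(path)
  meta <- list()
  t1 <- numeric(0); amp <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) {
        key <- substr(kv, 1, eq - 1)
        val <- substr(kv, eq + 1, nchar(kv))
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (is.na(num)) val else num
      }
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      .rpdlf_stop(sprintf("malformed data line %d in %s", i, path),
                  "rpdlf_parse_error")
    t1 <- c(t1, v[1]); amp <- c(amp, v[2])
  }
  if (length(t1) < 2L)
    .rpdlf_stop(sprintf("no usable data in %s (time column missing?)", path),
                "rpdlf_parse_error")
  if (any(diff(t1) <= 0))
    .rpdlf_stop(sprintf("t1 values not strictly increasing in %s", path),
                "rpdlf_validation_error")
  dipolar_modulation(t1, amp, meta = meta)
}
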