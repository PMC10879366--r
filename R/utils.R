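`%||%` <- function(a, b) if (is.null(a)) b else a

# Sampling rate inferred from a uniform time column; errors on a non-uniform
# grid rather than guessing.
infer_fs <- function(time_s, tol = 1e-6) {
  if (length(time_s) < 2) stop("need at least two samples to infer a sampling rate")
  d <- diff(time_s)
  if (max(d) - min(d) > tol * stats::median(d)) {
    stop("time column is not a uniform grid; cannot infer a sampling rate")
  }
  1 / stats::median(d)
}

channel_columns <- function(rec) {
  setdiff(names(rec), c("time_s", "settled"))
}

require_channels <- function(rec, channels = c("Fp1", "Fp2", "P3", "P4")) {
  have <- channel_columns(rec)
  missing <- setdiff(channels, have)
  if (length(missing) > 0) {
    stop(sprintf("missing channel(s): %s (available: %s)",
                 paste(missing, collapse = ", "),
                 paste(have, collapse = ", ")), call. = FALSE)
  }
  invisible(rec)
}
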