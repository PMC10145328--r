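#' Uniformly sampled single-channel signal
#'
#' The universal input container of the package: a numeric vector of
#' samples together with its sampling frequency in Hz and a free-text
#' label.  All decomposition, spectral and rate-estimation functions
#' accept a `signal_record`.
#'
#' @param samples Numeric vector of signal samples (arbitrary units),
#'   length at least 2, all finite.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param label Free-text label carried through analyses (default `""`).
#'
#' @return An object of class `signal_record` with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' rec <- signal_record(sin(2 * pi * 0.2 * t), fs = 100, label = "tone")
#' duration(rec)
#' @export
signal_record <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("'samples' must contain at least 2 values", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1L]),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record: %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, duration(x),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Record duration in seconds
#'
#' @param x A [signal_record()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  length(x$samples) / x$fs
}

#' Time axis of a record
#'
#' @param x A [signal_record()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  (seq_along(x$samples) - 1) / x$fs
}

#' @export
as.data.frame.signal_record <- function(x, ...) {
  data.frame(time_s = time_axis(x), value = x$samples)
}
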