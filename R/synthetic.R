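#' Specification for a synthetic cardiorespiratory surrogate
#'
#' Describes the test signals the estimator is designed for: a cardiac
#' oscillation (default 1.2 Hz, i.e. 72 bpm, safely above the
#' respiration band) whose amplitude and baseline are modulated by a
#' respiratory oscillation, with an optional paced-breathing schedule
#' (rate changes mid-record) and controlled additive white Gaussian
#' noise.
#'
#' @param fs Sampling frequency, Hz (default 100).
#' @param duration Record length in seconds (default 60).
#' @param cardiac_freq Cardiac frequency in Hz (default 1.2; must be
#'   below `fs/2`).
#' @param rr_bpm Respiratory rate in bpm: a single number, or a
#'   data frame with columns `start_s`, `rr_bpm` for a piecewise-
#'   constant paced schedule (first `start_s` must be 0).
#' @param am_depth Respiratory amplitude-modulation depth of the
#'   cardiac component, fraction in \[0, 1) (default 0.3).
#' @param baseline_gain Additive respiratory baseline-wander gain
#'   (default 0.5).
#' @param snr_db Signal-to-noise ratio of added white Gaussian noise in
#'   dB, or `NULL` for a noiseless record (default).
#' @param seed Integer seed for the noise generator, or `NULL`.
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 100, duration = 60, cardiac_freq = 1.2,
                       rr_bpm = 12, am_depth = 0.3, baseline_gain = 0.5,
                       snr_db = NULL, seed = NULL) {
  if (fs <= 2 * cardiac_freq)
    stop("'fs' must exceed twice the cardiac frequency", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (is.numeric(rr_bpm) && length(rr_bpm) == 1L)
    rr_bpm <- data.frame(start_s = 0, rr_bpm = rr_bpm)
  if (!is.data.frame(rr_bpm) ||
      !all(c("start_s", "rr_bpm") %in% names(rr_bpm)) ||
      nrow(rr_bpm) < 1L || rr_bpm$start_s[1L] != 0 ||
      is.unsorted(rr_bpm$start_s, strictly = TRUE))
    stop("'rr_bpm' must be a number or a schedule data frame with ",
         "strictly increasing 'start_s' beginning at 0", call. = FALSE)
  if (any(rr_bpm$rr_bpm <= 0) || any(rr_bpm$rr_bpm >= 60 * fs / 2))
    stop("scheduled rates must lie in (0, 60*fs/2) bpm", call. = FALSE)
  if (am_depth < 0 || am_depth >= 1)
    stop("'am_depth' must be a fraction in [0, 1)", call. = FALSE)
  structure(
    list(fs = fs, duration = duration, cardiac_freq = cardiac_freq,
         schedule = rr_bpm, am_depth = am_depth,
         baseline_gain = baseline_gain, snr_db = snr_db, seed = seed),
    class = "synth_spec"
  )
}

# phase-continuous respiratory oscillation at the scheduled rate
resp_wave <- function(spec) {
  t <- (seq_len(round(spec$duration * spec$fs)) - 1) / spec$fs
  idx <- findInterval(t, spec$schedule$start_s)
  f_inst <- spec$schedule$rr_bpm[idx] / 60          # Hz at each sample
  phase <- 2 * pi * cumsum(f_inst) / spec$fs
  list(t = t, wave = sin(phase), rr_true = spec$schedule$rr_bpm[idx])
}

#' Synthetic respiration-belt signal
#'
#' Respiratory sinusoid with phase-continuous frequency following the
#' scheduled rate; optional white Gaussian noise at `snr_db`.
#'
#' @param spec A [synth_spec()].
#' @return A [signal_record()] labelled `"resp"`, with the per-sample
#'   true rate attached as attribute `rr_true` (bpm).
#' @examples
#' r <- make_resp(synth_spec(duration = 60, rr_bpm = 12))
#' sum(abs(diff(sign(r$samples))) > 0)  # ~24 zero crossings
#' @export
make_resp <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  w <- resp_wave(spec)
  rec <- signal_record(w$wave, fs = spec$fs, label = "resp")
  if (!is.null(spec$snr_db))
    rec <- add_awgn(rec, spec$snr_db, seed = spec$seed)
  attr(rec, "rr_true") <- w$rr_true
  rec
}

#' Synthetic respiration-modulated PPG/SCG surrogate
#'
#' Builds the pulse-like surrogate the estimator is designed to
#' decompose:
#' \deqn{s(t) = [1 + d \cdot resp(t)] \cos(2\pi f_c t)
#'   + g \cdot resp(t) + noise,}
#' where `resp` is the scheduled respiratory sinusoid, `d` the
#' amplitude-modulation depth and `g` the baseline-wander gain.
#' Sinusoidal rather than beat-template morphology: every code path of
#' the pipeline (decomposition, instantaneous frequency, screening) is
#' exercised while the ground truth stays analytic.
#'
#' @param spec A [synth_spec()].
#' @return List with `signal` (a [signal_record()] labelled `"ppg"`)
#'   and `truth` (data frame `time_s`, `rr_bpm` of the per-sample true
#'   rate).
#' @examples
#' out <- make_ppg_surrogate(synth_spec(duration = 60, rr_bpm = 12, seed = 7))
#' estimate_rr(out$signal)$rr_bpm  # ~12
#' @export
make_ppg_surrogate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  w <- resp_wave(spec)
  s <- (1 + spec$am_depth * w$wave) * cos(2 * pi * spec$cardiac_freq * w$t) +
    spec$baseline_gain * w$wave
  rec <- signal_record(s, fs = spec$fs, label = "ppg")
  if (!is.null(spec$snr_db))
    rec <- add_awgn(rec, spec$snr_db, seed = spec$seed)
  list(signal = rec, truth = data.frame(time_s = w$t, rr_bpm = w$rr_true))
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise variance is set from the empirical signal power:
#' `var = mean(x^2) / 10^(snr_db/10)`.  The generator state is isolated:
#' the caller's RNG stream is saved and restored.
#'
#' @param x A [signal_record()] with nonzero power.
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` returns the
#'   input unchanged.
#' @param seed Integer seed for reproducible noise, or `NULL` to draw
#'   from the current RNG state.
#' @return A [signal_record()] with noise added.
#' @export
add_awgn <- function(x, snr_db, seed = NULL) {
  stopifnot(inherits(x, "signal_record"))
  if (is.infinite(snr_db)) return(x)
  p <- mean(x$samples^2)
  if (p == 0) stop("zero-power input: SNR undefined", call. = FALSE)
  noise_sd <- sqrt(p / 10^(snr_db / 10))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  noise <- stats::rnorm(length(x$samples), sd = noise_sd)
  out <- signal_record(x$samples + noise, fs = x$fs, label = x$label)
  attr(out, "rr_true") <- attr(x, "rr_true")
  out
}
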