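#' Analytic signal of a decomposed mode
#'
#' Builds the discrete analytic signal `z = x + i y` of a real sequence
#' by the frequency-domain construction: the DFT of `x` has its negative
#' frequencies zeroed and its positive frequencies doubled (DC and, for
#' even lengths, the Nyquist bin are kept as-is), and the inverse DFT
#' yields `z`.  The modulus `a = |z|` is the instantaneous amplitude,
#' the unwrapped phase `theta = arg(z)` the instantaneous phase, and the
#' phase gradient scaled by `fs / (2 pi)` the instantaneous frequency in
#' Hz ([instantaneous_frequency()]).
#'
#' A constant input has no meaningful phase: amplitude is set to the
#' absolute constant, phase to 0, and `degenerate` is flagged with a
#' warning.
#'
#' @param x Numeric vector (length >= 8, finite), typically one IMF.
#' @param fs Sampling frequency in Hz (default 1).
#' @param index Mode index carried along for bookkeeping (default
#'   `NA`).
#'
#' @return An object of class `analytic_imf`: list with `index`, `x`,
#'   `y` (Hilbert transform of `x`), `amplitude`, `phase` (unwrapped,
#'   radians), `inst_freq` (Hz, same length as `x`), `fs` and
#'   `degenerate`.
#' @examples
#' n <- 0:5999
#' a <- analytic_signal(cos(2 * pi * 0.2 * n / 100), fs = 100)
#' mean(a$inst_freq[100:5900])  # ~0.2 Hz
#' @export
analytic_signal <- function(x, fs = 1, index = NA_integer_) {
  if (!is.numeric(x) || length(x) < 8L)
    stop("'x' must be a numeric vector of length >= 8", call. = FALSE)
  if (!all(is.finite(x))) stop("'x' must be finite", call. = FALSE)
  N <- length(x)

  if (diff(range(x)) == 0) {
    warning("constant input: phase undefined, set to 0")
    return(structure(
      list(index = index, x = x, y = rep(0, N), amplitude = abs(x),
           phase = rep(0, N), inst_freq = rep(0, N), fs = fs,
           degenerate = TRUE),
      class = "analytic_imf"
    ))
  }

  h <- numeric(N)
  h[1L] <- 1
  if (N %% 2L == 0L) {
    h[N / 2L + 1L] <- 1
    h[2L:(N / 2L)] <- 2
  } else {
    h[2L:((N + 1L) / 2L)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / N
  theta <- as.numeric(signal::unwrap(Arg(z)))
  structure(
    list(index = index, x = x, y = Im(z), amplitude = Mod(z),
         phase = theta, inst_freq = instantaneous_frequency(theta, fs),
         fs = fs, degenerate = FALSE),
    class = "analytic_imf"
  )
}

#' Instantaneous frequency from an unwrapped phase
#'
#' Differentiates the unwrapped phase with central differences at
#' interior samples and one-sided differences at the two endpoints
#' (per-sample radians), then converts to Hz:
#' `f[n] = fs * omega[n] / (2 pi)`.
#'
#' @param theta Unwrapped phase in radians (length >= 2).
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of instantaneous frequency in Hz, same length
#'   as `theta`.  Values can be negative where the analytic phase
#'   momentarily regresses (low-amplitude or boundary samples).
#' @export
instantaneous_frequency <- function(theta, fs = 1) {
  N <- length(theta)
  if (N < 2L) stop("'theta' must have length >= 2", call. = FALSE)
  omega <- numeric(N)
  omega[1L] <- theta[2L] - theta[1L]
  omega[N] <- theta[N] - theta[N - 1L]
  if (N > 2L)
    omega[2L:(N - 1L)] <- (theta[3L:N] - theta[1L:(N - 2L)]) / 2
  fs * omega / (2 * pi)
}

#' Hilbert spectrum of a set of analytic modes
#'
#' Assembles the time-frequency-energy surface: every sample `n` of mode
#' `i` deposits its energy `a_i[n]^2` (or amplitude `a_i[n]`) into the
#' frequency bin whose center `(k-1) * df_h` is nearest to its
#' instantaneous frequency `f_i[n]`, and the per-mode layers are summed.
#' Samples whose instantaneous frequency falls outside the grid — e.g.
#' negative excursions near boundaries — are routed to an overflow
#' bucket rather than silently dropped, so total deposited energy is
#' conserved exactly.
#'
#' @param imfs List of [analytic_signal()] results of equal length.
#' @param fs Sampling frequency in Hz (defaults to the first mode's).
#' @param df_h Frequency bin width in Hz (default 0.01).
#' @param fmax Upper edge of the frequency grid (default `fs/2`).
#' @param weighting `"energy"` (`a^2`, default) or `"amplitude"` (`a`).
#'
#' @return An object of class `hilbert_spectrum`: `H` is the summed
#'   time-by-frequency matrix, `freq` the bin centers, `time` the
#'   sample times, `overflow` the per-mode out-of-grid mass, and
#'   `deposits` the per-mode bin index/mass vectors from which any
#'   single-mode layer can be rebuilt with [spectrum_layer()].
#' @export
hilbert_spectrum <- function(imfs, fs = NULL, df_h = 0.01, fmax = NULL,
                             weighting = c("energy", "amplitude")) {
  weighting <- match.arg(weighting)
  if (!is.list(imfs) || length(imfs) == 0L)
    stop("'imfs' must be a nonempty list of analytic_imf objects", call. = FALSE)
  if (inherits(imfs, "analytic_imf")) imfs <- list(imfs)
  stopifnot(all(vapply(imfs, inherits, logical(1), "analytic_imf")))
  if (is.null(fs)) fs <- imfs[[1L]]$fs
  if (is.null(fmax)) fmax <- fs / 2
  if (df_h <= 0 || fmax <= 0) stop("'df_h' and 'fmax' must be positive",
                                   call. = FALSE)
  N <- length(imfs[[1L]]$x)
  nbin <- as.integer(floor(fmax / df_h)) + 1L
  freq <- (seq_len(nbin) - 1L) * df_h

  H <- matrix(0, nrow = N, ncol = nbin)
  overflow <- numeric(length(imfs))
  deposits <- vector("list", length(imfs))
  for (i in seq_along(imfs)) {
    ai <- imfs[[i]]
    if (length(ai$x) != N) stop("all modes must have equal length", call. = FALSE)
    mass <- if (weighting == "energy") ai$amplitude^2 else ai$amplitude
    bin <- as.integer(round(ai$inst_freq / df_h)) + 1L
    ok <- ai$inst_freq >= 0 & bin <= nbin
    idx <- which(ok)
    H[cbind(idx, bin[idx])] <- H[cbind(idx, bin[idx])] + mass[idx]
    overflow[i] <- sum(mass[!ok])
    deposits[[i]] <- list(bin = ifelse(ok, bin, NA_integer_), mass = mass)
  }
  structure(
    list(H = H, freq = freq, df_h = df_h, time = (seq_len(N) - 1L) / fs,
         fs = fs, weighting = weighting, overflow = overflow,
         deposits = deposits),
    class = "hilbert_spectrum"
  )
}

#' Rebuild the spectrum layer contributed by one mode
#'
#' @param hs A [hilbert_spectrum()].
#' @param i Mode index.
#' @return Time-by-frequency matrix `H_i`; the full spectrum is the
#'   elementwise sum of all layers.
#' @export
spectrum_layer <- function(hs, i) {
  stopifnot(inherits(hs, "hilbert_spectrum"))
  d <- hs$deposits[[i]]
  Hi <- matrix(0, nrow = length(hs$time), ncol = length(hs$freq))
  idx <- which(!is.na(d$bin))
  Hi[cbind(idx, d$bin[idx])] <- d$mass[idx]
  Hi
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf(
    "hilbert_spectrum: %d x %d (time x freq), df = %g Hz, %s-weighted, %d mode(s)\n",
    nrow(x$H), ncol(x$H), x$df_h, x$weighting, length(x$deposits)))
  cat(sprintf("  total mass %.6g (overflow %.6g)\n",
              sum(x$H) + sum(x$overflow), sum(x$overflow)))
  invisible(x)
}
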