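#' Configuration for Gaussian average filtering decomposition
#'
#' @param alpha Gaussian shape parameter (default 4.0728, endpoint taps
#'   about 0.025% of the central tap); must be at least 2.45 so the
#'   truncated window still behaves like a Gaussian.
#' @param epsilon Window-scale factor in \[1.1, 3\] used by
#'   [window_half_length()] (default 1.8).
#' @param extension_style Boundary extension style, see [extend_signal()]
#'   (default `"double_symmetric_reflection"`).
#' @param energy_ratio_threshold Stop when the energy of the original
#'   signal divided by the energy of the current residual exceeds this
#'   value, i.e. the residual is negligible (default 1e6).
#' @param energy_diff_threshold Stop when the energy difference between
#'   neighbouring modes, normalized by the original signal energy, falls
#'   below this value (default 1e-3).
#' @param max_imfs Safeguard on the number of extracted modes
#'   (default 12).
#'
#' @return An object of class `gafd_config`.
#' @export
gafd_config <- function(alpha = 4.0728, epsilon = 1.8,
                        extension_style = c("double_symmetric_reflection",
                                            "constant", "periodical",
                                            "reflection"),
                        energy_ratio_threshold = 1e6,
                        energy_diff_threshold = 1e-3,
                        max_imfs = 12L) {
  extension_style <- match.arg(extension_style)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 2.45)
    stop("'alpha' must be >= 2.45 (endpoint taps below 5% of the maximum)",
         call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 1.1 || epsilon > 3)
    stop("'epsilon' must lie in [1.1, 3]", call. = FALSE)
  if (energy_ratio_threshold <= 0 || energy_diff_threshold <= 0)
    stop("energy thresholds must be positive", call. = FALSE)
  if (max_imfs < 1) stop("'max_imfs' must be >= 1", call. = FALSE)
  structure(
    list(alpha = alpha, epsilon = epsilon, extension_style = extension_style,
         energy_ratio_threshold = energy_ratio_threshold,
         energy_diff_threshold = energy_diff_threshold,
         max_imfs = as.integer(max_imfs)),
    class = "gafd_config"
  )
}

#' Gaussian average filtering decomposition (GAFD)
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' Gaussian moving-average sifting.  Each round measures the number of
#' local extrema of the current working signal, derives an adaptive
#' window half-length from it ([window_half_length()]), extends the
#' working signal across its boundaries, smooths it with the normalized
#' Gaussian window to obtain the instantaneous mean, and emits the
#' difference (working minus mean) as the next IMF.  The smoothed mean
#' becomes the working signal of the following round, so modes come out
#' ordered from the highest oscillation frequency down — the Gaussian
#' moving average is inherently a low-pass filter and each round peels
#' off the detail it rejects.
#'
#' Sifting terminates when any of the stop criteria fires:
#' \enumerate{
#'   \item the adaptive window no longer fits the record (`M >= N/2 - 1`)
#'     or no extrema remain (`window_bound`);
#'   \item the energy of the original signal divided by the residual
#'     energy exceeds `energy_ratio_threshold` (`energy_ratio`);
#'   \item the energy difference between the two most recent IMFs,
#'     normalized by the original energy, drops below
#'     `energy_diff_threshold` (`energy_diff`);
#'   \item `max_imfs` modes have been extracted (`max_imfs`).
#' }
#'
#' By construction the decomposition is reconstruction-exact: the sum of
#' all IMFs plus the final residual telescopes back to the input.
#'
#' @param x A [signal_record()] (or bare numeric vector, in which case
#'   `fs` defaults to 1 Hz).
#' @param config A [gafd_config()].
#'
#' @return An object of class `gafd_decomposition` with elements
#'   \describe{
#'     \item{`imfs`}{list of numeric vectors, index 1 = highest
#'       frequency; possibly empty for an extremum-free input.}
#'     \item{`residual`}{final working signal (the trend).}
#'     \item{`rounds`}{data frame with per-round `imf`, `n_extrema`,
#'       `half_length`.}
#'     \item{`stop_reason`}{which criterion ended the loop.}
#'     \item{`fs`, `label`, `config`}{provenance.}
#'   }
#' @examples
#' t <- seq(0, 60, by = 0.01)[-1]
#' s <- signal_record(cos(2 * pi * 1.2 * t) + sin(2 * pi * 0.2 * t), fs = 100)
#' dec <- gafd(s)
#' dec
#' max(abs(s$samples - Reduce(`+`, dec$imfs) - dec$residual))  # ~0
#' @export
gafd <- function(x, config = gafd_config()) {
  if (is.numeric(x)) x <- signal_record(x, fs = 1)
  stopifnot(inherits(x, "signal_record"), inherits(config, "gafd_config"))
  s <- x$samples
  N <- length(s)
  E0 <- sum(s^2)

  working <- s
  imfs <- list()
  rounds <- list()
  imf_energy_prev <- NA_real_
  stop_reason <- NA_character_

  repeat {
    Ne <- count_local_extrema(working)
    M <- window_half_length(N, Ne, config$epsilon)
    if (is.na(M)) {
      stop_reason <- "window_bound"
      break
    }
    w <- gaussian_window(M, config$alpha)
    ext <- extend_signal(working, M, config$extension_style)
    m_i <- instantaneous_mean(ext, w)
    imf <- working - m_i
    imfs[[length(imfs) + 1L]] <- imf
    rounds[[length(rounds) + 1L]] <-
      data.frame(imf = length(imfs), n_extrema = Ne, half_length = M)
    working <- m_i

    imf_energy <- sum(imf^2)
    res_energy <- sum(working^2)
    if (E0 > 0 && (res_energy == 0 ||
                   E0 / res_energy > config$energy_ratio_threshold)) {
      stop_reason <- "energy_ratio"
      break
    }
    if (!is.na(imf_energy_prev) && E0 > 0 &&
        abs(imf_energy - imf_energy_prev) / E0 < config$energy_diff_threshold) {
      stop_reason <- "energy_diff"
      break
    }
    imf_energy_prev <- imf_energy
    if (length(imfs) >= config$max_imfs) {
      stop_reason <- "max_imfs"
      break
    }
  }

  structure(
    list(imfs = imfs, residual = working,
         rounds = if (length(rounds)) do.call(rbind, rounds)
                  else data.frame(imf = integer(), n_extrema = integer(),
                                  half_length = integer()),
         stop_reason = stop_reason,
         fs = x$fs, label = x$label, config = config),
    class = "gafd_decomposition"
  )
}

#' @export
print.gafd_decomposition <- function(x, ...) {
  cat(sprintf("gafd_decomposition: %d IMF(s) + residual, N = %d @ %g Hz, stop = %s\n",
              length(x$imfs), length(x$residual), x$fs, x$stop_reason))
  if (nrow(x$rounds)) print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.gafd_decomposition <- function(x, ...) {
  out <- as.data.frame(x$imfs, col.names = sprintf("imf_%d", seq_along(x$imfs)),
                       optional = TRUE)
  if (!length(x$imfs)) out <- data.frame(row.names = seq_along(x$residual))
  names(out) <- sprintf("imf_%d", seq_along(x$imfs))
  out$residual <- x$residual
  out
}

#' Reconstruct the input from a decomposition
#'
#' @param x A `gafd_decomposition`.
#' @return Numeric vector: the sum of all IMFs plus the residual.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "gafd_decomposition"))
  Reduce(`+`, x$imfs, init = x$residual)
}
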