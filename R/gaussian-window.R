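#' Discrete Gaussian smoothing window
#'
#' Builds the (2M+1)-tap discrete Gaussian window
#' \deqn{w[m] = \exp\{-( \alpha m / M )^2 / 2\}, \quad -M \le m \le M,}
#' normalized to unit sum, \eqn{w_G[m] = w[m] / \sum_l w[l]}.  The shape
#' parameter `alpha` is inversely proportional to the standard deviation
#' of the underlying Gaussian; `alpha >= 2.45` keeps the endpoint taps
#' below 5% of the central tap, and the package default 4.0728 pushes
#' them down to about 0.025%, so the discrete window behaves like a
#' truncation-free Gaussian (its spectrum is again Gaussian, i.e. a
#' monotone low-pass response).
#'
#' @param M Window half-length (positive integer); full length is 2M+1.
#' @param alpha Positive shape parameter.
#'
#' @return An object of class `gaussian_window`: a list with `M`,
#'   `alpha`, `coeffs` (normalized, length 2M+1) and `endpoint_ratio`
#'   (the unnormalized ratio `w[M]/w[0] = exp(-alpha^2/2)`).
#' @examples
#' w <- gaussian_window(10, 4.0728)
#' sum(w$coeffs)            # 1
#' 100 * w$endpoint_ratio   # ~0.025 (% of the central value)
#' @export
gaussian_window <- function(M, alpha = 4.0728) {
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != floor(M))
    stop("'M' must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar", call. = FALSE)
  m <- seq.int(-M, M)
  w <- exp(-(alpha * m / M)^2 / 2)
  structure(
    list(M = as.integer(M), alpha = alpha, coeffs = w / sum(w),
         endpoint_ratio = exp(-alpha^2 / 2)),
    class = "gaussian_window"
  )
}

#' @export
print.gaussian_window <- function(x, ...) {
  cat(sprintf("gaussian_window: 2M+1 = %d taps, alpha = %g, endpoint/center = %.4g%%\n",
              2L * x$M + 1L, x$alpha, 100 * x$endpoint_ratio))
  invisible(x)
}

#' Count strict local extrema of a sequence
#'
#' Interior sample `n` is an extremum when the first differences change
#' sign across it (the discrete second-derivative test):
#' `(s[n]-s[n-1]) * (s[n+1]-s[n]) < 0`.  Runs of equal samples
#' (plateaus) are collapsed and counted as a single extremum when the
#' slopes on either side of the run have opposite signs.  Endpoints are
#' never counted.  Sequences shorter than 3 samples have no interior and
#' return 0.
#'
#' @param x Numeric vector.
#' @return Nonnegative integer count of local maxima plus local minima.
#' @examples
#' count_local_extrema(c(0, 1, 0, -1, 0, 1, 0))  # 3
#' count_local_extrema(1:10)                     # 0
#' @export
count_local_extrema <- function(x) {
  if (length(x) < 3L) return(0L)
  d <- diff(x)
  d <- d[d != 0]                    # collapse plateaus
  if (length(d) < 2L) return(0L)
  sum(d[-length(d)] * d[-1L] < 0)
}

#' Adaptive window half-length from the extrema count
#'
#' The half-length for one sifting round is tied to the mean oscillation
#' scale of the working signal: `M = 2 * floor(epsilon * N / Ne)`, where
#' `N` is the signal length and `Ne` its number of local extrema.  The
#' window must also fit the record, `M < N/2 - 1`; when it does not (too
#' few extrema left), or when `Ne = 0` or `M < 1`, the decomposition has
#' reached its natural end and `NA` is returned to signal termination.
#'
#' @param N Signal length (>= 3).
#' @param Ne Number of local extrema (nonnegative integer).
#' @param epsilon Scale factor, typically in \[1.1, 3\] (default 1.8).
#' @return Positive integer half-length, or `NA_integer_` meaning the
#'   sifting loop must terminate.
#' @examples
#' window_half_length(2000, 40, 1.8)   # 180
#' window_half_length(2000, 2, 1.8)    # NA: window would exceed record
#' @export
window_half_length <- function(N, Ne, epsilon = 1.8) {
  if (!is.numeric(N) || length(N) != 1L || N < 3)
    stop("'N' must be a scalar >= 3", call. = FALSE)
  if (!is.numeric(Ne) || length(Ne) != 1L || Ne < 0)
    stop("'Ne' must be a nonnegative scalar", call. = FALSE)
  if (Ne == 0) return(NA_integer_)
  M <- 2 * floor(epsilon * N / Ne)
  if (M < 1 || M >= N / 2 - 1) return(NA_integer_)
  as.integer(M)
}

#' Extend a signal beyond its boundaries
#'
#' Pads `M` samples on each side ahead of the moving-average filtering,
#' so the smoothed output is defined over the full record.  Four styles:
#' \describe{
#'   \item{`constant`}{hold the boundary sample.}
#'   \item{`periodical`}{circular wrap-around.}
#'   \item{`reflection`}{mirror the amplitudes about the boundary sample
#'     (the boundary sample itself is not repeated).}
#'   \item{`double_symmetric_reflection`}{point reflection through the
#'     boundary sample, `s[-k] = 2 s[0] - s[k]`, mirroring both position
#'     and amplitude; this preserves the local slope across the boundary
#'     and is the default used by the decomposition because it suppresses
#'     boundary artifacts best.}
#' }
#'
#' @param x Numeric vector of length N.
#' @param M Pad width on each side (positive integer; reflection styles
#'   require `M < N`).
#' @param style One of `"constant"`, `"periodical"`, `"reflection"`,
#'   `"double_symmetric_reflection"`.
#' @return Numeric vector of length `N + 2M`; the interior `M+1 ... M+N`
#'   is the unchanged input.
#' @examples
#' extend_signal(c(1, 2, 3), 2, "constant")                    # 1 1 1 2 3 3 3
#' extend_signal(c(1, 2, 3), 2, "double_symmetric_reflection") # -1 0 1 2 3 4 5
#' @export
extend_signal <- function(x, M,
                          style = c("double_symmetric_reflection", "constant",
                                    "periodical", "reflection")) {
  style <- match.arg(style)
  N <- length(x)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != floor(M))
    stop("'M' must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  if (style %in% c("reflection", "double_symmetric_reflection") && M >= N)
    stop(sprintf("reflection padding requires M < N (M = %d, N = %d)", M, N),
         call. = FALSE)
  k <- seq_len(M)
  switch(style,
    constant = c(rep(x[1L], M), x, rep(x[N], M)),
    periodical = c(x[((-(M:1)) %% N) + 1L], x, x[((N + k - 1L) %% N) + 1L]),
    reflection = c(x[1L + rev(k)], x, x[N - k]),
    double_symmetric_reflection =
      c(2 * x[1L] - x[1L + rev(k)], x, 2 * x[N] - x[N - k])
  )
}

#' Gaussian moving-average (instantaneous mean) over the valid region
#'
#' Correlates the extended signal with the normalized Gaussian window and
#' keeps the `N` samples aligned with the original record:
#' \deqn{m[n] = \sum_{m=-M}^{M} w_G[m] \, s_e[n+m], \quad 0 \le n \le N-1.}
#' Because the window is symmetric this is the convolution sum, i.e. a
#' low-pass filtering of the extended signal.  Uses an FFT-based product
#' internally; it is linear in the input and exact to rounding.
#'
#' @param extended Numeric vector of length `N + 2M` from
#'   [extend_signal()].
#' @param window A [gaussian_window()] of half-length `M`.
#' @return Numeric vector of length `N`: the instantaneous mean.
#' @export
instantaneous_mean <- function(extended, window) {
  stopifnot(inherits(window, "gaussian_window"))
  N <- length(extended) - 2L * window$M
  if (N < 1L)
    stop("extended signal shorter than the window: need length N + 2M",
         call. = FALSE)
  # cross-correlation == convolution for a symmetric kernel
  as.numeric(stats::convolve(extended, window$coeffs, type = "filter"))
}
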