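# Brute-force oracles, kept independent of the implementation paths they
# check.

# O(N*M) double-loop moving average over the valid region
bf_moving_average <- function(extended, coeffs) {
  M <- (length(coeffs) - 1L) / 2L
  N <- length(extended) - 2L * M
  out <- numeric(N)
  for (n in seq_len(N)) {
    acc <- 0
    for (m in seq_len(2L * M + 1L)) acc <- acc + coeffs[m] * extended[n + m - 1L]
    out[n] <- acc
  }
  out
}

# O(N^2) explicit-DFT analytic signal: forward DFT by direct summation,
# one-sided doubling, inverse DFT by direct summation
bf_dft_analytic <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  X <- vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * k * n / N)), complex(1))
  h <- numeric(N)
  h[1] <- 1
  if (N %% 2 == 0) {
    h[N / 2 + 1] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[2:((N + 1) / 2)] <- 2
  }
  Z <- X * h
  vapply(0:(N - 1), function(m)
    sum(Z * exp(2i * pi * (0:(N - 1)) * m / N)) / N, complex(1))
}

# interior-triple scan, strict extrema only (no plateaus in the inputs
# it is used on)
bf_count_extrema <- function(x) {
  cnt <- 0L
  for (n in 2:(length(x) - 1)) {
    if ((x[n] > x[n - 1] && x[n] > x[n + 1]) ||
        (x[n] < x[n - 1] && x[n] < x[n + 1])) cnt <- cnt + 1L
  }
  cnt
}

# ICC(A,1) via stats::aov variance decomposition (independent of the
# closed-form sums in icc_a1)
bf_icc_aov <- function(est, ref) {
  n <- length(est)
  d <- data.frame(score = c(est, ref),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# dominant periodogram frequency of a vector, in Hz
pgram_peak <- function(x, fs) {
  pg <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  pg$freq[which.max(pg$spec)] * fs
}
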