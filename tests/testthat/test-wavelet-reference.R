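tone_record <- function(f0, duration = 60, fs = 100, amp = 1)
  signal_record(amp * sin(2 * pi * f0 * (0:(duration * fs - 1)) / fs), fs = fs)

test_that("a pure tone localizes at its own grid point in every time slice", {
  sc <- morlet_scalogram(tone_record(0.2))
  interior <- which(sc$time > 10 & sc$time < 50)
  hit <- apply(sc$Sc[interior, ], 1, which.max)
  expect_true(all(abs(sc$freq[hit] - 0.2) < 1e-9))
})

test_that("scalogram energy is quadratic in amplitude", {
  s1 <- morlet_scalogram(tone_record(0.15, duration = 30))
  s2 <- morlet_scalogram(tone_record(0.15, duration = 30, amp = 2))
  expect_equal(s2$Sc, 4 * s1$Sc, tolerance = 1e-9)
})

test_that("two tones produce two ridges at their grid points", {
  n <- 0:5999
  s <- signal_record(sin(2 * pi * 0.1 * n / 100) + sin(2 * pi * 0.3 * n / 100),
                     fs = 100)
  sbar <- time_averaged_spectrum(morlet_scalogram(s))
  freq <- seq(0.09, 0.35, by = 0.01)
  lo <- freq <= 0.2
  expect_equal(freq[lo][which.max(sbar[lo])], 0.1)
  expect_equal(freq[!lo][which.max(sbar[!lo])], 0.3)
})

test_that("time averaging equals per-column means by brute force", {
  sc <- morlet_scalogram(tone_record(0.12, duration = 20))
  sbar <- time_averaged_spectrum(sc)
  for (j in seq_along(sc$freq))
    expect_equal(sbar[j], mean(sc$Sc[, j]))
  # separable surface: outer product collapses to mean(u) * v
  sc$Sc <- outer(seq_len(nrow(sc$Sc)) / 10, seq_along(sc$freq) + 0.5)
  expect_equal(time_averaged_spectrum(sc),
               mean(seq_len(nrow(sc$Sc)) / 10) * (seq_along(sc$freq) + 0.5))
})

test_that("the band-limited argmax converts peak frequency to bpm", {
  freq <- seq(0.09, 0.35, by = 0.01)
  s_c <- exp(-((freq - 0.20) / 0.02)^2)
  expect_equal(rr_from_spectrum(s_c, freq)$rr_bpm, 12)
  s_c <- exp(-((freq - 0.35) / 0.02)^2)
  expect_equal(rr_from_spectrum(s_c, freq)$rr_bpm, 21)
  flat <- rr_from_spectrum(rep(1, length(freq)), freq)
  expect_true(flat$low_confidence)
  expect_equal(flat$peak_freq, 0.09)   # lowest-frequency convention
})

test_that("a synthetic respiration channel is read back to one grid step", {
  spec <- synth_spec(duration = 60, rr_bpm = 9)
  ref <- rr_reference(make_resp(spec))
  expect_lt(abs(ref$rr_bpm - 9), 0.6 + 1e-12)
  # grid-aligned tones: error bounded by half a grid step
  for (f0 in c(0.10, 0.20, 0.30))
    expect_lt(abs(rr_reference(tone_record(f0))$rr_bpm - 60 * f0), 0.3 + 1e-12)
})

test_that("scalogram matches a direct time-domain wavelet convolution", {
  # independent oracle: sampled cmor kernel, explicit convolution sum
  fs <- 20; f0 <- 0.2; N <- 1200
  n0 <- 0:(N - 1)
  x <- sin(2 * pi * f0 * n0 / fs) * (1 + 0.3 * sin(2 * pi * 0.02 * n0 / fs))
  a <- 1 / f0                                    # scale for C = 1
  tk <- seq(-4 * a, 4 * a, by = 1 / fs)          # exp(-16) truncation
  psi <- exp(2i * pi * tk / a) * exp(-(tk / a)^2)
  half <- (length(tk) - 1) / 2
  w_bf <- rep(NA_real_, N)
  for (n in (half + 1):(N - half))
    w_bf[n] <- Mod(sum(x[(n - half):(n + half)] * Conj(psi)))^2
  sc <- morlet_scalogram(signal_record(x, fs = fs), rr_band(0.19, 0.21),
                         df = 0.01)
  mid <- (half + 50):(N - half - 50)
  ratio <- sc$Sc[mid, 2] / w_bf[mid]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.01)  # proportional surfaces
})

test_that("estimator and reference agree within 1 bpm on noiseless pairs", {
  for (rr in c(7, 11, 14)) {
    spec <- synth_spec(duration = 60, rr_bpm = rr, seed = rr)
    est <- estimate_rr(make_ppg_surrogate(spec)$signal)$rr_bpm
    ref <- rr_reference(make_resp(spec))$rr_bpm
    expect_lt(abs(est - ref), 1)
  }
})

test_that("invalid scalogram requests are refused", {
  expect_error(morlet_scalogram(tone_record(0.2, duration = 5)), ">=")
  s <- tone_record(0.2, duration = 60, fs = 0.5)
  expect_error(morlet_scalogram(s, rr_band(0.09, 0.35)), "Nyquist")
})
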