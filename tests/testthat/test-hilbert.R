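test_that("the analytic signal of a cosine has its sine in quadrature", {
  n <- 0:5999
  x <- cos(2 * pi * 0.2 * n / 100)
  a <- analytic_signal(x, fs = 100)
  interior <- 200:5800
  expect_lt(max(abs(a$y[interior] - sin(2 * pi * 0.2 * n[interior] / 100))),
            0.01)
  expect_lt(max(abs(a$amplitude[interior] - 1)), 0.01)
})

test_that("the FFT construction matches the explicit-DFT oracle", {
  set.seed(41)
  for (N in c(32L, 33L)) {            # even and odd Nyquist handling
    x <- rnorm(N)
    z <- bf_dft_analytic(x)
    a <- analytic_signal(x, fs = 1)
    expect_lt(max(abs(a$y - Im(z))), 1e-10)
    expect_lt(max(abs(a$amplitude - Mod(z))), 1e-10)
    expect_lt(max(abs(a$x - Re(z))), 1e-10)
  }
})

test_that("constant input degenerates gracefully", {
  expect_warning(a <- analytic_signal(rep(2, 64), fs = 10), "constant")
  expect_equal(a$amplitude, rep(2, 64))
  expect_equal(a$phase, rep(0, 64))
  expect_true(a$degenerate)
})

test_that("instantaneous frequency recovers linear and quadratic phase laws", {
  fs <- 100
  n <- 0:999
  f <- instantaneous_frequency(2 * pi * 0.2 * n / fs, fs)
  expect_equal(f[2:999], rep(0.2, 998), tolerance = 1e-12)
  expect_equal(instantaneous_frequency(rep(1.3, 100), fs), rep(0, 100))
  # chirp: theta = 2*pi*(0.1 t + 0.001 t^2) -> f = 0.1 + 0.002 t
  t <- n / fs
  theta <- 2 * pi * (0.1 * t + 0.001 * t^2)
  f <- instantaneous_frequency(theta, fs)
  expect_lt(max(abs(f[2:999] - (0.1 + 0.002 * t[2:999]))), 1e-6)
  expect_error(instantaneous_frequency(1, fs), "length")
})

test_that("a pure tone's interior instantaneous frequency is within 1%", {
  fs <- 100
  x <- cos(2 * pi * 0.2 * (0:5999) / fs)   # 12 cycles in 60 s
  a <- analytic_signal(x, fs = fs)
  interior <- 600:5400
  expect_lt(abs(mean(a$inst_freq[interior]) - 0.2) / 0.2, 0.01)
})

test_that("spectrum binning concentrates a tone and conserves energy", {
  fs <- 100
  a <- analytic_signal(cos(2 * pi * 0.2 * (0:5999) / fs), fs = fs, index = 1L)
  hs <- hilbert_spectrum(list(a), df_h = 0.01, fmax = 0.5)
  total <- sum(a$amplitude^2)
  expect_equal(sum(hs$H) + sum(hs$overflow), total, tolerance = 1e-9)
  bin_02 <- floor(0.2 / 0.01) + 1L
  expect_gt(sum(hs$H[, bin_02]) / total, 0.95)
})

test_that("spectrum layers are additive", {
  fs <- 100
  n <- 0:1999
  a1 <- analytic_signal(cos(2 * pi * 0.1 * n / fs), fs = fs, index = 1L)
  a2 <- analytic_signal(cos(2 * pi * 0.3 * n / fs), fs = fs, index = 2L)
  h12 <- hilbert_spectrum(list(a1, a2), df_h = 0.01, fmax = 0.5)
  h1 <- hilbert_spectrum(list(a1), df_h = 0.01, fmax = 0.5)
  h2 <- hilbert_spectrum(list(a2), df_h = 0.01, fmax = 0.5)
  expect_equal(h12$H, h1$H + h2$H)
  expect_equal(spectrum_layer(h12, 1) + spectrum_layer(h12, 2), h12$H)
})

test_that("energy conservation holds with out-of-grid overflow on real modes", {
  spec <- synth_spec(duration = 30, rr_bpm = 12, seed = 5)
  s <- make_ppg_surrogate(spec)$signal
  dec <- gafd(s)
  al <- lapply(seq_along(dec$imfs), function(i)
    analytic_signal(dec$imfs[[i]], fs = s$fs, index = i))
  hs <- hilbert_spectrum(al, df_h = 0.01, fmax = 2)
  total <- sum(vapply(al, function(a) sum(a$amplitude^2), numeric(1)))
  expect_equal(sum(hs$H) + sum(hs$overflow), total, tolerance = 1e-9)
  expect_true(all(hs$H >= 0))
})

test_that("amplitude weighting deposits a instead of a^2", {
  a <- analytic_signal(cos(2 * pi * 0.2 * (0:799) / 100), fs = 100, index = 1L)
  he <- hilbert_spectrum(list(a), df_h = 0.01, fmax = 0.5, weighting = "energy")
  ha <- hilbert_spectrum(list(a), df_h = 0.01, fmax = 0.5,
                         weighting = "amplitude")
  expect_equal(sum(ha$H) + sum(ha$overflow), sum(a$amplitude), tolerance = 1e-9)
  expect_equal(sum(he$H) + sum(he$overflow), sum(a$amplitude^2),
               tolerance = 1e-9)
})

test_that("degenerate spectrum inputs are rejected", {
  expect_error(hilbert_spectrum(list()), "nonempty")
  a <- analytic_signal(rnorm(64), fs = 10, index = 1L)
  expect_error(hilbert_spectrum(list(a), df_h = 0), "positive")
})
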