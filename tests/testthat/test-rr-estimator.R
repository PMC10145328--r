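make_summary <- function(idx, m, s) data.frame(imf_index = idx, mean_freq = m,
                                               std_freq = s)

test_that("instantaneous-frequency moments use the N-1 denominator", {
  a <- structure(list(index = 1L, inst_freq = rep(0.2, 100), fs = 100),
                 class = "analytic_imf")
  sm <- summarize_if(a)
  expect_equal(sm$mean_freq, 0.2)
  expect_equal(sm$std_freq, 0)
  a$inst_freq <- c(0.1, 0.3)
  sm <- summarize_if(a)
  expect_equal(sm$mean_freq, 0.2)
  expect_equal(sm$std_freq, sqrt(0.02), tolerance = 1e-12)  # ~0.1414
})

test_that("moments of seeded noisy frequencies match their population values", {
  set.seed(55)
  a <- structure(list(index = 2L, inst_freq = rnorm(1000, 0.2, 0.02), fs = 100),
                 class = "analytic_imf")
  sm <- summarize_if(a)
  expect_lt(abs(sm$mean_freq - 0.2), 0.002)
  expect_lt(abs(sm$std_freq - 0.02) / 0.02, 0.15)
})

test_that("band screening is inclusive and order-preserving", {
  sm <- make_summary(1:4, c(1.2, 0.45, 0.21, 0.07), c(0.2, 0.1, 0.05, 0.02))
  kept <- screen_candidates(sm, rr_band(0.09, 0.35))
  expect_identical(kept$imf_index, 3L)
  edge <- make_summary(1:2, c(0.09, 0.35), c(0.1, 0.1))
  expect_identical(nrow(screen_candidates(edge, rr_band())), 2L)
  empty <- make_summary(integer(), numeric(), numeric())
  expect_identical(nrow(screen_candidates(empty, rr_band())), 0L)
})

test_that("selection takes the minimum-std candidate, ties to lower index", {
  single <- make_summary(3L, 0.2, 0.05)
  expect_equal(60 * select_respiratory(single)$mean_freq, 12)
  two <- make_summary(c(2L, 4L), c(0.15, 0.2), c(0.05, 0.01))
  expect_identical(select_respiratory(two)$imf_index, 4L)
  tie_a <- make_summary(c(2L, 5L), c(0.15, 0.2), c(0.03, 0.03))
  tie_b <- tie_a[2:1, ]
  expect_identical(select_respiratory(tie_a)$imf_index, 2L)
  expect_identical(select_respiratory(tie_b)$imf_index, 2L)
  expect_error(select_respiratory(tie_a[0, ]), "no candidate")
})

test_that("a noiseless surrogate at 12 bpm is recovered within 1 bpm", {
  spec <- synth_spec(duration = 60, rr_bpm = 12, seed = 1)
  est <- estimate_rr(make_ppg_surrogate(spec)$signal)
  expect_identical(est$status, "ok")
  expect_lt(abs(est$rr_bpm - 12), 1)
  expect_true(est$selected_imf %in% est$candidates$imf_index)
  expect_true(est$rr_bpm / 60 >= 0.09 && est$rr_bpm / 60 <= 0.35)
})

test_that("records shorter than one slow respiratory cycle are refused", {
  spec <- synth_spec(duration = 10, rr_bpm = 12, seed = 2)
  s <- make_ppg_surrogate(spec)$signal
  expect_error(estimate_rr(s), "11.11 s")
  # above the cycle bound but under 20 s: accepted with a warning
  spec2 <- synth_spec(duration = 15, rr_bpm = 12, seed = 2)
  expect_warning(est <- estimate_rr(make_ppg_surrogate(spec2)$signal), "20 s")
  expect_identical(est$status, "ok")
})

test_that("a record with no respiratory content yields no candidate", {
  s <- signal_record(cos(2 * pi * 1.2 * (0:5999) / 100), fs = 100)
  est <- estimate_rr(s)
  expect_identical(est$status, "no_candidate")
  expect_true(is.na(est$rr_bpm))
})

test_that("windowed estimation segments without overlap and drops remainders", {
  spec <- synth_spec(duration = 60, rr_bpm = 12, seed = 3)
  s60 <- make_ppg_surrogate(spec)$signal
  expect_identical(nrow(estimate_rr_windowed(s60, 20)), 3L)
  spec <- synth_spec(duration = 120, rr_bpm = 10, seed = 3)
  s120 <- make_ppg_surrogate(spec)$signal
  w <- estimate_rr_windowed(s120, 20)
  expect_identical(nrow(w), 6L)
  expect_equal(w$window_start_s, seq(0, 100, by = 20))
  spec <- synth_spec(duration = 59, rr_bpm = 12, seed = 3)
  s59 <- make_ppg_surrogate(spec)$signal
  expect_identical(nrow(estimate_rr_windowed(s59, 20)), 2L)
  expect_error(estimate_rr_windowed(s60, 5), "at least")
})

test_that("estimation is deterministic: identical input, identical output", {
  spec <- synth_spec(duration = 40, rr_bpm = 15, seed = 9)
  s <- make_ppg_surrogate(spec)$signal
  e1 <- estimate_rr(s)
  e2 <- estimate_rr(s)
  expect_identical(e1, e2)
})

test_that("rates across the respiration band are recovered with low bias", {
  # 54 synthetic records: 6 paced rates x 9 seeds, noiseless, 60 s
  grid <- c(6, 8, 10, 12, 15, 18)
  err <- unlist(lapply(grid, function(rr) {
    sapply(1:9, function(seed) {
      spec <- synth_spec(duration = 60, rr_bpm = rr,
                         am_depth = 0.2 + 0.02 * seed, seed = seed)
      estimate_rr(make_ppg_surrogate(spec)$signal)$rr_bpm - rr
    })
  }))
  expect_lt(mean(abs(err)), 1)         # MAE within 1 bpm
  expect_lt(abs(mean(err)), 0.5)       # near-zero bias
})

test_that("windowed estimates track a paced rate change", {
  sched <- data.frame(start_s = c(0, 60), rr_bpm = c(6, 10))
  spec <- synth_spec(duration = 120, rr_bpm = sched, seed = 13)
  s <- make_ppg_surrogate(spec)$signal
  w <- estimate_rr_windowed(s, 20)
  first_min <- w$rr_bpm[w$window_start_s < 60]
  second_min <- w$rr_bpm[w$window_start_s >= 60]
  expect_lt(max(abs(first_min - 6)), 1)
  # second minute moves toward 10 bpm by at least half the step
  expect_true(all(second_min >= 8))
})

test_that("band bounds must be ordered and positive", {
  expect_error(rr_band(0.4, 0.35), "frL < frU")
  expect_error(rr_band(0, 0.35), "frL < frU")
})
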