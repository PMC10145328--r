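# hgt — Hilbert–Gauss transform for respiratory-rate estimation

`hgt` estimates respiratory rate (RR, breaths per minute) from a single
cardiac-dominated channel — finger or wrist photoplethysmography (PPG) or
a seismocardiogram (SCG) — by adaptive signal decomposition and Hilbert
spectral analysis.  It is aimed at researchers in physiological monitoring
who need a unified, tuning-light RR pathway across heterogeneous signal
sources, together with the reference estimator and agreement statistics
used to validate one.

## The method

**Gaussian average filtering decomposition (GAFD).**  An EMD-style sifting
loop whose primitive is a normalized discrete Gaussian moving average
instead of spline envelopes.  With window half-length *M* and shape
parameter α (default 4.0728, endpoint taps ≈ 0.025 % of the center):

    w[m] = exp(−(α·m/M)²/2),   w_G[m] = w[m] / Σ w[l],   −M ≤ m ≤ M

Each round sets *M* adaptively from the working signal's extrema count,
M = 2·⌊ε·N/Ne⌋ (ε default 1.8), extends the signal across its boundaries
by double-symmetric (point) reflection, subtracts the Gaussian
moving-average trend, and emits the difference as the next intrinsic mode
function (IMF); the loop recurses on the trend until the window no longer
fits (M ≥ N/2 − 1) or an energy stop criterion fires.  The modes plus
residual reconstruct the input exactly.

**Hilbert spectral analysis and the RR rule.**  Each IMF becomes an
analytic signal z = x + jH{x} = a·e^{jθ}; instantaneous frequency is the
unwrapped-phase gradient, f = fs·ω/2π.  Modes whose mean instantaneous
frequency lies in the respiration band (defaults 0.09–0.35 Hz, i.e.
5.4–21 bpm) are candidates; among several, the one with the smallest
frequency standard deviation — the most frequency-stable in-band
component — wins, and RR = 60·f̄.

**Validation machinery.**  A complex-Morlet scalogram reference estimator
for respiration-belt channels (time-averaged spectrum, band-limited argmax
at 0.01 Hz resolution), ICC(A,1) (two-way, absolute agreement, single
measure, with F-based confidence interval), Bland–Altman limits of
agreement, and a synthetic generator producing respiration-modulated
cardiac surrogates with paced-rate schedules and calibrated white noise.

## Worked example

A 120-s wrist-PPG surrogate, paced at 6 bpm for the first minute and
10 bpm for the second, with 10 dB additive white Gaussian noise; RR is
estimated on non-overlapping 20-s windows and compared with the
wavelet-reference rate of the (clean) respiration channel per minute:

```r
library(hgt)

sched <- data.frame(start_s = c(0, 60), rr_bpm = c(6, 10))
spec  <- synth_spec(duration = 120, rr_bpm = sched, snr_db = 10, seed = 42)
out   <- make_ppg_surrogate(spec)

est  <- estimate_rr_windowed(out$signal, window_s = 20)
resp <- make_resp(synth_spec(duration = 120, rr_bpm = sched))
ref  <- sapply(0:1, function(k)
  rr_reference(signal_record(resp$samples[(k*6000+1):((k+1)*6000)],
                             fs = 100))$rr_bpm)
cbind(est[c("window_start_s", "rr_bpm", "status")], ref_bpm = rep(ref, each = 3))
#>   window_start_s rr_bpm status ref_bpm
#> 1              0  5.950     ok     6.0
#> 2             20  5.977     ok     6.0
#> 3             40  6.022     ok     6.0
#> 4             60  9.657     ok    10.2
#> 5             80  9.893     ok    10.2
#> 6            100 10.045     ok    10.2

bland_altman(est$rr_bpm, rep(ref, each = 3))
#> Bland-Altman: bias -0.1760 +/- 0.2149, LoA [-0.5972, 0.2453], r = 0.9983 (n = 6)
icc_a1(est$rr_bpm, rep(ref, each = 3))
#> ICC(A,1) = 0.9929, 95% CI [0.9332, 0.9990]  (n = 6 pairs)
```

The windowed estimates track the paced change within a fraction of a
breath per minute; the small bias against the reference is dominated by
the reference's own 0.6-bpm grid granularity.  Limits of agreement well
inside ±1 bpm and an ICC above 0.99 are what "excellent agreement" looks
like at this scale.

Per-mode diagnostics are available from the lower-level functions:
`gafd()` returns the IMFs with per-round window sizes and the stop
reason, `analytic_signal()` the amplitude/phase/frequency tracks, and
`hilbert_spectrum()` the binned time-frequency-energy surface.

## Command line

A thin CLI over the same functions lives at `inst/cli/hgt.R`:

```sh
Rscript inst/cli/hgt.R synth --kind ppg --rr 12 --duration 60 --seed 7 --out x.csv
Rscript inst/cli/hgt.R rr --input x.csv --window 20 --out rr.csv
Rscript inst/cli/hgt.R refrr --input resp.csv
Rscript inst/cli/hgt.R decompose --input x.csv --out dec.csv
Rscript inst/cli/hgt.R agree --pairs pairs.csv --group-col label
```

Exit codes: 0 ok, 2 bad input, 3 no respiratory candidate.

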