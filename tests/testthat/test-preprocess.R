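fs <- 100
cfg <- preprocess_config()

test_that("low-pass filter has unit DC gain, flat passband, deep stopband", {
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  interior <- 500:(n - 500)

  const <- lowpass_filter(rep(2, n), fs, cfg)
  expect_lt(max(abs(const[interior] - 2)), 1e-6)

  tone25 <- lowpass_filter(sin(2 * pi * 25 * t), fs, cfg)
  expect_lt(sqrt(mean(tone25[interior]^2)) / sqrt(0.5), 0.01)

  tone1 <- lowpass_filter(sin(2 * pi * 1 * t), fs, cfg)
  amp <- (max(tone1[interior]) - min(tone1[interior])) / 2
  expect_equal(amp, 1.0, tolerance = 0.01)

  expect_error(lowpass_filter(rnorm(250), fs, cfg), "too short")
})

test_that("wavelet baseline removal restores drift-contaminated pulse", {
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  expect_equal(remove_baseline(rep(0, n), fs, cfg), rep(0, n),
               tolerance = 1e-12)

  st <- physio_state()
  rec <- generate_ppg(st, noise = noise_off(), duration = 60, seed = 4)
  clean <- rec$signals[, 1] - mean(rec$signals[, 1])
  ac_amp <- (max(clean) - min(clean))
  drift <- 5 * ac_amp * sin(2 * pi * 0.05 * t)
  out <- remove_baseline(clean + drift, fs, cfg)
  expect_length(out, n)
  expect_gt(cor(out, clean), 0.99)

  pure_drift <- sin(2 * pi * 0.05 * t)
  expect_lt(sqrt(mean(remove_baseline(pure_drift, fs, cfg)^2)) /
              sqrt(mean(pure_drift^2)), 0.10)
})

test_that("cardiac period estimation locks to the fundamental", {
  t <- (0:(60 * fs - 1)) / fs
  est <- estimate_period(sin(2 * pi * 1.2 * t), fs, cfg)
  expect_lt(abs(est$fundamental - 1.2), 0.02)
  expect_equal(est$period, round(fs / 1.2))

  # synthetic PPG at 72 bpm -> 1.2 Hz
  rec <- generate_ppg(physio_state(heart_rate = 72), noise = noise_off(),
                      duration = 60, seed = 2)
  x <- remove_baseline(lowpass_filter(rec$signals[, 1], fs, cfg), fs, cfg)
  expect_lt(abs(estimate_period(x, fs, cfg)$fundamental - 1.2), 0.05)

  # strong out-of-band tone must not steal the peak
  two <- sin(2 * pi * 1.2 * t) + 3 * sin(2 * pi * 0.3 * t)
  expect_lt(abs(estimate_period(two, fs, cfg)$fundamental - 1.2), 0.02)

  expect_error(estimate_period(rnorm(60 * fs), fs, cfg), "no clear spectral peak")
})

test_that("comb filter passes periodic signals and averages noise", {
  period <- 80
  t <- 0:(40 * period - 1)
  x <- sin(2 * pi * t / period) + 0.3 * sin(4 * pi * t / period)
  y <- comb_filter(x, period, M = 4)
  interior <- (3 * period + 1):length(x)
  expect_lt(max(abs(y[interior] - x[interior])), 1e-9)
  expect_length(y, length(x))

  set.seed(8)
  noise <- rnorm(length(x), sd = 0.1)
  yn <- comb_filter(x + noise, period, M = 4)
  resid <- (yn - x)[interior]
  expect_equal(sd(resid), 0.05, tolerance = 0.1)   # sigma / sqrt(4)

  spike <- numeric(length(x))
  spike[10 * period + 3] <- 1
  ys <- comb_filter(x + spike, period, M = 4)
  expect_equal(ys[10 * period + 3] - x[10 * period + 3], 0.25,
               tolerance = 1e-9)

  expect_error(comb_filter(x[1:100], 50), "third of the signal")
})

test_that("full preprocessing is near-identity on clean input and stable", {
  rec <- generate_ppg(physio_state(), noise = noise_off(), duration = 30,
                      seed = 5)
  x <- rec$signals[, 1]
  out1 <- preprocess_channel(x, fs, cfg)
  expect_length(out1$ac_source, length(x))
  expect_length(out1$dc_source, length(x))
  expect_gt(cor(out1$ac_source, x - mean(x)), 0.999)

  out2 <- preprocess_channel(x, fs, cfg)
  expect_identical(out1$ac_source, out2$ac_source)
})

test_that("noisy channel keeps its AC/DC within 5% of the clean truth", {
  st <- physio_state()
  clean <- generate_ppg(st, noise = noise_off(), duration = 60, seed = 6)
  noisy <- generate_ppg(st, noise = noise_config(), duration = 60, seed = 6)
  pc <- preprocess_record(clean)
  pn <- preprocess_record(noisy)
  acdc <- function(pp, k) {
    aw <- segment_windows(pp$channels[[k]]$ac_source, fs, 5)
    dw <- segment_windows(pp$channels[[k]]$dc_source, fs, 5)
    v <- vapply(seq_along(aw), function(w) {
      p <- extract_ac_dc(aw[[w]], dw[[w]], fs)
      if (p$valid) p$ac / p$dc else NA_real_
    }, 0)
    median(v, na.rm = TRUE)
  }
  for (k in c(1, 8))
    expect_equal(acdc(pn, k), acdc(pc, k), tolerance = 0.05)
})

test_that("linear stages are linear and baseline removal is near-idempotent", {
  set.seed(9)
  x <- rnorm(3000); y <- rnorm(3000)
  lin <- function(f) {
    expect_equal(f(2 * x - 0.5 * y), 2 * f(x) - 0.5 * f(y), tolerance = 1e-9)
  }
  lin(function(v) lowpass_filter(v, fs, cfg))
  lin(function(v) remove_baseline(v, fs, cfg))

  rec <- generate_ppg(physio_state(), noise = noise_config(), duration = 30,
                      seed = 10)
  once <- remove_baseline(rec$signals[, 1], fs, cfg)
  twice <- remove_baseline(once, fs, cfg)
  expect_lt(abs(sqrt(mean(twice^2)) - sqrt(mean(once^2))),
            0.01 * sqrt(mean(once^2)))
})
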