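test_that("theoretical ratio follows the two-chromophore absorbance model", {
  st <- physio_state(hb_total = 12, spo2 = 0.95)

  # identical extinction pairs at both wavelengths -> ratio 1
  opt_eq <- optical_config(ext_oxy = rep(500, 8), ext_deoxy = rep(1500, 8))
  expect_equal(theoretical_ratio(1, 5, st, opt_eq), 1.0)

  # fully oxygenated blood: only the oxy extinction spectrum remains
  opt <- optical_config()
  st100 <- physio_state(hb_total = 12, spo2 = 1.0)
  expect_equal(theoretical_ratio(2, 7, st100, opt),
               opt$ext_oxy[2] / opt$ext_oxy[7])

  # reciprocal identity for arbitrary states
  for (pair in list(c(1, 2), c(3, 8), c(5, 4))) {
    expect_equal(theoretical_ratio(pair[1], pair[2], st, opt) *
                   theoretical_ratio(pair[2], pair[1], st, opt), 1.0)
  }

  expect_error(theoretical_ratio(3, 3, st, opt), "invalid pair")
})

test_that("theoretical ratios are independent of path amplitude and intensity", {
  st <- physio_state(hb_total = 9, spo2 = 0.92)
  base <- optical_config()
  scaled <- optical_config(path_pulse_amplitude = base$path_pulse_amplitude * 100,
                           incident_intensity = base$incident_intensity * 100)
  expect_equal(theoretical_ratios(st, base), theoretical_ratios(st, scaled),
               tolerance = 1e-12)
})

test_that("generated PPG has the Beer-Lambert AC/DC amplitude per channel", {
  st <- physio_state(hb_total = 14, spo2 = 0.97, heart_rate = 72)
  opt <- optical_config()
  rec <- generate_ppg(st, opt, noise_off(), duration = 30, seed = 1)
  r_lambda <- (opt$ext_oxy * st$c1 + opt$ext_deoxy * st$c2) *
    opt$path_pulse_amplitude

  period <- round(rec$fs * 60 / st$heart_rate)
  for (k in c(1, 4, 8)) {
    x <- rec$signals[, k]
    # per-cycle (max - min) / mean against the closed-form swing r_lambda;
    # mean(1 - r*pulse) != 1, hence the 2% headroom
    cyc <- x[1:period]
    expect_equal((max(cyc) - min(cyc)) / mean(cyc), r_lambda[k],
                 tolerance = 0.02)
  }
})

test_that("ppg generation is a pure function of its seed", {
  st <- physio_state()
  a <- generate_ppg(st, duration = 12, seed = 7)
  b <- generate_ppg(st, duration = 12, seed = 7)
  expect_identical(a$signals, b$signals)
  c <- generate_ppg(st, duration = 12, seed = 8)
  expect_false(identical(a$signals, c$signals))
})

test_that("AC/DC swing is linear in total hemoglobin", {
  opt <- optical_config()
  rec14 <- generate_ppg(physio_state(14, 0.95), opt, noise_off(),
                        duration = 12, seed = 2)
  rec7 <- generate_ppg(physio_state(7, 0.95), opt, noise_off(),
                       duration = 12, seed = 2)
  swing <- function(rec, k) {
    x <- rec$signals[, k]
    (max(x) - min(x)) / mean(x)
  }
  for (k in c(1, 6))
    expect_equal(swing(rec14, k) / swing(rec7, k), 2.0, tolerance = 0.02)
})

test_that("cohort generation respects size, sampler, and metadata ranges", {
  coh <- generate_cohort(5, duration = 12, seed = 1)
  expect_length(coh, 5)
  for (s in coh) {
    expect_s3_class(s$ppg, "ppg_record")
    expect_identical(dim(s$ppg$signals), c(1200L, 8L))
    expect_true(s$age >= 18 && s$age <= 90)
    expect_true(s$gender %in% c(0L, 1L))
    expect_true(s$hb_ref > 4 && s$hb_ref < 22)
  }
  expect_error(generate_cohort(0), "n must be >= 1")

  # point-mass sampler propagates exactly
  pm <- generate_cohort(4, hb_sampler = function(n) rep(14, n),
                        duration = 12, seed = 2)
  expect_equal(vapply(pm, `[[`, 0, "hb_ref"), rep(14, 4))
})

test_that("hemoglobin sampler matches its analytic mixture mean", {
  # 0.8 * N(14, 1) + 0.2 * U(7, 19): mean 0.8*14 + 0.2*13 = 13.8
  set.seed(123)
  x <- hb_sampler_default(10000)
  analytic_mean <- 0.8 * 14 + 0.2 * 13
  analytic_var <- 0.8 * (1 + 14^2) + 0.2 * (12^2 / 12 + 13^2) - analytic_mean^2
  se <- sqrt(analytic_var / 10000)
  expect_lt(abs(mean(x) - analytic_mean), 3 * se)
  expect_true(all(x > 4 & x < 22))
})

test_that("cohorts round-trip through the on-disk CSV format", {
  coh <- generate_cohort(3, duration = 12, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  expect_equal(back[[2]]$hb_ref, coh[[2]]$hb_ref)
  expect_equal(back[[2]]$ppg$wavelengths, coh[[2]]$ppg$wavelengths)
  expect_equal(back[[2]]$ppg$signals, coh[[2]]$ppg$signals,
               ignore_attr = TRUE, tolerance = 1e-12)
})
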