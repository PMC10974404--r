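fs <- 100

test_that("windowing drops trailing partial windows", {
  expect_length(segment_windows(numeric(120 * fs), fs, 5), 24)
  w <- segment_windows(numeric(7 * fs), fs, 5)
  expect_length(w, 1)
  expect_length(w[[1]], 500)
  expect_length(segment_windows(numeric(4 * fs), fs, 5), 0)
})

test_that("AC/DC extraction reads constructed amplitudes", {
  t <- (0:(5 * fs - 1)) / fs
  pulse <- 0.5 - 0.5 * cos(2 * pi * 1.2 * t)   # unit-range pulse train
  win <- 2.0 + 0.1 * pulse
  p <- extract_ac_dc(win, win, fs)
  expect_true(p$valid)
  expect_equal(p$ac, 0.1, tolerance = 0.05)
  expect_equal(p$dc, mean(win), tolerance = 0.01)

  # constant window: no cycles
  pc <- extract_ac_dc(rep(2, 5 * fs), rep(2, 5 * fs), fs)
  expect_false(pc$valid)

  # homogeneity: scaling both sources scales ac and dc, ac/dc invariant
  p3 <- extract_ac_dc(3 * win, 3 * win, fs)
  expect_equal(p3$ac, 3 * p$ac, tolerance = 1e-9)
  expect_equal(p3$dc, 3 * p$dc, tolerance = 1e-9)
  expect_equal(p3$ac / p3$dc, p$ac / p$dc, tolerance = 1e-9)

  expect_error(extract_ac_dc(win, win - 10, fs), "non-positive DC")
})

test_that("ratio features follow the fixed ordered-pair layout", {
  idx <- ratio_pair_index(8)
  expect_equal(nrow(idx), 56)
  expect_equal(idx$i[1:7], rep(1, 7))
  expect_equal(idx$j[1:7], 2:8)
  expect_equal(unlist(idx[56, ]), c(i = 8, j = 7))

  r <- compute_ratios(rep(0.02, 8), rep(1, 8))
  expect_length(r, 56)
  expect_true(all(r == 1))

  ac <- c(0.02, 0.04, rep(0.03, 6)); dc <- rep(1, 8)
  r2 <- compute_ratios(ac, dc)
  expect_equal(unname(r2["R_610_630"]), 0.5)
  expect_equal(unname(r2["R_630_610"]), 2.0)

  expect_error(compute_ratios(c(0, rep(0.02, 7)), dc), "degenerate")
})

test_that("reciprocity holds for every extracted feature vector", {
  rec <- make_record(hb = 11, spo2 = 0.95, seed = 21)
  fv <- build_feature_vector(rec)
  idx <- ratio_pair_index(8)
  key <- paste(idx$i, idx$j)
  rev_pos <- match(paste(idx$j, idx$i), key)
  expect_equal(unname(fv[1:56] * fv[1:56][rev_pos]), rep(1, 56),
               tolerance = 1e-9)
})

test_that("noiseless records reproduce the closed-form ratios within 2%", {
  rec <- make_record(hb = 14, spo2 = 0.97, seed = 3, duration = 60)
  fv <- build_feature_vector(rec)
  expect_length(fv, 58)
  expect_equal(unname(fv[57:58]), c(40, 1))
  th <- theoretical_ratios(rec$state)
  expect_lt(max(abs(fv[1:56] / th - 1)), 0.02)
})

test_that("ratios are invariant to per-channel intensity scaling", {
  rec <- make_record(seed = 22)
  fv <- build_feature_vector(rec)
  rec2 <- rec
  rec2$ppg$signals[, 3] <- 7.5 * rec2$ppg$signals[, 3]
  rec2$ppg$signals[, 6] <- 0.2 * rec2$ppg$signals[, 6]
  fv2 <- build_feature_vector(rec2)
  expect_equal(unname(fv2[1:56]), unname(fv[1:56]), tolerance = 1e-6)
})

test_that("degenerate records are rejected", {
  rec <- make_record(seed = 23, duration = 12)
  rec$ppg$signals[] <- 1.0
  expect_error(build_feature_vector(rec), "unusable record|no clear spectral peak")
})

test_that("cohort featurization returns aligned matrix, labels and ids", {
  coh <- generate_cohort(4, noise = noise_off(), duration = 30, seed = 31)
  fz <- featurize_cohort(coh)
  expect_identical(dim(fz$X), c(4L, 58L))
  expect_equal(fz$y, vapply(coh, `[[`, 0, "hb_ref"))
  expect_identical(fz$ids, vapply(coh, `[[`, "", "id"))
  expect_identical(colnames(fz$X)[57:58], c("age", "gender"))
})
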