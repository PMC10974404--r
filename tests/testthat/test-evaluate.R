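test_that("splits have the protocol sizes and are seed-stable", {
  s <- split_dataset(249, 0.8, seed = 1)
  expect_length(s$train, 199)
  expect_length(s$test, 50)
  expect_setequal(c(s$train, s$test), 1:249)

  s10 <- split_dataset(10, 0.8, seed = 2)
  expect_length(s10$train, 8)
  expect_length(s10$test, 2)

  expect_identical(split_dataset(50, 0.8, seed = 7),
                   split_dataset(50, 0.8, seed = 7))
})

test_that("rmse matches hand-computed cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1.0)
  expect_equal(rmse(c(1, 2, 3, 4), c(2, 3, 4, 5)), 1.0)
})

test_that("pcc matches hand-computed cases with a t-based p-value", {
  expect_equal(pcc(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)$r, 1.0)
  expect_equal(pcc(c(1, 2, 3), -c(1, 2, 3))$r, -1.0)
  out <- pcc(c(1, 2, 3), c(1, 3, 2))
  expect_equal(out$r, 0.5)
  expect_true(out$p > 0 && out$p <= 1)
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Bland-Altman statistics match two-point and shift cases", {
  ba0 <- bland_altman(c(3, 4), c(3, 4))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba <- bland_altman(c(0, 0), c(1, -1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2.7719, tolerance = 1e-4)

  bac <- bland_altman(c(1, 2, 3), c(1, 2, 3) + 0.7)
  expect_equal(bac$mean_diff, 0.7)
  expect_equal(bac$sd_diff, 0)
})

test_that("error grid labels regions with inclusive boundaries", {
  g <- error_grid(rep(14, 3), c(14.5, 15.5, 17.0))
  expect_equal(as.character(g$labels), c("A", "B", "C"))
  expect_equal(unname(g$pct), rep(100 / 3, 3))
  expect_equal(sum(g$pct), 100)

  gb <- error_grid(c(10, 10), c(11, 12))   # e = 1 -> A, e = 2 -> B
  expect_equal(as.character(gb$labels), c("A", "B"))
})

test_that("about 95% of normal differences fall inside the limits", {
  set.seed(15)
  ref <- rnorm(10000, 14, 1)
  pred <- ref + rnorm(10000, 0, 0.8)
  expect_equal(bland_altman(ref, pred)$frac_within, 0.95, tolerance = 0.01)
})

test_that("repeated evaluation is deterministic and fully populated", {
  dat <- make_regression(n = 60, d = 6, noise_sd = 0.2, seed = 77)
  y <- 13 + dat$y   # shift into a plausible hemoglobin range
  r1 <- repeated_evaluation(dat$X, y, n_repeats = 2, K = 10, P = 5,
                            use_rfe = FALSE, seed = 3)
  r2 <- repeated_evaluation(dat$X, y, n_repeats = 2, K = 10, P = 5,
                            use_rfe = FALSE, seed = 3)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(sum(r1$grid_pct), 100)
  expect_true(all(c("rmse", "pcc", "pcc_p") %in% names(unlist(r1[1:3]))))
  expect_equal(nrow(r1$per_repeat), 2)
})

test_that("metric averages tighten as repeats accumulate", {
  dat <- make_regression(n = 60, d = 6, noise_sd = 0.3, seed = 88)
  y <- 13 + dat$y
  r <- repeated_evaluation(dat$X, y, n_repeats = 12, K = 10, P = 3,
                           use_rfe = FALSE, seed = 5)
  se6 <- sd(r$per_repeat[1:6, "rmse"]) / sqrt(6)
  se12 <- sd(r$per_repeat[, "rmse"]) / sqrt(12)
  expect_lt(se12, 2 * se6)   # shrinking standard error of the mean
})
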