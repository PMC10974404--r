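# Synthetic multi-wavelength PPG generation from the Beer-Lambert forward
# model. Gives the pipeline a ground-truth oracle: every generated subject
# carries its true hemoglobin value and the closed-form ratio features it
# should produce.

# Cardiac waveform template: raised-cosine systolic upstroke plus a smaller
# dicrotic bump, one period on phase in [0, 1), normalized to range [0, 1].
# Only the AC amplitude enters the feature model, so the precise morphology
# is cosmetic; this shape gives clean, unambiguous peaks for landmarking.
# Widths are chosen so the template is effectively band-limited to the
# physiological 1-10 Hz PPG band at resting heart rates (out-of-band energy
# ~2e-4), matching real pulse waves whose energy above 10 Hz is negligible.
pulse_waveform <- function(phase) {
  p <- phase - floor(phase)
  sys_w <- 0.34   # systolic width (fraction of cycle)
  dic_c <- 0.58   # dicrotic bump centre
  dic_w <- 0.26
  dic_a <- 0.25
  v <- numeric(length(p))
  m1 <- p < sys_w
  v[m1] <- 0.5 * (1 - cos(2 * pi * p[m1] / sys_w))
  m2 <- abs(p - dic_c) < dic_w / 2
  v[m2] <- v[m2] + dic_a * 0.5 * (1 + cos(2 * pi * (p[m2] - dic_c) / dic_w))
  v
}

#' Generate one eight-channel synthetic PPG recording
#'
#' Simulates transmitted light intensity per channel as
#' `I(t) = DC_lambda * (1 - r_lambda * pulse(t)) + noise`, where
#' `DC_lambda = I0 * exp(-baseline_absorbance)` and
#' `r_lambda = (eps_oxy c1 + eps_deoxy c2) * Delta<L>` is the small
#' fractional intensity swing per beat (the linearized Beer-Lambert
#' pulsatile term). Noise adds white Gaussian noise, a respiratory
#' baseline-wander sinusoid, a mains tone, and sparse motion transients,
#' each scaled by the channel DC.
#'
#' @param state a [physio_state()].
#' @param optics an [optical_config()].
#' @param noise a [noise_config()]; use [noise_off()] for a clean record.
#' @param duration recording length in seconds (>= 10).
#' @param fs sample rate in Hz (default 100).
#' @param seed integer seed; the same seed reproduces the record exactly.
#'
#' @return A `ppg_record`: list with `signals` (samples x 8 matrix, columns
#'   named by wavelength), `fs`, `wavelengths`, and the generating `state`.
#' @export
generate_ppg <- function(state, optics = optical_config(),
                         noise = noise_config(),
                         duration = 120, fs = 100, seed = 1) {
  stopifnot(inherits(state, "physio_state"), inherits(optics, "optical_config"),
            inherits(noise, "noise_config"))
  if (duration < 10) stop("duration must be >= 10 s")
  if (fs <= 0) stop("fs must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  dc <- optics$incident_intensity * exp(-optics$baseline_absorbance)
  r <- effective_extinction(state, optics) * optics$path_pulse_amplitude
  pulse <- pulse_waveform(t * state$heart_rate / 60)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # Shared (optical-path) disturbances: one realization applied to all
  # channels, scaled by each channel's DC.
  drift <- if (noise$drift_amp > 0) {
    noise$drift_amp * sin(2 * pi * state$resp_rate * t + stats::runif(1, 0, 2 * pi))
  } else numeric(n)
  mains <- if (noise$powerline_amp > 0) {
    noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
  } else numeric(n)
  motion <- numeric(n)
  if (noise$motion_prob > 0 && noise$motion_amp > 0) {
    seg <- 5 * fs
    n_seg <- floor(n / seg)
    for (s in seq_len(n_seg)) {
      if (stats::runif(1) < noise$motion_prob) {
        centre <- (s - 1) * seg + stats::runif(1, 0.2, 0.8) * seg
        width <- stats::runif(1, 0.3, 1.0) * fs  # 0.3-1 s transient
        motion <- motion + noise$motion_amp *
          exp(-0.5 * ((seq_len(n) - centre) / (width / 2))^2)
      }
    }
  }
  shared <- drift + mains + motion

  signals <- matrix(0, nrow = n, ncol = 8)
  for (k in 1:8) {
    clean <- dc[k] * (1 - r[k] * pulse)
    chan_noise <- if (noise$white_sd > 0) {
      stats::rnorm(n, sd = noise$white_sd * dc[k])
    } else 0
    signals[, k] <- clean + dc[k] * shared + chan_noise
  }
  colnames(signals) <- paste0("nm", optics$wavelengths)

  structure(
    list(signals = signals, fs = fs,
         wavelengths = optics$wavelengths, state = state),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, nrow(x$signals) / x$fs))
  cat("  wavelengths (nm):", paste(x$wavelengths, collapse = ", "), "\n")
  if (!is.null(x$state))
    cat(sprintf("  state: Hb %.2f g/dL, SpO2 %.3f, HR %.0f bpm\n",
                x$state$hb_total, x$state$spo2, x$state$heart_rate))
  invisible(x)
}

#' Default cohort hemoglobin sampler
#'
#' Mixture concentrated in the clinical normal range with sparse abnormal
#' tails: 0.8 * Normal(14, 1) + 0.2 * Uniform(7, 19), truncated to (4, 22)
#' g/dL. Its analytic mean is 0.8*14 + 0.2*13 = 13.8 g/dL (truncation is
#' negligible at these parameters).
#'
#' @param n number of draws.
#' @return numeric vector of hemoglobin values in g/dL.
#' @export
hb_sampler_default <- function(n) {
  comp <- stats::runif(n) < 0.8
  x <- ifelse(comp, stats::rnorm(n, 14, 1), stats::runif(n, 7, 19))
  while (any(bad <- (x <= 4 | x >= 22))) {
    nb <- sum(bad)
    comp <- stats::runif(nb) < 0.8
    x[bad] <- ifelse(comp, stats::rnorm(nb, 14, 1), stats::runif(nb, 7, 19))
  }
  x
}

#' Generate a synthetic cohort of subject records
#'
#' Each subject gets a physiological state (hemoglobin from `hb_sampler`,
#' SpO2 ~ N(0.97, 0.02) truncated to [0.90, 1.00], heart rate ~ N(72, 10)
#' truncated to [50, 110], age ~ N(41.7, 24.3) truncated to [18, 90],
#' gender ~ Bernoulli(100/249) male) and an eight-channel PPG generated
#' from it. Per-subject seeds are derived from the cohort seed as
#' `seed + subject index`, so the cohort is fully reproducible.
#'
#' @param n number of subjects (>= 1).
#' @param hb_sampler function(n) returning n hemoglobin values in g/dL.
#' @param optics an [optical_config()].
#' @param noise a [noise_config()].
#' @param duration,fs recording length (s) and sample rate (Hz).
#' @param seed integer cohort seed.
#'
#' @return A list of subject records; each has `id`, `ppg` (a
#'   `ppg_record`), `age`, `gender` (0 female / 1 male), and `hb_ref`
#'   (ground-truth hemoglobin, g/dL).
#' @export
generate_cohort <- function(n, hb_sampler = hb_sampler_default,
                            optics = optical_config(),
                            noise = noise_config(),
                            duration = 120, fs = 100, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  hb <- hb_sampler(n)
  spo2 <- pmin(1.0, pmax(0.90, stats::rnorm(n, 0.97, 0.02)))
  hr <- pmin(110, pmax(50, stats::rnorm(n, 72, 10)))
  rr <- pmin(0.4, pmax(0.15, stats::rnorm(n, 0.25, 0.05)))
  age <- round(pmin(90, pmax(18, stats::rnorm(n, 41.7, 24.3))))
  gender <- as.integer(stats::runif(n) < 100 / 249)

  lapply(seq_len(n), function(i) {
    st <- physio_state(hb_total = hb[i], spo2 = spo2[i],
                       heart_rate = hr[i], resp_rate = rr[i])
    list(
      id = sprintf("S%04d", i),
      ppg = generate_ppg(st, optics, noise, duration = duration,
                         fs = fs, seed = seed + i),
      age = age[i],
      gender = gender[i],
      hb_ref = hb[i]
    )
  })
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort` writes one metadata CSV (`subjects.csv`: subject_id, age,
#' gender, hb_ref) plus one channel-matrix CSV per subject (time x 8
#' channels, header row = wavelength in nm). `read_cohort` reverses it.
#'
#' @param cohort a list of subject records from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param fs sample rate recorded alongside (Hz), used on read.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   cohort list (states are not recoverable from disk and are `NULL`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "id"),
    age = vapply(cohort, `[[`, 0, "age"),
    gender = vapply(cohort, `[[`, 0L, "gender"),
    hb_ref = vapply(cohort, `[[`, 0, "hb_ref"),
    fs = vapply(cohort, function(s) s$ppg$fs, 0)
  )
  utils::write.csv(meta, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (s in cohort) {
    utils::write.csv(as.data.frame(s$ppg$signals),
                     file.path(dir, paste0(s$id, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "subjects.csv"))
  lapply(seq_len(nrow(meta)), function(i) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(meta$subject_id[i], ".csv"))))
    wl <- as.numeric(sub("^nm", "", colnames(m)))
    rec <- structure(
      list(signals = m, fs = meta$fs[i], wavelengths = wl, state = NULL),
      class = "ppg_record"
    )
    list(id = meta$subject_id[i], ppg = rec, age = meta$age[i],
         gender = meta$gender[i], hb_ref = meta$hb_ref[i])
  })
}

# Save/restore the global RNG state so generators behave as pure functions
# of (params, seed) without disturbing the caller's random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
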