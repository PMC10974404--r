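# Ratio-of-ratios feature extraction: window the preprocessed signals,
# measure per-channel AC and DC amplitudes, and form the 56 ordered-pair
# ratios R_ij = (AC_i/DC_i)/(AC_j/DC_j), plus age and gender.

#' Ordered channel pairs in the fixed feature order
#'
#' The feature order is (R_12, R_13, ..., R_1N, R_21, R_23, ..., R_N,N-1):
#' for each numerator channel i in order, all denominators j != i in order.
#'
#' @param n_channels number of channels (default 8, giving 56 pairs).
#' @return data.frame with columns `i`, `j`.
#' @export
ratio_pair_index <- function(n_channels = 8) {
  g <- expand.grid(j = seq_len(n_channels), i = seq_len(n_channels))
  g <- g[g$i != g$j, c("i", "j")]
  rownames(g) <- NULL
  g
}

#' Names for the ratio features
#'
#' @param wavelengths wavelengths in nm, one per channel.
#' @return character vector like `"R_610_630"`, in the fixed feature order.
#' @export
ratio_names <- function(wavelengths = HEMOPPG_WAVELENGTHS) {
  idx <- ratio_pair_index(length(wavelengths))
  paste0("R_", wavelengths[idx$i], "_", wavelengths[idx$j])
}

#' Split a signal into non-overlapping windows
#'
#' @param x numeric signal.
#' @param fs sample rate (Hz).
#' @param win_len window length in seconds (default 5). A trailing partial
#'   window is discarded.
#' @return list of numeric windows (possibly empty).
#' @export
segment_windows <- function(x, fs, win_len = 5) {
  stopifnot(fs > 0, win_len > 0)
  w <- round(win_len * fs)
  n_win <- floor(length(x) / w)
  if (n_win == 0) return(list())
  lapply(seq_len(n_win), function(k) x[((k - 1) * w + 1):(k * w)])
}

#' Extract AC and DC amplitudes from one window
#'
#' The AC amplitude comes from the differential method: sign changes of the
#' first difference locate systolic peaks (maxima) and their preceding
#' troughs (minima); AC is the mean peak-minus-trough over complete cardiac
#' cycles. The DC amplitude is the mean of the low-pass-filtered window
#' (the drift-removed signal has no meaningful mean).
#'
#' @param ac_window window of the fully preprocessed (baseline-removed,
#'   comb-filtered) signal.
#' @param dc_window corresponding window of the low-pass-only signal.
#' @param fs sample rate (Hz).
#' @return list with `ac`, `dc`, and `valid` (FALSE when no complete cycle
#'   was found).
#' @export
extract_ac_dc <- function(ac_window, dc_window, fs) {
  stopifnot(length(ac_window) == length(dc_window),
            length(ac_window) >= 2 * fs)
  dc <- mean(dc_window)
  if (dc <= 0) stop("invalid signal: non-positive DC level")

  d <- diff(ac_window)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- diff(s)
  maxima <- which(turn < 0) + 1      # + -> - : local maximum
  minima <- which(turn > 0) + 1      # - -> + : local minimum

  # Keep only prominent landmarks: transmissive PPG dips on systole, so the
  # beat extremes sit near the window's global extremes while dicrotic
  # bumps and filter ripple stay in the middle band. Keep maxima in the top
  # 40% of the swing and minima in the bottom 40%.
  # a perfusion index below 1e-6 is no pulse, only numerical ripple
  swing <- max(ac_window) - min(ac_window)
  if (swing <= 1e-6 * abs(dc)) return(list(ac = NA_real_, dc = dc, valid = FALSE))
  maxima <- maxima[ac_window[maxima] > max(ac_window) - 0.4 * swing]
  minima <- minima[ac_window[minima] < min(ac_window) + 0.4 * swing]
  if (length(maxima) == 0 || length(minima) == 0)
    return(list(ac = NA_real_, dc = dc, valid = FALSE))

  # Landmark values are read from the vertex of a least-squares parabola
  # fitted over +/-4 samples around each extremum: sub-sample accurate and
  # less sensitive to residual noise than the raw extreme sample (which
  # sits at a locally extreme noise excursion by construction). Any
  # morphology-induced reading distortion is common to all channels and
  # cancels in the ratio features.
  half <- 4L
  vertex <- function(i) {
    lo <- max(1L, i - half); hi <- min(length(ac_window), i + half)
    tt <- (lo:hi) - i
    y <- ac_window[lo:hi]
    if (length(y) < 5) return(ac_window[i])
    fit <- stats::lm.fit(cbind(1, tt, tt^2), y)
    cf <- fit$coefficients
    if (!is.finite(cf[3]) || cf[3] == 0) return(cf[1])
    t_star <- -cf[2] / (2 * cf[3])
    if (abs(t_star) > half) return(cf[1])   # no extrapolation beyond the fit
    cf[1] - cf[2]^2 / (4 * cf[3])
  }

  # One amplitude per cycle: each trough against a per-beat baseline
  # interpolated between the flanking peak levels (the average of the
  # nearest prominent maxima on either side). Interpolating the baseline
  # across the beat cancels any residual low-frequency drift to first
  # order, which matters most on weakly pulsatile channels.
  pk_val <- vapply(maxima, vertex, 0)
  amps <- vapply(minima, function(m) {
    before <- which(maxima < m)
    after <- which(maxima > m)
    base <- if (length(before) && length(after)) {
      (pk_val[max(before)] + pk_val[min(after)]) / 2
    } else if (length(before)) {
      pk_val[max(before)]
    } else {
      pk_val[min(after)]
    }
    base - vertex(m)
  }, 0)
  amps <- amps[amps > 0]
  if (length(amps) < 1) return(list(ac = NA_real_, dc = dc, valid = FALSE))
  list(ac = mean(amps), dc = dc, valid = TRUE)
}

#' Ratio-of-ratios features from eight AC/DC pairs
#'
#' @param ac numeric vector of 8 AC amplitudes (fixed channel order).
#' @param dc numeric vector of 8 DC amplitudes.
#' @param wavelengths wavelengths for naming.
#' @return named numeric vector of 56 ratios in the fixed feature order.
#' @export
compute_ratios <- function(ac, dc, wavelengths = HEMOPPG_WAVELENGTHS) {
  stopifnot(length(ac) == 8, length(dc) == 8)
  if (any(dc <= 0)) stop("invalid channel: non-positive DC")
  if (any(ac <= 0)) stop("degenerate channel: zero AC amplitude")
  r <- ac / dc
  idx <- ratio_pair_index(8)
  out <- r[idx$i] / r[idx$j]
  names(out) <- ratio_names(wavelengths)
  out
}

#' Build the 58-entry feature vector for one subject
#'
#' Windows every channel (5 s windows by default), extracts AC/DC per
#' window and channel, computes the 56 ratios for each window in which all
#' eight channels produced valid beats, aggregates ratios across windows by
#' the median (robust to windows with residual artifacts), and appends age
#' and gender.
#'
#' @param record a subject record (see [generate_cohort()]): needs `ppg`,
#'   `age`, `gender`.
#' @param cfg a [preprocess_config()].
#' @param win_len window length in seconds.
#' @return named numeric vector of length 58: 56 ratios, `age`, `gender`.
#' @export
build_feature_vector <- function(record, cfg = preprocess_config(),
                                 win_len = 5) {
  pp <- preprocess_record(record$ppg, cfg)
  fs <- pp$fs
  ac_wins <- lapply(pp$channels, function(ch)
    segment_windows(ch$ac_source, fs, win_len))
  dc_wins <- lapply(pp$channels, function(ch)
    segment_windows(ch$dc_source, fs, win_len))
  n_win <- length(ac_wins[[1]])
  if (n_win == 0) stop("unusable record: no complete window")

  per_window <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    ac <- dc <- rep(NA_real_, 8)
    ok <- TRUE
    for (k in 1:8) {
      p <- extract_ac_dc(ac_wins[[k]][[w]], dc_wins[[k]][[w]], fs)
      if (!p$valid || p$ac <= 0) { ok <- FALSE; break }
      ac[k] <- p$ac; dc[k] <- p$dc
    }
    if (ok) per_window[[w]] <- compute_ratios(ac, dc, pp$wavelengths)
  }
  per_window <- per_window[!vapply(per_window, is.null, TRUE)]
  if (length(per_window) == 0)
    stop("unusable record: no window with valid beats on all channels")

  ratio_mat <- do.call(rbind, per_window)
  ratios <- apply(ratio_mat, 2, stats::median)
  c(ratios, age = record$age, gender = record$gender)
}

#' Feature matrix for a whole cohort
#'
#' @param cohort list of subject records.
#' @param cfg a [preprocess_config()].
#' @param win_len window length in seconds.
#' @return list with `X` (n x 58 feature matrix), `y` (reference Hb,
#'   g/dL), and `ids`. Subjects whose record is unusable are dropped with a
#'   warning.
#' @export
featurize_cohort <- function(cohort, cfg = preprocess_config(), win_len = 5) {
  rows <- vector("list", length(cohort))
  ok <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    fv <- tryCatch(build_feature_vector(cohort[[i]], cfg, win_len),
                   error = function(e) NULL)
    if (!is.null(fv)) { rows[[i]] <- fv; ok[i] <- TRUE }
  }
  if (!all(ok))
    warning(sum(!ok), " unusable record(s) dropped")
  if (!any(ok)) stop("no usable records in cohort")
  X <- do.call(rbind, rows[ok])
  rownames(X) <- vapply(cohort[ok], `[[`, "", "id")
  list(X = X,
       y = vapply(cohort[ok], `[[`, 0, "hb_ref"),
       ids = rownames(X))
}

#' Train-set standardization
#'
#' `standardize_fit` learns per-column mean and SD (constant columns get
#' scale 1 so they map to 0 rather than NaN); `standardize_apply` applies
#' them. Features are z-scored with training-set statistics before
#' selection and regression, since both the SVR and the random-projection
#' hidden layer assume comparable feature scales.
#'
#' @param X numeric feature matrix (samples x features).
#' @return `standardize_fit`: list with `mean` and `sd`;
#'   `standardize_apply`: the transformed matrix.
#' @export
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

#' @rdname standardize_fit
#' @param stats statistics from `standardize_fit`.
#' @export
standardize_apply <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
}
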