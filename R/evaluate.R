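# Evaluation protocol: random 8:2 splits repeated many times, RMSE and
# Pearson correlation, Bland-Altman agreement statistics, and a
# Clarke-style hemoglobin error grid.

#' Random train/test split
#'
#' @param n number of records (or a list of records, whose length is used).
#' @param train_ratio fraction assigned to training (0 < ratio < 1);
#'   `floor(ratio * n)` records train, the rest test.
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   union = 1..n).
#' @export
split_dataset <- function(n, train_ratio = 0.8, seed = 1) {
  if (is.list(n)) n <- length(n)
  stopifnot(n >= 2, train_ratio > 0, train_ratio < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(train_ratio * n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1):n]))
}

#' Root mean square error
#'
#' @param y_ref,y_pred reference and predicted values (same length).
#' @return RMSE in the units of the inputs (g/dL for hemoglobin).
#' @export
rmse <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred))
  sqrt(mean((y_pred - y_ref)^2))
}

#' Pearson correlation with two-sided p-value
#'
#' @param y_ref,y_pred reference and predicted values (n >= 3, both with
#'   nonzero variance).
#' @return list with `r` and `p` (t transform on n - 2 df).
#' @export
pcc <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred), length(y_ref) >= 3)
  if (stats::sd(y_ref) == 0 || stats::sd(y_pred) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(y_ref, y_pred, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement statistics
#'
#' Differences are predicted minus reference; limits of agreement are the
#' mean difference +/- 1.96 sample standard deviations.
#'
#' @param y_ref,y_pred reference and predicted values.
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high` (all
#'   g/dL) and `frac_within` (fraction of points inside the limits).
#' @export
bland_altman <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred))
  d <- y_pred - y_ref
  m <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  list(mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi,
       frac_within = mean(d >= lo & d <= hi))
}

#' Clarke-style hemoglobin error grid
#'
#' Absolute error e = |pred - ref| classifies each point: region A (e <= 1
#' g/dL, clinically safe), region B (1 < e <= 2 g/dL, no inappropriate
#' treatment), region C (e > 2 g/dL, risk of inappropriate treatment).
#' Boundaries are inclusive: e = 1 is A, e = 2 is B.
#'
#' @param y_ref,y_pred reference and predicted values (g/dL).
#' @return list with `pct` (named percentages A/B/C summing to 100) and
#'   `labels` (per-point factor).
#' @export
error_grid <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred))
  e <- abs(y_pred - y_ref)
  labels <- cut(e, breaks = c(-Inf, 1, 2, Inf), labels = c("A", "B", "C"))
  pct <- 100 * as.numeric(table(labels)) / length(e)
  names(pct) <- c("A", "B", "C")
  list(pct = pct, labels = labels)
}

#' One train/evaluate pass on a prepared feature set
#'
#' Standardizes on the training rows, optionally restricts to a feature
#' mask, trains an EELM, and scores the held-out rows.
#' @noRd
.fit_and_score <- function(X, y, idx, mask = NULL, K = 20, P = 200,
                           activation = "sigmoid", seed = 1) {
  Xtr <- X[idx$train, , drop = FALSE]
  st <- standardize_fit(Xtr)
  Xtr <- standardize_apply(Xtr, st)
  Xte <- standardize_apply(X[idx$test, , drop = FALSE], st)
  if (!is.null(mask)) {
    Xtr <- Xtr[, mask, drop = FALSE]
    Xte <- Xte[, mask, drop = FALSE]
  }
  model <- train_eelm(Xtr, y[idx$train], K = K, P = P,
                      activation = activation, seed = seed)
  pred <- predict(model, Xte)
  list(pred = pred, ref = y[idx$test])
}

#' Repeated random-split evaluation
#'
#' The full protocol: for each repeat, draw a fresh random split,
#' standardize features on the training rows, (optionally) apply an
#' SVR-RFE feature mask, train an EELM, predict the test rows, and compute
#' RMSE, Pearson correlation, Bland-Altman statistics, and error-grid
#' percentages. Metrics are averaged over repeats. By default the RFE
#' ranking is computed once on the first training split and its mask
#' reused; set `rfe_per_repeat = TRUE` to re-rank inside every repeat.
#'
#' @param X feature matrix (n x d), unstandardized.
#' @param y reference hemoglobin (g/dL).
#' @param n_repeats number of random splits (protocol default 200).
#' @param train_ratio training fraction (default 0.8).
#' @param K,P,activation EELM hyperparameters (defaults 20, 200, sigmoid).
#' @param use_rfe run SVR-RFE feature selection (default TRUE).
#' @param rfe_per_repeat recompute the ranking inside every repeat.
#' @param seed master seed; per-repeat split seeds and model seeds derive
#'   from it.
#' @return object of class `eval_report`: averaged `rmse`, `pcc`, `pcc_p`,
#'   `bland_altman`, `grid_pct`, plus `n_repeats`, `n_skipped`, `mask`,
#'   `k_selected` and the per-repeat metric table `per_repeat`.
#' @export
repeated_evaluation <- function(X, y, n_repeats = 200, train_ratio = 0.8,
                                K = 20, P = 200, activation = "sigmoid",
                                use_rfe = TRUE, rfe_per_repeat = FALSE,
                                seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n_repeats >= 1)

  mask <- NULL
  k_sel <- NA_integer_
  if (use_rfe && !rfe_per_repeat) {
    idx0 <- split_dataset(n, train_ratio, seed = derive_seed(seed, 1))
    st0 <- standardize_fit(X[idx0$train, , drop = FALSE])
    rk <- svr_rfe(standardize_apply(X[idx0$train, , drop = FALSE], st0),
                  y[idx0$train], seed = derive_seed(seed, 100003))
    k_sel <- choose_k(rk)
    mask <- selection_mask(rk, k_sel)
  }

  rows <- vector("list", n_repeats)
  skipped <- 0L
  for (r in seq_len(n_repeats)) {
    idx <- split_dataset(n, train_ratio, seed = derive_seed(seed, r))
    m_r <- mask
    if (use_rfe && rfe_per_repeat) {
      st_r <- standardize_fit(X[idx$train, , drop = FALSE])
      rk_r <- svr_rfe(standardize_apply(X[idx$train, , drop = FALSE], st_r),
                      y[idx$train], seed = derive_seed(seed, 100003 + r))
      m_r <- selection_mask(rk_r, choose_k(rk_r))
    }
    res <- .fit_and_score(X, y, idx, mask = m_r, K = K, P = P,
                          activation = activation,
                          seed = derive_seed(seed, 200003 + r))
    if (stats::sd(res$ref) == 0 || stats::sd(res$pred) == 0) {
      warning("repeat ", r, " skipped: degenerate test-set variance")
      skipped <- skipped + 1L
      next
    }
    pc <- pcc(res$ref, res$pred)
    ba <- bland_altman(res$ref, res$pred)
    gr <- error_grid(res$ref, res$pred)
    rows[[r]] <- c(rmse = rmse(res$ref, res$pred), pcc = pc$r, pcc_p = pc$p,
                   mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                   loa_low = ba$loa_low, loa_high = ba$loa_high,
                   pct_A = gr$pct[["A"]], pct_B = gr$pct[["B"]],
                   pct_C = gr$pct[["C"]])
  }
  per_repeat <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per_repeat)) stop("all repeats skipped")
  avg <- colMeans(per_repeat)

  structure(list(
    rmse = avg[["rmse"]], pcc = avg[["pcc"]], pcc_p = avg[["pcc_p"]],
    bland_altman = list(mean_diff = avg[["mean_diff"]],
                        sd_diff = avg[["sd_diff"]],
                        loa_low = avg[["loa_low"]],
                        loa_high = avg[["loa_high"]]),
    grid_pct = c(A = avg[["pct_A"]], B = avg[["pct_B"]], C = avg[["pct_C"]]),
    n_repeats = n_repeats, n_skipped = skipped,
    mask = mask, k_selected = k_sel,
    per_repeat = per_repeat
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  repeats: %d (skipped %d)\n", x$n_repeats, x$n_skipped))
  cat(sprintf("  RMSE: %.3f g/dL   PCC: %.3f (p = %.3g)\n",
              x$rmse, x$pcc, x$pcc_p))
  cat(sprintf("  Bland-Altman: mean %.3f, LoA [%.3f, %.3f] g/dL\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  cat(sprintf("  error grid: A %.1f%%  B %.1f%%  C %.2f%%\n",
              x$grid_pct[["A"]], x$grid_pct[["B"]], x$grid_pct[["C"]]))
  if (!is.na(x$k_selected))
    cat(sprintf("  RFE-selected features: %d\n", x$k_selected))
  invisible(x)
}
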