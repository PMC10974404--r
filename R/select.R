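# Feature selection by recursive feature elimination with a linear support
# vector regression: train SVR on the surviving features, score each
# feature by its squared weight, drop the weakest, and record
# cross-validated performance of every surviving subset; the chosen subset
# size minimizes the CV RMSE.

.svr_weights <- function(X, y, cost = 1, epsilon = 0.1) {
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE)
  drop(t(fit$coefs) %*% fit$SV)
}

.svr_cv_rmse <- function(X, y, folds, cost = 1, epsilon = 0.1) {
  errs <- lapply(unique(folds), function(f) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    stats::predict(fit, X[!tr, , drop = FALSE]) - y[!tr]
  })
  sqrt(mean(unlist(errs)^2))
}

#' Rank features by SVR-based recursive feature elimination
#'
#' Starting from all `d` features: fit a linear-kernel eps-SVR, score
#' feature importance as the squared entry of the primal weight vector
#' `w = t(coefs) %*% SV`, remove the single least important feature, record
#' the k-fold CV RMSE of the surviving set, and repeat until no features
#' remain.
#'
#' @param X standardized feature matrix (n x d, n >= 10).
#' @param y response vector (hemoglobin, g/dL).
#' @param cost,epsilon SVR hyperparameters (defaults C = 1, eps = 0.1).
#' @param n_folds folds for the CV curve (default 5).
#' @param seed seed for the fold assignment.
#' @return object of class `rfe_ranking`: `elimination_order` (first
#'   eliminated ... last eliminated, column indices of `X`),
#'   `cv_rmse_by_k` (named numeric, entry for every subset size 1..d), and
#'   `feature_names`.
#' @export
svr_rfe <- function(X, y, cost = 1, epsilon = 0.1, n_folds = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 10) stop("need at least 10 samples")
  if (d < 1) stop("need at least 1 feature")
  if (stats::sd(y) == 0) stop("degenerate target: y is constant")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))

  surviving <- seq_len(d)
  elimination_order <- integer(0)
  cv_rmse <- stats::setNames(rep(NA_real_, d), seq_len(d))

  while (length(surviving) > 0) {
    k <- length(surviving)
    Xs <- X[, surviving, drop = FALSE]
    cv_rmse[k] <- .svr_cv_rmse(Xs, y, folds, cost, epsilon)
    if (k == 1) {
      elimination_order <- c(elimination_order, surviving)
      break
    }
    w <- .svr_weights(Xs, y, cost, epsilon)
    drop_i <- which.min(w^2)
    elimination_order <- c(elimination_order, surviving[drop_i])
    surviving <- surviving[-drop_i]
  }

  structure(list(elimination_order = elimination_order,
                 cv_rmse_by_k = cv_rmse,
                 feature_names = colnames(X),
                 n_folds = n_folds, seed = seed),
            class = "rfe_ranking")
}

#' Pick the subset size from the CV curve
#'
#' @param ranking an `rfe_ranking` from [svr_rfe()].
#' @return `k*`, the subset size minimizing CV RMSE; ties break toward the
#'   smaller size.
#' @export
choose_k <- function(ranking) {
  stopifnot(inherits(ranking, "rfe_ranking"))
  cv <- ranking$cv_rmse_by_k
  if (anyNA(cv)) stop("cv_rmse_by_k is not fully populated")
  as.integer(which.min(cv))   # which.min returns the first (smallest k) tie
}

#' Column mask of the top-k features
#'
#' The top-k important features are the last k eliminated; the mask keeps
#' their original column order.
#'
#' @param ranking an `rfe_ranking`.
#' @param k subset size, 1 <= k <= d.
#' @return sorted integer vector of k column indices.
#' @export
selection_mask <- function(ranking, k) {
  d <- length(ranking$elimination_order)
  stopifnot(k >= 1, k <= d)
  sort(utils::tail(ranking$elimination_order, k))
}

#' Reduce a feature matrix to the selected subset
#'
#' @param X feature matrix with the same columns the ranking was built on.
#' @param ranking an `rfe_ranking`.
#' @param k subset size.
#' @return `X` restricted to the top-k columns (original order preserved).
#' @export
apply_selection <- function(X, ranking, k) {
  X[, selection_mask(ranking, k), drop = FALSE]
}

#' @export
print.rfe_ranking <- function(x, ...) {
  d <- length(x$elimination_order)
  k <- as.integer(which.min(x$cv_rmse_by_k))
  cat(sprintf("<rfe_ranking> %d features; best CV RMSE %.3f at k=%d\n",
              d, min(x$cv_rmse_by_k), k))
  top <- rev(utils::tail(x$elimination_order, min(5, d)))
  nm <- if (!is.null(x$feature_names)) x$feature_names[top] else top
  cat("  top features:", paste(nm, collapse = ", "), "\n")
  invisible(x)
}
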