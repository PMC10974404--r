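# Extreme learning machine regression and its averaging ensemble.
#
# An ELM is a single-hidden-layer feedforward network whose input-to-hidden
# weights W and biases b are drawn randomly and frozen; only the
# hidden-to-output weights beta are fitted, in closed form, as the
# minimum-norm least-squares solution beta = pinv(H) %*% Y with
# H = g(X W' + b). Training is therefore non-iterative. The ensemble trains
# P independently initialized ELMs and averages their predictions, which
# suppresses the initialization variance of a single ELM.

.activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh = tanh,
  relu = function(x) pmax(x, 0)
)

# Deterministic, platform-stable derivation of member seeds from a base
# seed: a Lehmer-style mix kept inside exact double-precision integers.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 69069 + as.numeric(index) * 12345) %%
               2147483647)
}

#' Moore-Penrose pseudoinverse via SVD
#'
#' Singular values below `rtol * max(singular values)` are treated as zero,
#' with `rtol = max(dim(A)) * .Machine$double.eps` by default (no ridge
#' regularization).
#'
#' @param A numeric matrix.
#' @param rtol relative singular-value cutoff.
#' @return the pseudoinverse of `A`.
#' @export
pseudoinverse <- function(A, rtol = NULL) {
  s <- svd(A)
  if (is.null(rtol)) rtol <- max(dim(A)) * .Machine$double.eps
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

.hidden_layer <- function(X, W, b, activation) {
  g <- .activations[[activation]]
  if (is.null(g)) stop("unknown activation: ", activation)
  H <- X %*% t(W)
  g(sweep(H, 2, b, "+"))
}

#' Train a single extreme learning machine
#'
#' Hidden weights and biases are drawn i.i.d. Uniform(-1, 1) from `seed`
#' and frozen; the output weights solve the least-squares problem
#' `H beta = Y` through the SVD pseudoinverse.
#'
#' @param X numeric matrix, samples x features (standardize first: the
#'   random hidden layer assumes comparable feature scales).
#' @param y numeric response vector (or matrix for multi-output).
#' @param K number of hidden neurons.
#' @param activation one of `"sigmoid"` (default), `"tanh"`, `"relu"`.
#' @param seed integer seed for the hidden-layer draw.
#' @return object of class `elm` with `W` (K x n), `b` (K), `beta` (K x m),
#'   `activation`, `seed`.
#' @export
train_elm <- function(X, y, K = 20, activation = "sigmoid", seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty training matrix")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  stopifnot(K >= 1)
  Y <- as.matrix(y)
  if (nrow(Y) != nrow(X)) stop("X and y disagree on sample count")

  n_feat <- ncol(X)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(stats::runif(K * n_feat, -1, 1), nrow = K)
  b <- stats::runif(K, -1, 1)

  H <- .hidden_layer(X, W, b, activation)
  beta <- pseudoinverse(H) %*% Y
  structure(list(W = W, b = b, beta = beta,
                 activation = activation, seed = seed),
            class = "elm")
}

#' Predict from a trained ELM
#'
#' @param object an `elm` from [train_elm()].
#' @param X samples x features matrix (same feature count as training).
#' @param ... unused.
#' @return numeric vector (or matrix for multi-output) of predictions.
#' @export
predict.elm <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(object$W))
    stop("feature count mismatch: model expects ", ncol(object$W))
  out <- .hidden_layer(X, object$W, object$b, object$activation) %*% object$beta
  if (ncol(out) == 1) drop(out) else out
}

#' Train an ensemble of extreme learning machines
#'
#' Trains `P` ELMs that differ only in their random hidden layers (member
#' `i` uses a seed derived deterministically from `seed` and `i`) and
#' predicts with the arithmetic mean of the members.
#'
#' @inheritParams train_elm
#' @param P ensemble size (default 200).
#' @return object of class `eelm` with `members` (list of `elm`), plus the
#'   shared `K`, `activation`, `seed`.
#' @export
train_eelm <- function(X, y, K = 20, P = 200, activation = "sigmoid",
                       seed = 1) {
  stopifnot(P >= 1)
  members <- lapply(seq_len(P), function(i)
    train_elm(X, y, K = K, activation = activation,
              seed = derive_seed(seed, i)))
  structure(list(members = members, K = K, P = P,
                 activation = activation, seed = seed),
            class = "eelm")
}

#' Predict from an EELM ensemble
#'
#' @param object an `eelm` from [train_eelm()].
#' @param X samples x features matrix.
#' @param ... unused.
#' @return per-sample mean of the member predictions.
#' @export
predict.eelm <- function(object, X, ...) {
  preds <- vapply(object$members, function(m) predict(m, X),
                  numeric(nrow(as.matrix(X))))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> K=%d hidden neurons, %d inputs, activation=%s\n",
              nrow(x$W), ncol(x$W), x$activation))
  invisible(x)
}

#' @export
print.eelm <- function(x, ...) {
  cat(sprintf("<eelm> P=%d members, K=%d hidden neurons, activation=%s\n",
              x$P, x$K, x$activation))
  invisible(x)
}
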