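# Multilevel discrete wavelet transform used for baseline-drift removal.
# Periodized (circular) filter-bank transform; signals are symmetrically
# padded to a multiple of 2^levels before the transform and cropped after,
# so boundary behaviour stays benign for finite records.

# coif5 scaling (low-pass decomposition) filter, 30 taps, from the standard
# published Coiflet filter tables. The wavelet filter and reconstruction
# filters follow by quadrature-mirror relations.
COIF5_DEC_LO <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07,  2.0612203985788783e-06,
   3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
   1.4035632812373243e-04,  3.018579416682448e-04,  -6.375589261258812e-04,
  -1.6616273039298788e-03,  2.4315754425382886e-03,  6.761520220620417e-03,
  -9.159507338676163e-03,  -1.9758391600965465e-02,  3.2674799467057355e-02,
   4.1287530472117834e-02, -1.0556315130733723e-01, -6.203775157498196e-02,
   4.379823066591634e-01,   7.742936228603274e-01,   4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.192158806008609e-02,   2.8169744270532353e-02,
   2.3408322118927783e-02, -1.0131584846900276e-02, -4.15931262757864e-03,
   2.1782943778456947e-03,  3.585777411617577e-04,  -2.12081862067494e-04
)

wavelet_filters <- function(name = "coif5") {
  if (!identical(name, "coif5"))
    stop("unsupported wavelet: ", name, " (only 'coif5' is provided)")
  lo_d <- COIF5_DEC_LO
  L <- length(lo_d)
  hi_d <- rev(lo_d) * (-1)^(seq_len(L))       # QMF: g[k] = (-1)^k h[L-1-k]
  list(lo_d = lo_d, hi_d = hi_d)
}

# Circular convolution of x with filter f followed by dyadic downsampling:
# full[i] = sum_k f[k] x[((i - k) mod n) + 1], keeping even positions.
# Implemented as a linear FIR pass (stats::filter, C-level) on a circularly
# pre-padded copy of x.
.dwt_step <- function(x, f) {
  n <- length(x)
  L <- length(f)
  z <- c(x[((n - ((L - 1):1)) %% n) + 1], x)   # wraps if n < L
  full <- stats::filter(z, f, method = "convolution", sides = 1)[L:(n + L - 1)]
  full[seq(2, n, by = 2)]
}

# Upsample-by-two then circular correlation with the analysis filter: the
# adjoint of .dwt_step. For an orthogonal filter bank the synthesis operator
# is exactly this adjoint, so decomposition filters are reused here.
.idwt_step <- function(c, f, n) {
  up <- numeric(n)
  up[seq(2, n, by = 2)] <- c
  L <- length(f)
  z <- c(up, up[((seq_len(L - 1) - 1) %% n) + 1])   # wraps if n < L
  stats::filter(z, rev(f), method = "convolution", sides = 1)[L:(n + L - 1)]
}

#' Multilevel periodized DWT
#'
#' @param x numeric signal; length must be a multiple of 2^levels (use
#'   [dwt_pad()] first for arbitrary lengths).
#' @param levels decomposition depth.
#' @param wavelet wavelet name (only `"coif5"` is shipped).
#' @return list with `approx` (level-`levels` approximation coefficients)
#'   and `details` (list of detail coefficient vectors, level 1 first).
#' @export
dwt_multilevel <- function(x, levels = 7, wavelet = "coif5") {
  stopifnot(levels >= 1)
  if (length(x) %% 2^levels != 0)
    stop("signal length must be a multiple of 2^levels")
  flt <- wavelet_filters(wavelet)
  a <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    details[[j]] <- .dwt_step(a, flt$hi_d)
    a <- .dwt_step(a, flt$lo_d)
  }
  list(approx = a, details = details, levels = levels, wavelet = wavelet)
}

#' Inverse of [dwt_multilevel()]
#'
#' @param dec a decomposition as returned by [dwt_multilevel()].
#' @return the reconstructed signal.
#' @export
idwt_multilevel <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    n <- 2 * length(a)
    a <- .idwt_step(a, flt$lo_d, n) + .idwt_step(dec$details[[j]], flt$hi_d, n)
  }
  a
}

# Symmetric (whole-point reflection) padding to a multiple of 2^levels.
# The margin is generous -- at least min(n, 1024) samples per side -- so
# that the discontinuity where the periodized transform wraps around sits
# far from the retained samples (a level-7 filter spreads boundary
# artifacts over ~ filter_length * 2^7 samples). Returns the padded vector
# and the index range of the original samples.
dwt_pad <- function(x, levels, margin = 1024) {
  n <- length(x)
  block <- 2^levels
  m <- min(n, margin)
  target <- ceiling((n + 2 * m) / block) * block
  left <- floor((target - n) / 2)
  right <- target - n - left
  # reflected index: fold any integer position into 1..n by mirroring
  reflect <- function(k) {
    p <- (k - 1) %% (2 * n)
    ifelse(p < n, p + 1, 2 * n - p)
  }
  list(x = x[reflect(seq.int(1 - left, n + right))], idx = left + seq_len(n))
}
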