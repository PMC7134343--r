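#' @importFrom stats fft median sd mad cor quantile rnorm runif approx coef lm
#'   var prcomp
#' @importFrom utils read.table write.table head tail
NULL

## Periodic Hann taper (first sample 0, period n) -- sums to a constant under
## overlap-add at any hop dividing n.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

## Robust z-score: deviation from the median scaled by 1.4826*MAD.
robust_z <- function(x) {
  s <- mad(x)
  if (s <= .Machine$double.eps) return(rep(0, length(x)))
  (x - median(x)) / s
}

## Power in a frequency band via the periodogram (mean squared magnitude).
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  sum(Mod(X[keep])^2) / n^2
}

#' Welch power spectral density estimate
#'
#' Mean periodogram over Hann-tapered segments with 50% overlap. Returns power
#' per frequency bin on a one-sided grid.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param seg_sec segment length in seconds (default 1).
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `power` (linear units, per bin).
#' @export
welch_psd <- function(x, fs, seg_sec = 1, overlap_frac = 0.5) {
  nseg <- max(8L, round(seg_sec * fs))
  nseg <- min(nseg, length(x))
  hop <- max(1L, round(nseg * (1 - overlap_frac)))
  w <- hann_window(nseg)
  wnorm <- sum(w^2)
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / (length(starts) * wnorm)
  nh <- floor(nseg / 2) + 1L
  list(freq = (seq_len(nh) - 1) * fs / nseg, power = p[seq_len(nh)])
}

## 1/f^alpha noise via spectral shaping of white Gaussian noise; unit RMS.
pink_noise <- function(n, alpha = 1) {
  X <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))          # guard DC
  f <- pmin(f, n - f + 1)            # mirror for conjugate symmetry
  X <- X * f^(-alpha / 2)
  x <- Re(fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

## Moore-Penrose pseudo-inverse via SVD.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

## Raised-cosine cross-fade weights for stitching overlapping windows.
crossfade_weights <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
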