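## Windowed subspace cleaners: PCA cleaning with noise-referenced criteria,
## lag-1 CCA cleaning, and a simplified ASR comparator.

#' @rdname pca_window_clean
#' @param window_sec,overlap_frac sliding-window geometry.
#' @param score_z outlier PC-score threshold, SD units from the median.
#' @param noise_corr_z noise-correlation flag threshold, SD units from the
#'   median of all component-noise correlations.
#' @param cancel_mult flag multiplier for the in-component frequency-domain
#'   cancellation (bins with noise magnitude above `cancel_mult` x median).
#' @param robust_scale use MAD instead of SD as the deviation scale.
#' @param corr_enabled disable the noise-correlation criterion when FALSE.
#' @export
pca_clean_config <- function(window_sec = 0.5, overlap_frac = 0.5,
                             score_z = 2, noise_corr_z = 5, cancel_mult = 2,
                             robust_scale = FALSE, corr_enabled = TRUE) {
  stopifnot(window_sec > 0, overlap_frac >= 0, overlap_frac < 1,
            score_z > 0, noise_corr_z > 0, cancel_mult > 0)
  list(window_sec = window_sec, overlap_frac = overlap_frac,
       score_z = score_z, noise_corr_z = noise_corr_z,
       cancel_mult = cancel_mult, robust_scale = robust_scale,
       corr_enabled = corr_enabled)
}

#' @rdname cca_window_clean
#' @param window_sec,overlap_frac sliding-window geometry.
#' @param skew_kurt_z outlier spectral skewness/kurtosis threshold, SD units
#'   from the median across components.
#' @param upper_mult,lower_mult cancellation cutoffs applied to flagged
#'   components (see [cancellation_config()]).
#' @export
cca_clean_config <- function(window_sec = 3.0, overlap_frac = 0.5,
                             skew_kurt_z = 2, upper_mult = 6, lower_mult = 2) {
  stopifnot(window_sec > 0, overlap_frac >= 0, overlap_frac < 1,
            skew_kurt_z > 0, upper_mult > lower_mult, lower_mult > 0)
  list(window_sec = window_sec, overlap_frac = overlap_frac,
       skew_kurt_z = skew_kurt_z, upper_mult = upper_mult,
       lower_mult = lower_mult)
}

## Apply `fun` (ch x nwin matrix -> same shape) over sliding windows and
## stitch with raised-cosine cross-fade weights; identity-preserving.
sliding_apply <- function(x, nwin, hop, fun) {
  n <- ncol(x)
  if (n <= nwin) return(fun(x))
  starts <- unique(c(seq(1L, n - nwin + 1L, by = hop), n - nwin + 1L))
  w <- crossfade_weights(nwin)
  acc <- matrix(0, nrow(x), n)
  norm <- numeric(n)
  for (s in starts) {
    idx <- s:(s + nwin - 1L)
    acc[, idx] <- acc[, idx] + sweep(fun(x[, idx, drop = FALSE]), 2, w, `*`)
    norm[idx] <- norm[idx] + w
  }
  sweep(acc, 2, pmax(norm, 1e-12), `/`)
}

dev_scale <- function(v, robust = FALSE) if (robust) mad(v) else sd(v)

#' Windowed PCA cleaning against the noise-layer mean
#'
#' Per sliding window: principal components of the scalp channels are
#' computed; score samples deviating more than `score_z` SD from the
#' component's median are replaced by the median; components whose absolute
#' correlation with the window's noise-layer mean trace is more than
#' `noise_corr_z` SD above the median of all component-noise correlations are
#' additionally cleaned by frequency-domain cancellation (bins above
#' `cancel_mult` x the noise median) against that trace. Channels are then
#' reconstructed from the cleaned components and overlapping windows
#' cross-faded.
#'
#' @param eeg channels x samples matrix (scalp block).
#' @param noise_mean noise-layer mean trace, same length.
#' @param fs sampling rate, Hz.
#' @param cfg a [pca_clean_config()].
#' @return cleaned channels x samples matrix.
#' @export
pca_window_clean <- function(eeg, noise_mean, fs, cfg = pca_clean_config()) {
  nwin <- round(cfg$window_sec * fs)
  hop <- max(1L, round(nwin * (1 - cfg$overlap_frac)))
  stopifnot(ncol(eeg) >= nwin, length(noise_mean) == ncol(eeg))
  n <- ncol(eeg)
  starts <- unique(c(seq(1L, n - nwin + 1L, by = hop), n - nwin + 1L))
  w <- crossfade_weights(nwin)
  acc <- matrix(0, nrow(eeg), n)
  norm <- numeric(n)
  for (s0 in starts) {
    idx <- s0:(s0 + nwin - 1L)
    cleaned <- clean_pca_window(eeg[, idx, drop = FALSE], noise_mean[idx],
                                fs, cfg)
    acc[, idx] <- acc[, idx] + sweep(cleaned, 2, w, `*`)
    norm[idx] <- norm[idx] + w
  }
  sweep(acc, 2, pmax(norm, 1e-12), `/`)
}

clean_pca_window <- function(W, noise_win, fs, cfg) {
  nw <- ncol(W)
  if (nw <= nrow(W) + 1L) return(W)            # rank-deficient: pass through
  ctr <- rowMeans(W)
  Xc <- W - ctr
  pc <- tryCatch(prcomp(t(Xc), center = FALSE), error = function(e) NULL)
  if (is.null(pc)) return(W)
  scores <- pc$x                               # nw x ncomp
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    med <- median(v)
    s <- dev_scale(v, cfg$robust_scale)
    if (is.finite(s) && s > 0)
      scores[abs(v - med) > cfg$score_z * s, j] <- med
  }
  if (cfg$corr_enabled && sd(noise_win) > 0) {
    r <- abs(apply(scores, 2, cor, y = noise_win))
    r[!is.finite(r)] <- 0
    sr <- sd(r)
    if (is.finite(sr) && sr > 0) {
      flagged <- which(r > median(r) + cfg$noise_corr_z * sr)
      if (length(flagged)) {
        ccfg <- cancellation_config(
          window_sec = min(cfg$window_sec, nw / fs), overlap_frac = 0.5,
          upper_mult = cfg$cancel_mult, lower_mult = cfg$cancel_mult / 2,
          persist_frac = 1.1)                  # persistence pass disabled
        for (j in flagged)
          scores[, j] <- cancel_channel(scores[, j], noise_win, fs,
                                        ccfg)$signal
      }
    }
  }
  t(tcrossprod(scores, pc$rotation)) + ctr
}

#' Canonical components of a signal against its one-sample lag
#'
#' Canonical correlation analysis between x(t) and x(t-1), solved by
#' whitening both views and taking the singular value decomposition of the
#' cross-covariance; canonical correlations equal the components' lag-1
#' autocorrelations, so components come out ordered from smooth (motion-like)
#' to rough (muscle/electrical-like). Near-singular covariances are
#' ridge-regularized.
#'
#' @param x channels x samples matrix.
#' @param ridge ridge added to the covariances when near-singular (default
#'   `1e-6 * trace/nchannels`).
#' @return list of class `cca_components`: `unmixing` (ncomp x ch), `mixing`
#'   (ch x ncomp), `activations` (ncomp x samples), `cancor` (canonical
#'   correlations, decreasing), `autocorr` (lag-1 autocorrelation of each
#'   activation), `center`.
#' @export
cca_components <- function(x, ridge = NULL) {
  n <- ncol(x)
  ctr <- rowMeans(x)
  Xc <- x - ctr
  X1 <- Xc[, -n, drop = FALSE]
  X2 <- Xc[, -1, drop = FALSE]
  X1 <- X1 - rowMeans(X1)                      # per-view centering
  X2 <- X2 - rowMeans(X2)
  m <- n - 1
  Cxx <- tcrossprod(X1) / m
  Cyy <- tcrossprod(X2) / m
  Cxy <- tcrossprod(X1, X2) / m
  whiten <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values)) {
      lam <- ridge %||% (1e-6 * sum(diag(C)) / nrow(C))
      e <- eigen(C + diag(lam, nrow(C)), symmetric = TRUE)
    }
    e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300)))
  }
  Wx <- whiten(Cxx)
  Wy <- whiten(Cyy)
  K <- Wx %*% Cxy %*% Wy
  s <- svd(K)
  wx <- Wx %*% s$u                             # ch x ncomp, canonical weights
  unmixing <- t(wx)
  activations <- unmixing %*% Xc
  mixing <- pinv(unmixing)
  ac1 <- apply(activations, 1, function(v)
    cor(v[-length(v)], v[-1]))
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = activations, cancor = s$d, autocorr = ac1,
                 center = ctr), class = "cca_components")
}

#' Locate the knee of a descending component-autocorrelation profile
#'
#' Maximum perpendicular distance to the chord joining the first and last
#' points (Kneedle-style); distance ties resolve toward the larger index, so
#' flat or linear profiles flag nothing. Components strictly after the knee
#' index count as "low autocorrelation".
#'
#' @param values autocorrelations sorted in decreasing order.
#' @return the knee index; with fewer than 3 values, the last index (nothing
#'   flagged).
#' @export
autocorr_knee <- function(values) {
  n <- length(values)
  if (n < 3) return(n)
  dx <- n - 1
  dy <- values[n] - values[1]
  i <- seq_len(n)
  d <- abs(dy * (i - 1) - dx * (values - values[1])) / sqrt(dx^2 + dy^2)
  ties <- which(d >= max(d) - 1e-12)
  ties[length(ties)]
}

## Spectral shape moments of the normalized power spectrum treated as a
## distribution over frequency.
spectral_moments <- function(x, fs) {
  ## short, heavily averaged segments: the moments need stable estimates far
  ## more than they need fine frequency resolution
  p <- welch_psd(x, fs, seg_sec = min(0.5, length(x) / fs / 2),
                 overlap_frac = 0.5)
  w <- p$power / sum(p$power)
  mu <- sum(w * p$freq)
  s2 <- sum(w * (p$freq - mu)^2)
  s <- sqrt(max(s2, 1e-300))
  c(skew = sum(w * (p$freq - mu)^3) / s^3,
    kurt = sum(w * (p$freq - mu)^4) / s^4)
}

#' Windowed CCA cleaning against the noise-layer mean
#'
#' Per sliding window: lag-1 canonical components are computed
#' ([cca_components()]); components below the autocorrelation knee, with
#' negatively skewed power spectra (power concentrated at high frequency), or
#' with spectral skewness or kurtosis more than `skew_kurt_z` SD from the
#' median across components, are cleaned by frequency-domain cancellation
#' against the window's noise-layer mean trace; channels are reconstructed
#' and overlapping windows cross-faded.
#'
#' @inheritParams pca_window_clean
#' @param cfg a [cca_clean_config()].
#' @return cleaned channels x samples matrix.
#' @export
cca_window_clean <- function(eeg, noise_mean, fs, cfg = cca_clean_config()) {
  nwin <- round(cfg$window_sec * fs)
  hop <- max(1L, round(nwin * (1 - cfg$overlap_frac)))
  stopifnot(length(noise_mean) == ncol(eeg))
  if (ncol(eeg) < nwin) nwin <- ncol(eeg)
  n <- ncol(eeg)
  starts <- unique(c(seq(1L, n - nwin + 1L, by = hop), n - nwin + 1L))
  w <- crossfade_weights(nwin)
  acc <- matrix(0, nrow(eeg), n)
  norm <- numeric(n)
  ccfg <- cancellation_config(upper_mult = cfg$upper_mult,
                              lower_mult = cfg$lower_mult)
  for (s0 in starts) {
    idx <- s0:(s0 + nwin - 1L)
    cleaned <- clean_cca_window(eeg[, idx, drop = FALSE], noise_mean[idx],
                                fs, cfg, ccfg)
    acc[, idx] <- acc[, idx] + sweep(cleaned, 2, w, `*`)
    norm[idx] <- norm[idx] + w
  }
  sweep(acc, 2, pmax(norm, 1e-12), `/`)
}

clean_cca_window <- function(W, noise_win, fs, cfg, ccfg) {
  cs <- tryCatch(cca_components(W), error = function(e) NULL)
  if (is.null(cs)) return(W)
  acts <- cs$activations
  nc <- nrow(acts)
  ## components already come ordered by canonical correlation (= lag-1
  ## autocorrelation under the canonical ordering)
  knee <- autocorr_knee(cs$cancor)
  low_auto <- which(seq_len(nc) > knee)
  mom <- t(apply(acts, 1, spectral_moments, fs = fs))
  neg_skew <- which(mom[, "skew"] < 0)
  out_stat <- integer(0)
  for (col in c("skew", "kurt")) {
    v <- mom[, col]
    s <- sd(v)
    if (is.finite(s) && s > 0)
      out_stat <- c(out_stat, which(abs(v - median(v)) > cfg$skew_kurt_z * s))
  }
  flagged <- sort(unique(c(low_auto, neg_skew, out_stat)))
  for (j in flagged)
    acts[j, ] <- cancel_channel(acts[j, ], noise_win, fs, ccfg)$signal
  cs$mixing %*% acts + cs$center
}

#' Calibrate a simplified ASR model on a standing baseline
#'
#' Fixed PCA basis of the baseline scalp channels; per-component RMS over
#' 0.5 s baseline windows gives thresholds mean + k*SD.
#'
#' @param x baseline scalp block (channels x samples) or a
#'   `dual_layer_recording`.
#' @param fs sampling rate (from the recording if one is given).
#' @param k standard-deviation cutoff (default 7).
#' @param window_sec analysis window, s (default 0.5).
#' @return object of class `asr_model`.
#' @export
asr_calibrate <- function(x, fs = NULL, k = 7, window_sec = 0.5) {
  if (inherits(x, "dual_layer_recording")) {
    fs <- x$fs
    x <- x$eeg[good_channels(x), , drop = FALSE]
  }
  stopifnot(!is.null(fs))
  nwin <- round(window_sec * fs)
  n_windows <- floor(ncol(x) / nwin)
  if (n_windows < 10) stop("baseline shorter than 10 windows")
  ctr <- rowMeans(x)
  Xc <- x - ctr
  e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  V <- e$vectors
  scores <- t(V) %*% Xc
  rms <- sapply(seq_len(n_windows), function(i) {
    idx <- ((i - 1) * nwin + 1):(i * nwin)
    sqrt(rowMeans(scores[, idx, drop = FALSE]^2))
  })                                           # ncomp x n_windows
  thr <- rowMeans(rms) + k * apply(rms, 1, sd)
  structure(list(center = ctr, basis = V, thresholds = thr, k = k,
                 window_sec = window_sec, fs = fs), class = "asr_model")
}

#' Clean a recording with a calibrated ASR model
#'
#' Per 0.5 s sliding window (50% overlap, cross-faded), data are projected
#' onto the calibration basis; components whose window RMS exceeds their
#' calibrated threshold are reconstructed from the sub-threshold subspace
#' (which, in the uncorrelated calibration basis, removes the exceeding
#' components' contribution); thresholds of `Inf` leave the data untouched.
#'
#' @param x scalp block (channels x samples) or `dual_layer_recording`.
#' @param model an `asr_model` calibrated on matching channels.
#' @return cleaned object of the same type.
#' @export
asr_clean <- function(x, model) {
  if (inherits(x, "dual_layer_recording")) {
    gc_ <- good_channels(x)
    x$eeg[gc_, ] <- asr_clean(x$eeg[gc_, , drop = FALSE], model)
    return(x)
  }
  if (nrow(x) != length(model$center))
    stop("channel count does not match the calibration model")
  nwin <- round(model$window_sec * model$fs)
  hop <- max(1L, round(nwin / 2))
  V <- model$basis
  thr <- model$thresholds
  ctr <- model$center
  cleaned <- sliding_apply(x - ctr, nwin, hop, function(W) {
    Z <- t(V) %*% W
    rms <- sqrt(rowMeans(Z^2))
    bad <- which(rms > thr)
    if (length(bad)) Z[bad, ] <- 0
    V %*% Z
  })
  cleaned + ctr
}
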