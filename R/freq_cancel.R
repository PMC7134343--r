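## Sliding-window frequency-domain cancellation of artifacts in scalp
## channels against matched noise-layer channels.

#' Cancellation configuration
#'
#' @param window_sec STFT window length, s (default 0.5).
#' @param overlap_frac fractional window overlap (default 0.94).
#' @param upper_mult transient (motion) flag: bins whose noise magnitude
#'   exceeds `upper_mult` x the window's median noise magnitude (default 6).
#' @param lower_mult persistent (electrical) flag: bins whose noise magnitude
#'   exceeds `lower_mult` x the median in at least `persist_frac` of all
#'   windows (defaults 2 and 0.9).
#' @param persist_frac fraction of windows for the persistence criterion.
#' @param mode "subtract" (scaled magnitude subtraction along the EEG phase,
#'   floored at zero) or "zero" (flagged bins zeroed).
#' @param median_scope "window" (median over bins per window, default) or
#'   "global" (single median over all windows).
#' @return list of class `cancellation_config`.
#' @export
cancellation_config <- function(window_sec = 0.5, overlap_frac = 0.94,
                                upper_mult = 6, lower_mult = 2,
                                persist_frac = 0.9,
                                mode = c("subtract", "zero"),
                                median_scope = c("window", "global")) {
  stopifnot(overlap_frac >= 0, overlap_frac < 1,
            upper_mult > lower_mult, lower_mult > 0)
  structure(list(window_sec = window_sec, overlap_frac = overlap_frac,
                 upper_mult = upper_mult, lower_mult = lower_mult,
                 persist_frac = persist_frac, mode = match.arg(mode),
                 median_scope = match.arg(median_scope)),
            class = "cancellation_config")
}

#' Short-time Fourier transform
#'
#' Hann-tapered sliding-window FFT with the geometry stored for exact
#' weighted overlap-add inversion. The signal tail is zero-padded to cover
#' whole windows.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_sec window length, s.
#' @param overlap_frac fractional overlap; hop =
#'   `round(window_sec * fs * (1 - overlap_frac))`.
#' @return object of class `windowed_spectrum`: complex coefficient matrix
#'   (n_windows x n_bins) plus geometry.
#' @export
stft <- function(x, fs, window_sec = 0.5, overlap_frac = 0.94) {
  nwin <- round(window_sec * fs)
  if (length(x) < nwin) stop("signal shorter than one window")
  hop <- max(1L, as.integer(round(nwin * (1 - overlap_frac))))
  ## zero-pad both ends by a full window so every real sample sits under the
  ## complete window stack: per-sample overlap-add weights are then at full
  ## strength everywhere, and modified spectra cannot be edge-amplified
  npad <- nwin
  starts <- seq(1L, by = hop,
                length.out = ceiling((npad + length(x)) / hop) + 1L)
  xp <- c(numeric(npad), x,
          numeric(starts[length(starts)] + nwin - 1L - npad - length(x)))
  w <- hann_window(nwin)
  coeffs <- matrix(0 + 0i, length(starts), nwin)
  for (i in seq_along(starts)) {
    seg <- xp[starts[i]:(starts[i] + nwin - 1L)]
    coeffs[i, ] <- fft(seg * w)
  }
  structure(list(coeffs = coeffs, window_starts = starts, nwin = nwin,
                 hop = hop, fs = fs, n = length(x), npad = npad,
                 window = "hann"),
            class = "windowed_spectrum")
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add with per-sample window-power compensation; with
#' unmodified coefficients this reproduces the analyzed signal exactly
#' wherever the window coverage is nonzero.
#'
#' @param W a `windowed_spectrum`.
#' @return numeric signal of the original length.
#' @export
istft <- function(W) {
  stopifnot(inherits(W, "windowed_spectrum"))
  w <- hann_window(W$nwin)
  total <- max(W$window_starts) + W$nwin - 1L
  acc <- numeric(total)
  norm <- numeric(total)
  for (i in seq_along(W$window_starts)) {
    idx <- W$window_starts[i]:(W$window_starts[i] + W$nwin - 1L)
    seg <- Re(fft(W$coeffs[i, ], inverse = TRUE)) / W$nwin
    acc[idx] <- acc[idx] + seg * w
    norm[idx] <- norm[idx] + w^2
  }
  out <- numeric(total)
  ok <- norm > 1e-12
  out[ok] <- acc[ok] / norm[ok]
  out[W$npad + seq_len(W$n)]
}

## positive-frequency bin indices (excluding DC) of an n-point FFT
pos_bins <- function(n) 2:(floor(n / 2) + 1L)

## mirror partner of bin k in an n-point FFT (k and mirror share magnitude)
mirror_bins <- function(bins, n) {
  mb <- n - bins + 2L
  mb[bins == 1L] <- 1L
  mb
}

flag_bins <- function(Wn, cfg) {
  n <- Wn$nwin
  pb <- pos_bins(n)
  mag <- Mod(Wn$coeffs[, pb, drop = FALSE])
  med <- apply(mag, 1, median)
  if (cfg$median_scope == "global") med[] <- median(mag)
  upper <- mag > cfg$upper_mult * med          # transient / motion pass
  exceed_lower <- mag > cfg$lower_mult * med
  zero_med <- med <= .Machine$double.eps       # degenerate: nothing to cancel
  upper[zero_med, ] <- FALSE
  exceed_lower[zero_med, ] <- FALSE
  persistent <- colMeans(exceed_lower) >= cfg$persist_frac
  flags <- upper | matrix(persistent, nrow(mag), ncol(mag), byrow = TRUE)
  flags[zero_med, ] <- FALSE
  list(flags = flags, pb = pb, noise_med = med)
}

#' Cancel noise-layer artifacts from one EEG channel
#'
#' Both channels are transformed with the same sliding-window FFT. Per window,
#' frequency bins are flagged where the noise magnitude exceeds
#' `upper_mult` x that window's median noise magnitude (transient motion
#' pass), or exceeds `lower_mult` x the median in at least `persist_frac` of
#' all windows (persistent electrical pass). At flagged bins the noise
#' coefficient, rescaled so the window's median noise magnitude matches the
#' window's median EEG magnitude, is subtracted from the EEG magnitude (floored
#' at zero, EEG phase retained); the channel is then reconstructed by inverse
#' transform. All criteria are median-relative, so the operation is
#' scale-equivariant, and a zero noise channel leaves the input untouched.
#'
#' @param eeg_ch,noise_ch equal-length signals; `noise_ch` is the (virtual)
#'   matched noise pair of `eeg_ch`.
#' @param fs sampling rate, Hz.
#' @param cfg a [cancellation_config()].
#' @return list with `signal` (cleaned channel) and `n_flagged` (flagged-bin
#'   count per window).
#' @export
cancel_channel <- function(eeg_ch, noise_ch, fs, cfg = cancellation_config()) {
  if (length(eeg_ch) != length(noise_ch)) stop("length mismatch")
  We <- stft(eeg_ch, fs, cfg$window_sec, cfg$overlap_frac)
  Wn <- stft(noise_ch, fs, cfg$window_sec, cfg$overlap_frac)
  fb <- flag_bins(Wn, cfg)
  n <- We$nwin
  pb <- fb$pb
  mb <- mirror_bins(pb, n)
  eeg_mag <- Mod(We$coeffs[, pb, drop = FALSE])
  eeg_med <- apply(eeg_mag, 1, median)
  scale <- ifelse(fb$noise_med > .Machine$double.eps,
                  eeg_med / fb$noise_med, 0)
  for (i in seq_len(nrow(We$coeffs))) {
    f <- which(fb$flags[i, ])
    if (!length(f)) next
    bins <- pb[f]
    X <- We$coeffs[i, bins]
    Nmag <- Mod(Wn$coeffs[i, bins]) * scale[i]
    if (cfg$mode == "zero") {
      newX <- 0 + 0i
    } else {
      ## complex subtraction of the rescaled noise coefficient: in-phase
      ## artifact content cancels while residual content at the same bin is
      ## retained; floored so a bin is never amplified -- if the scaled noise
      ## magnitude exceeds the EEG magnitude the bin is cancelled to the
      ## magnitude margin (zero when the noise coefficient dominates)
      Xmag <- Mod(X)
      newX <- X - scale[i] * Wn$coeffs[i, bins]
      floor_mag <- pmax(Xmag - Nmag, 0)
      over <- Mod(newX) > Xmag
      if (any(over)) {
        nm_ <- Mod(newX[over])
        newX[over] <- ifelse(nm_ > 0, newX[over] * floor_mag[over] / nm_,
                             0 + 0i)
      }
    }
    We$coeffs[i, bins] <- newX
    We$coeffs[i, mb[f]] <- Conj(newX)
  }
  list(signal = istft(We), n_flagged = rowSums(fb$flags))
}

#' Amplitude-matched noise signal
#'
#' Rescales the noise channel, window by window, so its median Fourier
#' magnitude matches the paired EEG channel's, compensating the impedance
#' difference between the artificial-skin circuit and the scalp; used later as
#' stacked input to ICA.
#'
#' @inheritParams cancel_channel
#' @return rescaled noise signal of the same length.
#' @export
amplitude_matched_noise <- function(eeg_ch, noise_ch, fs,
                                    cfg = cancellation_config()) {
  if (length(eeg_ch) != length(noise_ch)) stop("length mismatch")
  We <- stft(eeg_ch, fs, cfg$window_sec, cfg$overlap_frac)
  Wn <- stft(noise_ch, fs, cfg$window_sec, cfg$overlap_frac)
  pb <- pos_bins(Wn$nwin)
  for (i in seq_len(nrow(Wn$coeffs))) {
    nmed <- median(Mod(Wn$coeffs[i, pb]))
    emed <- median(Mod(We$coeffs[i, pb]))
    s <- if (nmed > .Machine$double.eps) emed / nmed else 0
    Wn$coeffs[i, ] <- Wn$coeffs[i, ] * s
  }
  istft(Wn)
}

#' Cancel artifacts across all scalp channels of a recording
#'
#' Applies [cancel_channel()] to every non-bad scalp channel against its
#' virtual matched-noise channel; noise and EMG blocks are untouched.
#'
#' @param rec a `dual_layer_recording`.
#' @param virtual_noise n_eeg x n_samples matrix from
#'   [interpolate_noise_layer()].
#' @param cfg a [cancellation_config()].
#' @return list with `recording` (cleaned) and `flag_counts` (total flagged
#'   bins per channel).
#' @export
cancel_recording <- function(rec, virtual_noise, cfg = cancellation_config()) {
  if (is.null(virtual_noise)) stop("missing virtual noise channels")
  stopifnot(nrow(virtual_noise) == nrow(rec$eeg),
            ncol(virtual_noise) == ncol(rec$eeg))
  counts <- numeric(nrow(rec$eeg))
  for (ch in good_channels(rec)) {
    res <- cancel_channel(rec$eeg[ch, ], virtual_noise[ch, ], rec$fs, cfg)
    rec$eeg[ch, ] <- res$signal
    counts[ch] <- sum(res$n_flagged)
  }
  list(recording = rec, flag_counts = counts)
}
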