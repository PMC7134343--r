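## Channel-domain conditioning shared by all pipeline variants.

apply_rows <- function(m, fun) {
  if (nrow(m) == 0) return(m)
  t(apply(m, 1, fun))
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase) to every
#' channel block of a recording, or to a vector/matrix directly.
#'
#' @param x a `dual_layer_recording`, numeric vector, or channels x samples
#'   matrix.
#' @param cutoff high-pass cutoff, Hz.
#' @param fs sampling rate (taken from the recording when `x` is one).
#' @param order filter order (default 4).
#' @return object of the same shape, filtered.
#' @export
highpass <- function(x, cutoff = 1, fs = NULL, order = 4) UseMethod("highpass")

#' @export
highpass.default <- function(x, cutoff = 1, fs = NULL, order = 4) {
  stopifnot(!is.null(fs))
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  ## remove the mean first: the filter kills DC asymptotically, but the
  ## forward-backward transient on a large offset decays slowly
  filt1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.matrix(x)) apply_rows(x, filt1) else filt1(x)
}

#' @export
highpass.dual_layer_recording <- function(x, cutoff = 1, fs = NULL, order = 4) {
  fs <- fs %||% x$fs
  for (blk in c("eeg", "noise", "emg"))
    x[[blk]] <- highpass.default(x[[blk]], cutoff, fs, order)
  x
}

#' Reject outlier scalp channels by kurtosis and spread
#'
#' Marks scalp channels bad when the robust z-score (median/MAD) of their
#' sample kurtosis or of their log standard deviation exceeds `z_thresh`.
#' Noise and EMG blocks are untouched.
#'
#' @param rec a `dual_layer_recording` with at least 8 scalp channels.
#' @param z_thresh robust z threshold (default 5).
#' @return list with `recording` (bad_channels updated) and `report` data
#'   frame (channel, kurtosis_z, log_sd_z, rejected).
#' @export
reject_channels <- function(rec, z_thresh = 5) {
  stopifnot(nrow(rec$eeg) >= 8)
  ku <- apply(rec$eeg, 1, e1071::kurtosis)
  lsd <- log(apply(rec$eeg, 1, sd))
  zk <- robust_z(ku); zs <- robust_z(lsd)
  bad <- which(abs(zk) > z_thresh | abs(zs) > z_thresh)
  if (length(bad) == nrow(rec$eeg)) stop("all scalp channels rejected")
  rec$bad_channels <- sort(unique(c(rec$bad_channels, bad)))
  list(recording = rec,
       report = data.frame(channel = seq_len(nrow(rec$eeg)),
                           kurtosis_z = zk, log_sd_z = zs,
                           rejected = seq_len(nrow(rec$eeg)) %in% bad))
}

#' Re-reference scalp channels to an average
#'
#' `type = "robust"` subtracts the mean of non-bad scalp channels from all
#' scalp channels (bad channels excluded from the reference but still
#' re-referenced); `type = "common"` uses the plain all-channel average.
#' Idempotent.
#'
#' @param rec a `dual_layer_recording`.
#' @param type "robust" or "common".
#' @return the re-referenced recording.
#' @export
rereference <- function(rec, type = c("robust", "common")) {
  type <- match.arg(type)
  keep <- if (type == "robust") good_channels(rec) else seq_len(nrow(rec$eeg))
  ref <- colMeans(rec$eeg[keep, , drop = FALSE])
  rec$eeg <- sweep(rec$eeg, 2, ref)
  rec
}

#' Downsample a recording
#'
#' Anti-alias FIR decimation of every channel block by an integer factor;
#' gait-event indices attached by callers must be rescaled separately with
#' [rescale_events()]. Upsampling is not supported.
#'
#' @param rec a `dual_layer_recording` (or matrix/vector with `fs` given).
#' @param target target rate, Hz; must divide `fs`.
#' @param fs source rate when `rec` is not a recording.
#' @return downsampled object (recordings keep class and metadata).
#' @export
resample_recording <- function(rec, target, fs = NULL) {
  if (inherits(rec, "dual_layer_recording")) {
    fs <- rec$fs
    if (target > fs) stop("upsampling is not supported")
    if (target == fs) return(rec)
    for (blk in c("eeg", "noise", "emg"))
      rec[[blk]] <- resample_recording(rec[[blk]], target, fs = fs)
    rec$fs <- target
    return(rec)
  }
  if (target > fs) stop("upsampling is not supported")
  if (target == fs) return(rec)
  q <- fs / target
  if (abs(q - round(q)) > 1e-9) stop("fs must be an integer multiple of target")
  q <- as.integer(round(q))
  dec1 <- function(v) signal::decimate(v, q, ftype = "fir")
  if (is.matrix(rec)) apply_rows(rec, dec1) else dec1(rec)
}

#' Rescale gait-event indices to a new sampling rate
#'
#' @param events a `gait_event_table`.
#' @param target new rate, Hz.
#' @param n_samples optional new recording length.
#' @return a `gait_event_table` on the new clock (indices rounded to the
#'   nearest sample).
#' @export
rescale_events <- function(events, target, n_samples = NULL) {
  r <- target / events$fs
  sc <- function(x) pmax(1, round((x - 1) * r) + 1)
  gait_event_table(rhs = sc(events$rhs), lhs = sc(events$lhs),
                   rto = sc(events$rto), lto = sc(events$lto),
                   fs = target, n_samples = n_samples)
}

## ---- spherical spline interpolation (Perrin-style) ----

## g(cos angle) kernel as a truncated Legendre series.
spline_g <- function(cosang, m = 4, nterms = 50) {
  ## Legendre recurrence evaluated at all cosang simultaneously
  dm <- dim(cosang)
  x <- as.vector(cosang)
  P_prev <- rep(1, length(x))   # P_0
  P_cur <- x                    # P_1
  out <- (2 * 1 + 1) / (1^m * 2^m) * P_cur
  for (l in 2:nterms) {
    P_next <- ((2 * l - 1) * x * P_cur - (l - 1) * P_prev) / l
    out <- out + (2 * l + 1) / (l^m * (l + 1)^m) * P_next
    P_prev <- P_cur; P_cur <- P_next
  }
  out <- out / (4 * pi)
  dim(out) <- dm
  out
}

#' Spherical-spline spatial interpolation
#'
#' Interpolates values measured at source electrode positions onto target
#' positions on the unit sphere (positions are normalized to unit length).
#' Constant fields are reproduced exactly through the constraint term.
#'
#' @param pos_from n_src x 3 source positions.
#' @param pos_to n_dst x 3 target positions.
#' @param values n_src vector or n_src x n matrix of measurements.
#' @param m spline stiffness order (default 4).
#' @param lambda ridge smoothing (default 1e-5).
#' @param nterms Legendre-series truncation (default 50).
#' @return interpolated values at `pos_to` (vector or n_dst x n matrix).
#' @export
spherical_spline_interp <- function(pos_from, pos_to, values, m = 4,
                                    lambda = 1e-5, nterms = 50) {
  normr <- function(p) p / sqrt(rowSums(p^2))
  pos_from <- normr(as.matrix(pos_from)); pos_to <- normr(as.matrix(pos_to))
  if (any(!is.finite(pos_from)) || any(!is.finite(pos_to)))
    stop("missing electrode positions")
  ns <- nrow(pos_from)
  clamp <- function(M) { M[M > 1] <- 1; M[M < -1] <- -1; M }
  G <- spline_g(clamp(tcrossprod(pos_from)), m, nterms)
  A <- rbind(cbind(G + diag(lambda, ns), rep(1, ns)), c(rep(1, ns), 0))
  vals <- as.matrix(values)
  rhs <- rbind(vals, 0)
  sol <- solve(A, rhs)
  C <- sol[seq_len(ns), , drop = FALSE]
  c0 <- sol[ns + 1, , drop = FALSE]
  Gt <- spline_g(clamp(tcrossprod(pos_to, pos_from)), m, nterms)
  out <- Gt %*% C + matrix(1, nrow(pos_to), 1) %*% c0
  if (is.null(dim(values))) drop(out) else out
}

#' Interpolate the noise layer onto all scalp positions
#'
#' Spherical-spline interpolation of the noise-layer channels onto every scalp
#' electrode position, producing one virtual matched-noise channel per scalp
#' channel for frequency-domain cancellation.
#'
#' @param rec a `dual_layer_recording` with montage positions for scalp and
#'   noise channels.
#' @param m,lambda,nterms spline hyperparameters (see
#'   [spherical_spline_interp()]).
#' @return matrix n_eeg x n_samples of virtual noise channels.
#' @export
interpolate_noise_layer <- function(rec, m = 4, lambda = 1e-5, nterms = 50) {
  if (is.null(rec$montage)) stop("missing montage positions")
  lab <- rec$montage$label
  scalp_pos <- as.matrix(rec$montage[grepl("^EEG", lab), c("x", "y", "z")])
  noise_pos <- as.matrix(rec$montage[grepl("^NZ", lab), c("x", "y", "z")])
  if (nrow(scalp_pos) != nrow(rec$eeg) || nrow(noise_pos) != nrow(rec$noise))
    stop("montage does not cover all scalp and noise channels")
  ## interpolate sample-wise: solve the spline system once (positions fixed)
  spherical_spline_interp(noise_pos, scalp_pos, rec$noise, m, lambda, nterms)
}
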