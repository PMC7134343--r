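## Gait-event detection, stride epoching, time-warped ERSP with bootstrap
## significance masking, and permutation statistics across speed conditions.

#' Detect gait events from vertical ground reaction force
#'
#' Heel strike = upward crossing of the force threshold, toe off = downward
#' crossing, per limb, with a debounce interval suppressing re-crossings.
#'
#' @param grf_left,grf_right vertical GRF traces, newtons.
#' @param fs sampling rate, Hz.
#' @param thresh_N force threshold (default 20 N).
#' @param debounce_sec minimum time between same-type events (default 0.1 s).
#' @return a [gait_event_table()].
#' @export
detect_gait_events <- function(grf_left, grf_right, fs, thresh_N = 20,
                               debounce_sec = 0.1) {
  crossings <- function(f) {
    above <- f >= thresh_N
    up <- which(diff(above) == 1) + 1L
    down <- which(diff(above) == -1) + 1L
    if (above[1]) up <- c(1L, up)
    deb <- function(idx) {
      if (length(idx) < 2) return(idx)
      keep <- idx[1]
      for (i in idx[-1]) if (i - keep[length(keep)] >= debounce_sec * fs)
        keep <- c(keep, i)
      keep
    }
    list(hs = deb(up), to = deb(down))
  }
  L <- crossings(grf_left)
  R <- crossings(grf_right)
  if (!length(L$hs) || !length(R$hs))
    stop("no gait events detected: force never crosses the threshold")
  gait_event_table(rhs = R$hs, lhs = L$hs, rto = R$to, lto = L$to, fs = fs,
                   n_samples = length(grf_left))
}

#' Extract stride epochs delimited by right heel strikes
#'
#' One epoch per valid stride (consecutive right heel strikes with in-order
#' lto < lhs < rto between them); epochs overlapping `bad_spans` are dropped.
#'
#' @param x signal vector or channels x samples matrix.
#' @param events a `gait_event_table` on the same sample clock.
#' @param bad_spans optional 2-column matrix of sample spans to avoid.
#' @param margin_sec context margin carried on both sides of each epoch
#'   (default 0); time-frequency consumers use it so wavelet estimates at the
#'   stride boundaries rest on real neighbouring data.
#' @return list of class `stride_epochs`: `epochs` (list of vectors/matrices,
#'   including any margin), `latencies` (per-epoch sample offsets of lto,
#'   lhs, rto, end, relative to the stride start), `starts` (stride start
#'   samples), `lead` (per-epoch left-margin length), `fs`.
#' @export
epoch_strides <- function(x, events, bad_spans = NULL, margin_sec = 0) {
  st <- events$strides
  if (is.null(st) || sum(st$valid) < 3)
    stop("need at least 3 valid strides to epoch")
  st <- st[st$valid, , drop = FALSE]
  n <- if (is.matrix(x)) ncol(x) else length(x)
  marg <- round(margin_sec * events$fs)
  epochs <- list(); lats <- list(); starts <- numeric(0); leads <- integer(0)
  for (i in seq_len(nrow(st))) {
    a <- st$rhs[i]; b <- st$rhs_next[i]
    if (b > n) next
    if (!is.null(bad_spans) &&
        any(pmax(a, bad_spans[, 1]) <= pmin(b, bad_spans[, 2]))) next
    a2 <- max(1L, a - marg); b2 <- min(n, b + marg)
    epochs[[length(epochs) + 1L]] <-
      if (is.matrix(x)) x[, a2:b2, drop = FALSE] else x[a2:b2]
    lats[[length(lats) + 1L]] <- c(lto = st$lto[i] - a, lhs = st$lhs[i] - a,
                                   rto = st$rto[i] - a, end = b - a)
    starts <- c(starts, a)
    leads <- c(leads, a - a2)
  }
  if (length(epochs) < 3) stop("fewer than 3 usable stride epochs")
  structure(list(epochs = epochs, latencies = lats, starts = starts,
                 lead = leads, fs = events$fs), class = "stride_epochs")
}

## wavelet transform of an epoch carried with context margin, trimmed back to
## the stride span
stride_tfr <- function(ep, i, freqs, fs, cycles = c(3, 8)) {
  tfr <- single_trial_tfr(ep$epochs[[i]], freqs, fs, cycles)
  lead <- ep$lead[i]
  len <- ep$latencies[[i]][["end"]] + 1L
  tfr[, (lead + 1L):(lead + len), drop = FALSE]
}

#' Morlet-wavelet time-frequency transform of one epoch
#'
#' Complex Morlet wavelets with cycle counts scaling linearly from
#' `cycles[1]` at the lowest frequency to `cycles[2]` at the highest;
#' log power in dB.
#'
#' @param epoch signal vector.
#' @param freqs analysis frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @param cycles length-2 cycle range (default c(3, 8)).
#' @return matrix length(freqs) x length(epoch) of log power (dB).
#' @export
single_trial_tfr <- function(epoch, freqs, fs, cycles = c(3, 8)) {
  n <- length(epoch)
  ncyc <- if (length(freqs) > 1)
    cycles[1] + (cycles[2] - cycles[1]) *
      (freqs - min(freqs)) / (max(freqs) - min(freqs))
  else rep(cycles[1], 1)
  max_len <- max(ceiling(ncyc / freqs * fs * 3))
  if (n < max_len %/% 3)
    stop("epoch shorter than the longest wavelet")
  ## reflection padding: without context the wavelet power rolls off at the
  ## epoch edges, which would masquerade as cycle-locked modulation
  pad <- min(n - 1, ceiling(max_len / 2))
  xp <- c(epoch[(pad + 1):2], epoch, epoch[(n - 1):(n - pad)])
  np <- length(xp)
  nfft <- 2^ceiling(log2(np + max_len))
  X <- fft(c(xp, numeric(nfft - np)))
  out <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sd_t <- ncyc[k] / (2 * pi * f)
    half <- ceiling(3 * sd_t * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sum(Mod(w))
    W <- fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- fft(X * W, inverse = TRUE) / nfft
    idx <- (half + pad + 1):(half + pad + n)
    out[k, ] <- 10 * log10(pmax(Mod(conv[idx])^2, 1e-300))
  }
  out
}

#' Warp an epoch's time axis onto the common gait-cycle grid
#'
#' Piecewise-linear mapping so the epoch's event latencies {0, lto, lhs, rto,
#' end} land on the target (across-epoch median) latencies, then resampling
#' onto a fixed percent-of-gait-cycle grid; 0% and 100% both correspond to
#' right heel strike.
#'
#' @param tfr freq x time matrix (or any row-wise signal matrix).
#' @param latencies named per-epoch latencies (lto, lhs, rto, end), samples.
#' @param targets named target latencies on the same scale.
#' @param n_grid output grid resolution (default 200).
#' @return freq x n_grid matrix on the 0-100% axis.
#' @export
time_warp <- function(tfr, latencies, targets, n_grid = 200) {
  anchors_src <- c(0, latencies[["lto"]], latencies[["lhs"]],
                   latencies[["rto"]], latencies[["end"]])
  anchors_dst <- c(0, targets[["lto"]], targets[["lhs"]],
                   targets[["rto"]], targets[["end"]])
  if (any(diff(anchors_src) <= 0) || any(diff(anchors_dst) <= 0))
    stop("event latencies must be strictly increasing")
  grid_dst <- seq(0, anchors_dst[5], length.out = n_grid)
  grid_src <- approx(anchors_dst, anchors_src, xout = grid_dst)$y
  src_axis <- seq(0, by = 1, length.out = ncol(tfr))
  out <- t(apply(tfr, 1, function(v)
    approx(src_axis, v, xout = grid_src, rule = 2)$y))
  out
}

#' Event-related spectral perturbation over the gait cycle
#'
#' Baseline = per-frequency mean log power over the full gait cycle within the
#' condition; ERSP = epoch mean of (log power - baseline) on the warped grid.
#' Significance by a surrogate distribution: each bootstrap draws one random
#' time column per epoch, averages across epochs, and the resulting
#' per-frequency deviations from baseline form the null; cells whose empirical
#' two-tailed p exceeds `alpha` are zeroed in the masked view.
#'
#' @param tfrs list of warped freq x time log-power matrices (equal shape), or
#'   a `stride_epochs` of raw epochs together with `freqs`.
#' @param freqs analysis frequencies (required when `tfrs` is a
#'   `stride_epochs`).
#' @param n_boot bootstrap iterations (default 200; < 50 warns).
#' @param alpha two-tailed significance level (default 0.05).
#' @param seed RNG seed for the bootstrap.
#' @param n_grid warp grid (used when warping raw epochs).
#' @param cycles wavelet cycle range for raw epochs.
#' @return object of class `ersp_result`: `power` (dB re. condition baseline),
#'   `masked`, `mask`, `p`, `freqs`, `pct` (0-100), `baseline`, `n_epochs`,
#'   `targets` (median warp latencies, if warped here), bootstrap settings.
#' @export
ersp <- function(tfrs, freqs = NULL, n_boot = 200, alpha = 0.05, seed = 1,
                 n_grid = 200, cycles = c(3, 8)) {
  targets <- NULL
  if (inherits(tfrs, "stride_epochs")) {
    stopifnot(!is.null(freqs))
    ep <- tfrs
    lat <- do.call(rbind, ep$latencies)
    targets <- apply(lat, 2, median)
    tfrs <- lapply(seq_along(ep$epochs), function(i)
      time_warp(stride_tfr(ep, i, freqs, ep$fs, cycles),
                ep$latencies[[i]], as.list(targets), n_grid))
  }
  n_ep <- length(tfrs)
  if (n_ep < 3) stop("need at least 3 epochs")
  if (n_boot < 50) warning("n_boot < 50 gives a coarse significance mask")
  arr <- simplify2array(tfrs)                  # freq x time x epoch
  nf <- dim(arr)[1]; nt <- dim(arr)[2]
  baseline <- apply(arr, 1, mean)
  mean_tf <- apply(arr, c(1, 2), mean)
  power <- mean_tf - baseline
  set.seed(seed)
  surro <- array(0, c(nf, n_boot))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(nt, n_ep, replace = TRUE)
    acc <- matrix(0, nf, 1)
    for (i in seq_len(n_ep)) acc <- acc + arr[, cols[i], i]
    surro[, b] <- acc / n_ep - baseline
  }
  p <- matrix(1, nf, nt)
  for (f in seq_len(nf)) {
    dev <- abs(power[f, ])
    sdev <- abs(surro[f, ])
    p[f, ] <- (1 + vapply(dev, function(d) sum(sdev >= d), 0)) / (n_boot + 1)
  }
  mask <- p <= alpha
  masked <- power * mask
  structure(list(power = power, masked = masked, mask = mask, p = p,
                 freqs = if (!is.null(freqs)) freqs else seq_len(nf),
                 pct = seq(0, 100, length.out = nt), baseline = baseline,
                 n_epochs = n_ep, targets = targets,
                 n_boot = n_boot, alpha = alpha, seed = seed),
            class = "ersp_result")
}

#' @export
print.ersp_result <- function(x, ...) {
  cat(sprintf("ERSP: %d frequencies x %d gait-cycle points, %d epochs\n",
              length(x$freqs), length(x$pct), x$n_epochs))
  cat(sprintf("  significant cells at alpha=%.3g: %.1f%%\n",
              x$alpha, 100 * mean(x$mask)))
  invisible(x)
}

#' Plot an ERSP as a gait-cycle time-frequency image
#'
#' @param x an `ersp_result`.
#' @param masked plot the significance-masked view (default TRUE).
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image abline axis
#' @importFrom grDevices hcl.colors
#' @export
plot.ersp_result <- function(x, masked = TRUE, ...) {
  z <- if (masked) x$masked else x$power
  lim <- max(abs(z), 1e-6)
  image(x$pct, x$freqs, t(z), xlab = "% gait cycle (RHS to RHS)",
        ylab = "Frequency (Hz)", zlim = c(-lim, lim),
        col = hcl.colors(64, "RdBu", rev = TRUE), ...)
  if (!is.null(x$targets)) {
    tot <- x$targets[["end"]]
    for (ev in c("lto", "lhs", "rto"))
      abline(v = 100 * x$targets[[ev]] / tot, lty = 2)
  }
  invisible(x)
}

#' Compare spectral power across speed conditions
#'
#' Per frequency, a one-way F statistic across conditions of per-epoch mean
#' log power, with the null built by permuting condition labels across
#' epochs; p = permutation tail probability, masked at `alpha`.
#'
#' @param spectra named list (one element per condition) of epochs x
#'   frequencies matrices of mean log power (dB).
#' @param freqs frequency axis, Hz.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return object of class `speed_comparison`: `means` (condition x freq),
#'   `p`, `mask`, `F`, `freqs`, settings.
#' @export
speed_comparison <- function(spectra, freqs = NULL, n_perm = 1000,
                             alpha = 0.05, seed = 1) {
  if (length(spectra) < 2) stop("need at least 2 conditions")
  groups <- rep(seq_along(spectra), vapply(spectra, nrow, 0L))
  X <- do.call(rbind, spectra)                 # all epochs x freqs
  nf <- ncol(X)
  freqs <- freqs %||% seq_len(nf)
  fstat <- function(g) {
    ## one-way F per column, vectorized over frequencies
    k <- max(g); n <- length(g)
    gm <- colMeans(X)
    ssb <- 0; ssw <- 0
    for (j in seq_len(k)) {
      Xi <- X[g == j, , drop = FALSE]
      mi <- colMeans(Xi)
      ssb <- ssb + nrow(Xi) * (mi - gm)^2
      ssw <- ssw + colSums(sweep(Xi, 2, mi)^2)
    }
    (ssb / (k - 1)) / pmax(ssw / (n - k), 1e-300)
  }
  Fobs <- fstat(groups)
  set.seed(seed)
  exceed <- numeric(nf)
  for (b in seq_len(n_perm))
    exceed <- exceed + (fstat(sample(groups)) >= Fobs)
  p <- (1 + exceed) / (n_perm + 1)
  means <- do.call(rbind, lapply(spectra, colMeans))
  structure(list(means = means, p = p, mask = p <= alpha, F = Fobs,
                 freqs = freqs, n_perm = n_perm, alpha = alpha, seed = seed),
            class = "speed_comparison")
}

#' @export
print.speed_comparison <- function(x, ...) {
  cat(sprintf("Speed comparison: %d conditions, %d frequencies; %d significant at alpha=%.3g\n",
              nrow(x$means), length(x$freqs), sum(x$mask), x$alpha))
  invisible(x)
}

## Per-epoch mean log-power spectra (epochs x freqs) from raw stride epochs,
## via the wavelet transform used everywhere else.
epoch_mean_spectra <- function(ep, freqs, cycles = c(3, 8)) {
  t(vapply(ep$epochs, function(epoch)
    rowMeans(single_trial_tfr(epoch, freqs, ep$fs, cycles)),
    numeric(length(freqs))))
}

#' Channel-level gait analysis of noise or EMG channels
#'
#' Applies the standard channel conditioning (1 Hz high-pass, downsampling),
#' stride epoching, and the time-warped ERSP with bootstrap masking to raw
#' noise-layer or EMG channels -- the artifact-reference view of the gait
#' cycle. Selected channels are pooled: each channel's stride epochs enter the
#' ERSP as additional trials.
#'
#' @param rec a `dual_layer_recording`.
#' @param events gait events on the recording's original clock.
#' @param role "noise" or "emg".
#' @param channels channel indices within the role block (default: all).
#' @param freqs analysis frequencies, Hz (default 3-100 Hz, log-spaced).
#' @param resample_hz analysis rate (default 256).
#' @param n_boot,alpha,seed passed to [ersp()].
#' @return an `ersp_result`; the per-epoch mean spectra are attached as
#'   attribute "spectra" for use in [speed_comparison()].
#' @export
channel_level_analysis <- function(rec, events, role = c("noise", "emg"),
                                   channels = NULL,
                                   freqs = exp(seq(log(3), log(100),
                                                   length.out = 30)),
                                   resample_hz = 256, n_boot = 200,
                                   alpha = 0.05, seed = 1) {
  role <- match.arg(role)
  blk <- rec[[role]]
  channels <- channels %||% seq_len(nrow(blk))
  blk <- blk[channels, , drop = FALSE]
  blk <- highpass(blk, 1, fs = rec$fs)
  if (resample_hz < rec$fs) {
    blk <- resample_recording(blk, resample_hz, fs = rec$fs)
    events <- rescale_events(events, resample_hz, n_samples = ncol(blk))
  }
  fs <- min(resample_hz, rec$fs)
  freqs <- freqs[freqs < fs / 2]
  all_tfrs <- list(); all_spec <- NULL
  targets <- NULL
  for (ch in seq_len(nrow(blk))) {
    ep <- epoch_strides(blk[ch, ], events, margin_sec = 0.3)
    if (is.null(targets)) {
      lat <- do.call(rbind, ep$latencies)
      targets <- as.list(apply(lat, 2, median))
    }
    for (i in seq_along(ep$epochs)) {
      tfr <- stride_tfr(ep, i, freqs, fs)
      all_tfrs[[length(all_tfrs) + 1L]] <-
        time_warp(tfr, ep$latencies[[i]], targets)
      all_spec <- rbind(all_spec, rowMeans(tfr))
    }
  }
  res <- ersp(all_tfrs, freqs = freqs, n_boot = n_boot, alpha = alpha,
              seed = seed)
  res$targets <- targets
  attr(res, "spectra") <- all_spec
  res
}
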