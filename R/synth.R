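## Synthetic dual-layer walking-EEG generator. Every downstream stage is
## exercised against recordings whose brain, motion-artifact, EMG-leakage and
## line-noise parts are known exactly, so recovery can be scored against
## ground truth rather than eyeballed.

#' Synthetic-generator configuration
#'
#' Amplitudes are microvolts RMS unless noted. Per-speed gains are piecewise
#' linear in walking speed between the anchor points given as `x` (m/s) and
#' `y` (multiplier); the defaults program the study conditions: cortical
#' alpha/beta power decreasing, and motion/EMG artifact amplitude increasing,
#' with speed.
#'
#' @param n_eeg,n_noise,n_emg channel counts (defaults 128/40/8).
#' @param fs sampling rate, Hz.
#' @param brain list: `pink_rms` background 1/f level; `alpha_amp`, `beta_amp`
#'   oscillation amplitudes; `alpha_freq`, `beta_freq` (Hz); `mod_depth`
#'   gait-phase envelope modulation depth in [0,1]; `speed_gain` anchors.
#' @param motion list: `burst_amp` heel-strike burst scale; `gain_range`
#'   per-channel coupling gain range between layers; `decorr` fractional RMS of
#'   layer-decorrelation noise; `speed_gain` anchors.
#' @param emg list: `rms` EMG-channel level; `leak_gain` peak scalp-leakage
#'   fraction; `mod_depth`; `band` (Hz); `speed_gain` anchors.
#' @param line list: `freq` (Hz), `amp`.
#' @param sensor_rms white sensor-noise level.
#' @param stride list: `cv` stride-time coefficient of variation; `phasing`
#'   within-stride event fractions (lto, lhs, rto).
#' @return nested configuration list of class `synth_config`.
#' @export
synth_config <- function(n_eeg = 128, n_noise = 40, n_emg = 8, fs = 512,
                         brain = list(), motion = list(), emg = list(),
                         line = list(), sensor_rms = 1, stride = list()) {
  merge_cfg <- function(def, user) { def[names(user)] <- user; def }
  structure(list(
    n_eeg = n_eeg, n_noise = n_noise, n_emg = n_emg, fs = fs,
    brain = merge_cfg(list(pink_rms = 3, bg_rms = 3, alpha_amp = 2,
                           beta_amp = 1,
                           alpha_freq = 10, beta_freq = 20, mod_depth = 0.5,
                           speed_gain = list(x = c(0.5, 2.0), y = c(1.0, 0.7))),
                      brain),
    motion = merge_cfg(list(burst_amp = 40, gain_range = c(0.5, 2.0),
                            decorr = 0.05,
                            speed_gain = list(x = c(0.5, 2.0), y = c(0.6, 1.8))),
                       motion),
    emg = merge_cfg(list(rms = 30, leak_gain = 0.15, mod_depth = 0.6,
                         band = c(20, 124),
                         speed_gain = list(x = c(0.5, 2.0), y = c(0.7, 1.6))),
                    emg),
    line = merge_cfg(list(freq = 60, amp = 2), line),
    sensor_rms = sensor_rms,
    stride = merge_cfg(list(cv = 0.03,
                            phasing = c(lto = 0.12, lhs = 0.50, rto = 0.62)),
                       stride)), class = "synth_config")
}

speed_gain_at <- function(anchors, speed) {
  approx(anchors$x, anchors$y, xout = speed, rule = 2)$y
}

## Stride period (s) as a function of walking speed: log-linear between
## 1.6 s at 0.5 m/s and 1.0 s at 2.0 m/s (plausible human range).
stride_time <- function(speed) {
  expo <- log(1.6) / log(4)
  1.6 * 0.5^expo * speed^(-expo)
}

## Fibonacci lattice on the upper hemisphere; head-centered frame, unit radius.
make_montage <- function(n_eeg, n_noise, pairing = NULL) {
  i <- seq_len(n_eeg)
  z <- (i - 0.5) / n_eeg                      # upper hemisphere only
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(1 - z^2)
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  if (is.null(pairing)) pairing <- round(seq(1, n_eeg, length.out = n_noise))
  mont <- data.frame(
    label = c(sprintf("EEG%03d", i), sprintf("NZ%03d", seq_len(n_noise))),
    rbind(pos, pos[pairing, , drop = FALSE]))
  attr(mont, "pairing") <- as.integer(pairing)
  mont
}

#' Generate gait events for a walking bout
#'
#' Stride period follows a log-linear speed model (1.6 s at 0.5 m/s to 1.0 s
#' at 2.0 m/s) with Gaussian stride-to-stride jitter; within-stride events are
#' placed at fixed phase fractions of each stride.
#'
#' @param speed walking speed, m/s.
#' @param duration bout length, s; must cover at least two stride periods.
#' @param fs sampling rate, Hz.
#' @param seed optional RNG seed.
#' @param cv stride-time coefficient of variation (default 0.03).
#' @param phasing named fractions of the stride for lto, lhs, rto.
#' @return a [gait_event_table()].
#' @export
make_gait_events <- function(speed, duration, fs, seed = NULL, cv = 0.03,
                             phasing = c(lto = 0.12, lhs = 0.50, rto = 0.62)) {
  stopifnot(speed > 0)
  if (!is.null(seed)) set.seed(seed)
  T0 <- stride_time(speed)
  if (duration < 2 * T0)
    stop("duration too short: need at least two stride periods (",
         signif(2 * T0, 3), " s)")
  t <- 0.3
  rhs_t <- numeric(0)
  repeat {
    rhs_t <- c(rhs_t, t)
    t <- t + T0 * max(0.2, 1 + cv * rnorm(1))
    if (t > duration - 0.02) break
  }
  k <- length(rhs_t) - 1
  lto_t <- lhs_t <- rto_t <- numeric(0)
  if (k >= 1) {
    dur_i <- diff(rhs_t)
    lto_t <- rhs_t[seq_len(k)] + phasing[["lto"]] * dur_i
    lhs_t <- rhs_t[seq_len(k)] + phasing[["lhs"]] * dur_i
    rto_t <- rhs_t[seq_len(k)] + phasing[["rto"]] * dur_i
  }
  to_idx <- function(x) pmax(1, round(x * fs) + 1)
  gait_event_table(rhs = to_idx(rhs_t), lhs = to_idx(lhs_t),
                   rto = to_idx(rto_t), lto = to_idx(lto_t),
                   fs = fs, n_samples = ceiling(duration * fs))
}

## Continuous gait phase in [0,1): 0 at each right heel strike, linear in
## between; constant rate extrapolation outside the covered span.
gait_phase <- function(events, n_samples, fs) {
  if (is.null(events) || length(events$rhs) < 2) return(rep(0, n_samples))
  rhs <- events$rhs
  t <- seq_len(n_samples)
  cyc <- approx(rhs, seq_along(rhs) - 1, xout = t, rule = 2)$y
  mean_stride <- mean(diff(rhs))
  before <- t < rhs[1]
  cyc[before] <- (t[before] - rhs[1]) / mean_stride
  after <- t > rhs[length(rhs)]
  cyc[after] <- (length(rhs) - 1) + (t[after] - rhs[length(rhs)]) / mean_stride
  cyc - floor(cyc)
}

## Envelope 1 + depth*cos(2*pi*(phase - peak)); >=0 when depth <= 1.
phase_envelope <- function(phase, peak, depth) {
  1 + depth * cos(2 * pi * (phase - peak))
}

#' Generate lateralized sensorimotor brain sources
#'
#' Two sources over left/right motor-cortex-like positions: pink-noise
#' background plus alpha and beta oscillations whose amplitude envelopes are
#' locked to the gait cycle. The left source peaks around left heel strike
#' (right-limb stance) and bottoms during right-limb swing; the right source
#' is mirrored. A per-speed gain scales the oscillation amplitudes.
#'
#' @param events gait events (NULL for a standing, unmodulated condition).
#' @param fs sampling rate, Hz.
#' @param n_samples length in samples.
#' @param montage montage data frame (scalp rows first).
#' @param cfg `synth_config`.
#' @param speed walking speed used for the per-speed gain (ignored if NULL).
#' @param seed optional RNG seed.
#' @return list with `signals` (2 x n), `topographies` (n_eeg x 2),
#'   `envelopes` (2 x n), `scalp` (topographies %*% signals).
#' @export
make_brain_sources <- function(events, fs, n_samples, montage, cfg,
                               speed = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- cfg$brain
  gain <- if (is.null(speed)) 1 else speed_gain_at(b$speed_gain, speed)
  phase <- gait_phase(events, n_samples, fs)
  tt <- (seq_len(n_samples) - 1) / fs
  peaks <- c(left = 0.5, right = 0.0)   # phase of envelope maximum
  signals <- matrix(0, 2, n_samples)
  envs <- matrix(0, 2, n_samples)
  depth <- if (is.null(events)) 0 else b$mod_depth
  for (s in 1:2) {
    env <- phase_envelope(phase, peaks[s], depth)
    osc <- gain * env *
      (b$alpha_amp * sin(2 * pi * b$alpha_freq * tt + runif(1, 0, 2 * pi)) +
       b$beta_amp  * sin(2 * pi * b$beta_freq  * tt + runif(1, 0, 2 * pi)))
    signals[s, ] <- b$pink_rms * pink_noise(n_samples) + osc
    envs[s, ] <- env
  }
  n_eeg <- sum(grepl("^EEG", montage$label))
  pos <- as.matrix(montage[seq_len(n_eeg), c("x", "y", "z")])
  centers <- rbind(left = c(-0.55, 0.05, 0.83), right = c(0.55, 0.05, 0.83))
  centers <- centers / sqrt(rowSums(centers^2))
  topo <- sapply(1:2, function(s) {
    ang <- acos(pmin(1, pmax(-1, pos %*% centers[s, ])))
    exp(-ang^2 / (2 * 0.6^2))
  })
  ## distributed 1/f background: many cortical patches seen through volume
  ## conduction (smooth topographies), plus a small electrode-local residue
  k_bg <- max(6L, ceiling(n_eeg / 2))
  bg_centers <- matrix(rnorm(3 * k_bg), k_bg, 3)
  bg_centers[, 3] <- abs(bg_centers[, 3])
  bg_centers <- bg_centers / sqrt(rowSums(bg_centers^2))
  bg_topo <- sapply(seq_len(k_bg), function(j) {
    ang <- acos(pmin(1, pmax(-1, pos %*% bg_centers[j, ])))
    exp(-ang^2 / (2 * 0.45^2))
  })
  ## heterogeneous source spectra: varying 1/f exponents and idiosyncratic
  ## rhythmic peaks (individual alpha/mu/theta), none gait-modulated
  bg_src <- t(sapply(seq_len(k_bg), function(j) {
    v <- pink_noise(n_samples, alpha = runif(1, 0.8, 1.4))
    ## each patch carries a clear rhythm (theta/alpha/beta range), as human
    ## cortical sources do, and waxes/wanes on a seconds scale (making the
    ## source super-Gaussian, as cortical activity is)
    fpk <- runif(1, 6, 25)
    v <- v + runif(1, 0.5, 1.3) * sin(2 * pi * fpk * seq_len(n_samples) / fs +
                                      runif(1, 0, 2 * pi))
    env_n <- max(4L, ceiling(n_samples / fs / 2))
    env <- approx(seq(1, n_samples, length.out = env_n),
                  pmax(0.15, 1 + 0.7 * rnorm(env_n)),
                  xout = seq_len(n_samples))$y
    v * env
  }))
  bg <- bg_topo %*% bg_src
  bg <- bg / sqrt(mean(bg^2)) * b$bg_rms
  list(signals = signals, topographies = topo, envelopes = envs,
       scalp = topo %*% signals + bg)
}

#' Generate stride-locked motion artifacts for both layers
#'
#' A small set of spatially smooth latent burst trains, time-locked to heel
#' strikes (damped 2-12 Hz oscillations with broadband onsets), is sampled at
#' every electrode position. Each scalp channel's artifact equals the latent
#' field at its position times a per-channel coupling gain plus a small
#' decorrelation noise; a noise-layer channel records the same field at its
#' (paired) position with unit gain -- mechanically coupled, electrically
#' independent layers.
#'
#' @inheritParams make_brain_sources
#' @param pairing noise-to-scalp pairing map.
#' @return list with `scalp` (n_eeg x n) and `noise_layer` (n_noise x n).
#' @export
make_motion_artifact <- function(events, fs, n_samples, montage, pairing, cfg,
                                 speed = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cfg$motion
  n_eeg <- sum(grepl("^EEG", montage$label))
  n_noise <- length(pairing)
  if (is.null(events) || length(events$rhs) < 1) {
    return(list(scalp = matrix(0, n_eeg, n_samples),
                noise_layer = matrix(0, n_noise, n_samples)))
  }
  gain <- if (is.null(speed)) 1 else speed_gain_at(m$speed_gain, speed)
  strikes <- sort(c(events$rhs, events$lhs))
  ## enough latent burst fields that individual electrodes see distinct
  ## artifact mixtures (electrode-level rattling, not one rigid cap mode)
  K <- max(3L, ceiling(length(pairing) * 0.8))
  latents <- matrix(0, K, n_samples)
  ## bursts confined to roughly the double-support interval after each strike
  tau <- 0.07 * fs
  for (k in seq_len(K)) {
    for (s0 in strikes) {
      f <- runif(1, 2, 12)
      a <- m$burst_amp * gain * runif(1, 0.5, 1.5)
      idx <- s0:min(n_samples, s0 + round(0.3 * fs))
      u <- idx - s0
      latents[k, idx] <- latents[k, idx] +
        a * exp(-u / tau) * sin(2 * pi * f * u / fs + runif(1, 0, 2 * pi))
    }
  }
  pos <- as.matrix(montage[seq_len(n_eeg), c("x", "y", "z")])
  centers <- matrix(rnorm(3 * K), K, 3)
  centers[, 3] <- abs(centers[, 3])
  centers <- centers / sqrt(rowSums(centers^2))
  loadings <- sapply(seq_len(K), function(k) {
    ang <- acos(pmin(1, pmax(-1, pos %*% centers[k, ])))
    exp(-ang^2 / (2 * 0.5^2))
  })                                           # n_eeg x K
  field <- loadings %*% latents                # latent field at scalp positions
  noise_layer <- field[pairing, , drop = FALSE]
  ch_gain <- runif(n_eeg, m$gain_range[1], m$gain_range[2])
  scalp <- field * ch_gain
  if (m$decorr > 0) {
    rms <- sqrt(rowMeans(scalp^2))
    scalp <- scalp + matrix(rnorm(n_eeg * n_samples), n_eeg) * (m$decorr * rms)
  }
  list(scalp = scalp, noise_layer = noise_layer)
}

#' Generate neck-EMG artifacts and their scalp leakage
#'
#' Four muscle sources (left/right sternocleidomastoid and trapezius):
#' band-limited broadband noise with gait-phase-locked envelopes peaking in
#' double support with the contralateral limb leading. Sources project fully
#' onto the 8 EMG channels (two per muscle) and leak onto scalp channels with
#' spatially decaying gain from the neck.
#'
#' @inheritParams make_brain_sources
#' @param n_emg number of EMG channels.
#' @return list with `emg` (n_emg x n), `scalp_leak` (n_eeg x n),
#'   `envelopes` (4 x n).
#' @export
make_emg_artifact <- function(events, fs, n_samples, montage, cfg,
                              n_emg = 8, speed = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- cfg$emg
  gain <- if (is.null(speed)) 1 else speed_gain_at(e$speed_gain, speed)
  phase <- gait_phase(events, n_samples, fs)
  depth <- if (is.null(events)) 0 else e$mod_depth
  band <- c(e$band[1], min(e$band[2], 0.92 * fs / 2))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  ## peak phases: left muscles at right-lead double support (just after rhs),
  ## right muscles at left-lead double support (just after lhs)
  peaks <- c(L_scm = 0.06, R_scm = 0.56, L_trap = 0.06, R_trap = 0.56)
  sources <- matrix(0, 4, n_samples)
  envs <- matrix(0, 4, n_samples)
  for (s in 1:4) {
    raw <- signal::filtfilt(bf, rnorm(n_samples))
    raw <- raw / sd(raw)
    env <- phase_envelope(phase, peaks[s], depth)
    sources[s, ] <- e$rms * gain * env * raw
    envs[s, ] <- env
  }
  mix <- matrix(0, n_emg, 4)
  for (ch in seq_len(n_emg)) {
    mus <- ((ch - 1) %% 4) + 1
    mix[ch, mus] <- runif(1, 0.8, 1.2)
  }
  emg <- mix %*% sources
  n_eeg <- sum(grepl("^EEG", montage$label))
  pos <- as.matrix(montage[seq_len(n_eeg), c("x", "y", "z")])
  muscle_pos <- rbind(c(-0.5, 0.35, -0.3), c(0.5, 0.35, -0.3),
                      c(-0.45, -0.5, -0.2), c(0.45, -0.5, -0.2))
  muscle_pos <- muscle_pos / sqrt(rowSums(muscle_pos^2))
  leak_w <- sapply(1:4, function(s) {
    d <- sqrt(rowSums((pos - matrix(muscle_pos[s, ], n_eeg, 3,
                                    byrow = TRUE))^2))
    e$leak_gain * exp(-(d - min(d))^2 / (2 * 0.5^2))
  })
  list(emg = emg, scalp_leak = leak_w %*% sources, envelopes = envs)
}

#' Generate one synthetic dual-layer recording with ground truth
#'
#' Emits a recording whose scalp EEG is the exact sample-wise sum of the
#' returned ground-truth parts (brain + motion + EMG leakage + line noise +
#' sensor noise). A standing baseline (no gait events, no motion artifact,
#' unmodulated sources) is produced with `baseline = TRUE`.
#'
#' @param speed walking speed, m/s (ignored when `baseline = TRUE`).
#' @param duration length in seconds.
#' @param seed RNG seed (determinism: same seed and config give an identical
#'   recording).
#' @param cfg a [synth_config()].
#' @param baseline logical; standing condition.
#' @return list with `recording` (a `dual_layer_recording`), `ground_truth`
#'   (brain, motion, emg_leak, line, sensor matrices; events; brain_envelopes;
#'   emg_envelopes; params), and `grf` (left/right vertical ground reaction
#'   force traces).
#' @export
generate_recording <- function(speed = 1.0, duration = 180, seed = 1,
                               cfg = synth_config(), baseline = FALSE) {
  set.seed(seed)
  fs <- cfg$fs
  n_samples <- round(duration * fs)
  mont <- make_montage(cfg$n_eeg, cfg$n_noise)
  pairing <- attr(mont, "pairing")
  events <- if (baseline) NULL else
    make_gait_events(speed, duration, fs, cv = cfg$stride$cv,
                     phasing = cfg$stride$phasing)
  br <- make_brain_sources(events, fs, n_samples, mont, cfg, speed = speed)
  mo <- make_motion_artifact(events, fs, n_samples, mont, pairing, cfg,
                             speed = speed)
  em <- make_emg_artifact(events, fs, n_samples, mont, cfg,
                          n_emg = cfg$n_emg, speed = speed)
  ## line noise: common sinusoid, per-channel gain
  tt <- (seq_len(n_samples) - 1) / fs
  line_wave <- sin(2 * pi * cfg$line$freq * tt + runif(1, 0, 2 * pi))
  lg <- function(n) cfg$line$amp * runif(n, 0.5, 1.5)
  line_eeg <- outer(lg(cfg$n_eeg), line_wave)
  line_noise_blk <- outer(lg(cfg$n_noise), line_wave)
  line_emg <- outer(lg(cfg$n_emg), line_wave)
  sn <- function(n) matrix(rnorm(n * n_samples, sd = cfg$sensor_rms), n)
  sensor_eeg <- sn(cfg$n_eeg)
  eeg <- br$scalp + mo$scalp + em$scalp_leak + line_eeg + sensor_eeg
  noise_blk <- mo$noise_layer + line_noise_blk + sn(cfg$n_noise)
  emg_blk <- em$emg + line_emg + sn(cfg$n_emg)
  rec <- dual_layer_recording(eeg, noise_blk, emg_blk, fs, montage = mont,
                              pairing = pairing)
  grf <- if (baseline) NULL else make_grf(events, fs, n_samples)
  list(recording = rec,
       ground_truth = list(brain = br$scalp, motion = mo$scalp,
                           emg_leak = em$scalp_leak, line = line_eeg,
                           sensor = sensor_eeg, events = events,
                           brain_envelopes = br$envelopes,
                           brain_topographies = br$topographies,
                           emg_envelopes = em$envelopes,
                           params = list(speed = speed, duration = duration,
                                         seed = seed, cfg = cfg,
                                         baseline = baseline)),
       grf = grf)
}

#' Synthesize vertical ground-reaction-force traces from gait events
#'
#' Stylized double-bump vertical GRF per stance phase with a sharp onset (the
#' force exceeds typical detection thresholds at the programmed event sample),
#' so threshold-based gait-event detection can be tested end to end.
#'
#' @param events a `gait_event_table`.
#' @param fs sampling rate, Hz.
#' @param n_samples trace length.
#' @param body_weight_N peak-scale force in newtons.
#' @return list with `left` and `right` force traces (N).
#' @export
make_grf <- function(events, fs, n_samples, body_weight_N = 700) {
  trace <- function(hs, to_all) {
    f <- numeric(n_samples)
    for (h in hs) {
      to_after <- to_all[to_all > h]
      if (!length(to_after)) next
      to <- to_after[1]
      if (to > n_samples) to <- n_samples + 1
      idx <- h:(to - 1)
      u <- (idx - h) / max(1, (to - 1 - h))
      f[idx] <- 40 + body_weight_N * sin(pi * u)^2 * (1 + 0.2 * cos(2 * pi * u))
    }
    f
  }
  list(left = trace(events$lhs, events$lto),
       right = trace(events$rhs, events$rto))
}

#' Generate the multi-speed synthetic dataset
#'
#' One walking recording per speed plus a standing baseline, all from a single
#' seed (bit-reproducible for a fixed seed and configuration).
#'
#' @param speeds walking speeds, m/s.
#' @param duration seconds per condition.
#' @param seed RNG seed.
#' @param cfg a [synth_config()].
#' @return named list: one element per speed (names like "1.0") plus
#'   "baseline", each as returned by [generate_recording()].
#' @export
generate_dataset <- function(speeds = c(0.5, 1.0, 1.5, 2.0), duration = 180,
                             seed = 1, cfg = synth_config()) {
  out <- list()
  for (i in seq_along(speeds)) {
    out[[format(speeds[i], nsmall = 1)]] <-
      generate_recording(speeds[i], duration, seed = seed + i, cfg = cfg)
  }
  out[["baseline"]] <- generate_recording(duration = duration,
                                          seed = seed + length(speeds) + 1,
                                          cfg = cfg, baseline = TRUE)
  out
}
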