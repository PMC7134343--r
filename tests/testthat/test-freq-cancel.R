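test_that("stft geometry matches the 0.5 s / 94% specification", {
  fs <- 256
  x <- rnorm(4 * fs)
  W <- stft(x, fs, 0.5, 0.94)
  expect_equal(W$nwin, 128)
  expect_equal(W$hop, 8)         # round(128 * 0.06)
  expect_equal(diff(W$window_starts[1:2]), 8)

  ## pure sinusoid: per-window magnitude peak at its frequency bin
  t <- (0:(4 * fs - 1)) / fs
  Ws <- stft(sin(2 * pi * 10 * t), fs, 0.5, 0.94)
  pb <- 2:65
  freqs <- (pb - 1) * fs / 128
  mid <- floor(nrow(Ws$coeffs) / 2) + (-5:5)
  peaks <- freqs[apply(Mod(Ws$coeffs[mid, pb]), 1, which.max)]
  expect_true(all(peaks == 10))

  expect_equal(max(Mod(stft(numeric(512), fs)$coeffs)), 0)
  expect_error(stft(rnorm(64), fs, 0.5), "shorter")
})

test_that("istft inverts stft exactly and removes zeroed tones cleanly", {
  fs <- 256
  set.seed(14)
  x <- rnorm(8 * fs)
  W <- stft(x, fs, 0.5, 0.94)
  xr <- istft(W)
  expect_lt(sqrt(sum((xr - x)^2) / sum(x^2)), 1e-10)

  ## zero the 32 Hz tone's bins (its Hann mainlobe spans the centre bin and
  ## one neighbour either side) in every window of a two-tone signal: the
  ## output matches the remaining tone built directly in the time domain
  t <- (0:(8 * fs - 1)) / fs
  tone_keep <- sin(2 * pi * 10 * t)
  tone_cut <- 0.8 * sin(2 * pi * 32 * t)
  W2 <- stft(tone_keep + tone_cut, fs, 0.5, 0.94)
  ctr <- which.min(abs((0:127) * fs / 128 - 32))
  bins <- (ctr - 1):(ctr + 1)
  mirrors <- 128 - (bins - 1) + 1
  W2$coeffs[, bins] <- 0
  W2$coeffs[, mirrors] <- 0
  y <- istft(W2)
  ## interior comparison: the abrupt signal edges splatter across bins in the
  ## first/last windows
  keep <- 129:(8 * fs - 128)
  expect_lt(sqrt(mean((y[keep] - tone_keep[keep])^2)) /
              sqrt(mean(tone_keep[keep]^2)), 0.02)
})

test_that("cancellation is an identity under zero noise", {
  fs <- 256
  set.seed(15)
  x <- rnorm(6 * fs)
  out <- cancel_channel(x, numeric(length(x)), fs)
  expect_lt(max(abs(out$signal - x)), 1e-9)
  expect_equal(sum(out$n_flagged), 0)
})

test_that("cancellation is scale-equivariant", {
  fs <- 256
  set.seed(16)
  n <- 6 * fs
  noise <- duallayer:::pink_noise(n) * 10
  x <- rnorm(n) + noise
  c1 <- cancel_channel(x, noise, fs)$signal
  c3 <- cancel_channel(3 * x, 3 * noise, fs)$signal
  expect_lt(max(abs(c3 - 3 * c1)) / max(abs(c1)), 1e-8)
})

test_that("cancellation attenuates a shared artifact and spares a probe tone", {
  fs <- 256
  set.seed(17)
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  brain <- 2 * duallayer:::pink_noise(n) + 1.5 * sin(2 * pi * 10 * t)
  artifact <- 12 * sin(2 * pi * 5 * t) * (1 + 0.3 * sin(2 * pi * 0.7 * t))
  ## the noise layer records the artifact over its own sensor-noise floor
  noise_ch <- artifact + 1.0 * rnorm(n)
  eeg <- brain + artifact
  out <- cancel_channel(eeg, noise_ch, fs)$signal
  bp <- function(x, lo, hi) duallayer:::band_power(x, fs, lo, hi)
  atten <- 10 * log10(bp(eeg - brain, 4.5, 5.5) /
                        max(bp(out - brain, 4.5, 5.5), 1e-12))
  expect_gt(atten, 10)
  probe_change <- abs(10 * log10(bp(out, 9.5, 10.5) / bp(brain, 9.5, 10.5)))
  expect_lt(probe_change, 1)
})

test_that("raising the transient cutoff never increases flagged bins", {
  fs <- 256
  set.seed(18)
  n <- 8 * fs
  noise <- duallayer:::pink_noise(n) * 5
  x <- rnorm(n)
  counts <- vapply(c(3, 6, 9, 15), function(u)
    sum(cancel_channel(x, noise, fs,
                       cancellation_config(upper_mult = u))$n_flagged), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("amplitude matching rescales noise to the EEG median magnitude", {
  fs <- 256
  set.seed(19)
  n <- 4 * fs
  x <- rnorm(n)
  ## noise already at the EEG's median magnitude: output == input
  out_same <- amplitude_matched_noise(x, x, fs)
  expect_lt(max(abs(out_same - x)), 1e-9)

  ## scaling the noise input leaves the matched output unchanged
  nz <- duallayer:::pink_noise(n)
  m1 <- amplitude_matched_noise(x, nz, fs)
  m2 <- amplitude_matched_noise(x, 2 * nz, fs)
  expect_lt(max(abs(m1 - m2)) / max(abs(m1)), 1e-9)

  expect_equal(max(abs(amplitude_matched_noise(x, numeric(n), fs))), 0)
})

test_that("recording-level cancellation improves ground-truth recovery", {
  g <- tiny_walk(seed = 23, duration = 20)
  rec <- highpass(g$recording, 1)
  brain <- highpass(g$ground_truth$brain, 1, fs = rec$fs)
  vn <- interpolate_noise_layer(rec)
  out <- cancel_recording(rec, vn)
  rmse <- function(M) sqrt(rowMeans((M - brain)^2))
  frac_improved <- mean(rmse(out$recording$eeg) < rmse(rec$eeg))
  expect_gte(frac_improved, 0.9)
  expect_equal(out$recording$noise, rec$noise)

  ## artifact-free recording passes through nearly unchanged
  cfg0 <- small_cfg(motion = list(burst_amp = 0), emg = list(leak_gain = 0),
                    line = list(amp = 0))
  g0 <- generate_recording(1.0, 20, seed = 24, cfg = cfg0)
  rec0 <- highpass(g0$recording, 1)
  vn0 <- interpolate_noise_layer(rec0)
  out0 <- cancel_recording(rec0, vn0)
  bp <- function(v) duallayer:::band_power(v, rec0$fs, 1, 100)
  db_change <- abs(10 * log10(vapply(1:nrow(rec0$eeg), function(i)
    bp(out0$recording$eeg[i, ]) / bp(rec0$eeg[i, ]), 0)))
  expect_lt(max(db_change), 0.5)

  ## standing baseline flags fewer bins than fast walking
  gb <- generate_recording(duration = 20, seed = 25, cfg = small_cfg(),
                           baseline = TRUE)
  gf <- generate_recording(2.0, 20, seed = 25, cfg = small_cfg())
  fb <- cancel_recording(highpass(gb$recording, 1),
                         interpolate_noise_layer(highpass(gb$recording, 1)))
  ff <- cancel_recording(highpass(gf$recording, 1),
                         interpolate_noise_layer(highpass(gf$recording, 1)))
  expect_lt(sum(fb$flag_counts), sum(ff$flag_counts))
})
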