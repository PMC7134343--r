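test_that("stride counts follow the speed model", {
  ## ~48 strides in 60 s at 1.0 m/s (stride period ~1.26 s)
  ev <- make_gait_events(1.0, 60, 256, seed = 1)
  expect_gt(length(ev$rhs), 44)
  expect_lt(length(ev$rhs), 51)

  ## zero jitter -> identical stride durations
  ev0 <- make_gait_events(1.0, 30, 256, seed = 1, cv = 0)
  expect_lt(diff(range(diff(ev0$rhs))), 1.5)  # rounding only

  ## faster walking -> strictly more strides over the same duration
  nf <- length(make_gait_events(2.0, 40, 256, seed = 2)$rhs)
  ns <- length(make_gait_events(0.5, 40, 256, seed = 2)$rhs)
  expect_gt(nf, ns)

  expect_error(make_gait_events(0.5, 2, 256), "too short")
})

test_that("emitted EEG equals the sum of ground-truth parts", {
  g <- tiny_walk(seed = 7, duration = 10)
  gt <- g$ground_truth
  resid <- g$recording$eeg - gt$brain - gt$motion - gt$emg_leak -
    gt$line - gt$sensor
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("generation is deterministic in the seed", {
  a <- tiny_walk(seed = 11, duration = 5)
  b <- tiny_walk(seed = 11, duration = 5)
  expect_identical(a$recording$eeg, b$recording$eeg)
  expect_identical(a$ground_truth$motion, b$ground_truth$motion)
  c <- tiny_walk(seed = 12, duration = 5)
  expect_false(identical(a$recording$eeg, c$recording$eeg))
})

test_that("baseline condition has no gait events and zero motion", {
  g <- generate_recording(duration = 10, seed = 2, cfg = small_cfg(),
                          baseline = TRUE)
  expect_null(g$ground_truth$events)
  expect_equal(max(abs(g$ground_truth$motion)), 0)
  ## unmodulated sources: envelopes constant
  expect_lt(diff(range(g$ground_truth$brain_envelopes)), 1e-12)
})

test_that("dataset generation yields walking conditions plus baseline", {
  ds <- generate_dataset(speeds = c(0.5, 2.0), duration = 6, seed = 9,
                         cfg = small_cfg())
  expect_named(ds, c("0.5", "2.0", "baseline"))
  ds2 <- generate_dataset(speeds = c(0.5, 2.0), duration = 6, seed = 9,
                          cfg = small_cfg())
  expect_identical(ds$`0.5`$recording$eeg, ds2$`0.5`$recording$eeg)
})

test_that("brain source envelopes are gait-phase locked as programmed", {
  fs <- 256; dur <- 20
  ev <- make_gait_events(1.0, dur, fs, seed = 3)
  mont <- duallayer:::make_montage(16, 6)
  br <- make_brain_sources(ev, fs, dur * fs, mont, small_cfg(), speed = 1.0)
  phase <- duallayer:::gait_phase(ev, dur * fs, fs)
  ## left source (row 1) peaks at left heel strike (phase 0.5), dips in
  ## right-limb swing (phase ~0.8)
  at_lhs <- abs(phase - 0.5) < 0.05
  mid_rswing <- abs(phase - 0.81) < 0.05
  expect_gt(mean(br$envelopes[1, at_lhs]), mean(br$envelopes[1, mid_rswing]))
  ## right source mirrored: peak near phase 0
  near_rhs <- phase < 0.05 | phase > 0.95
  expect_gt(mean(br$envelopes[2, near_rhs]), mean(br$envelopes[2, at_lhs]))

  ## zero modulation depth -> flat envelope
  cfg0 <- small_cfg(brain = list(mod_depth = 0))
  br0 <- make_brain_sources(ev, fs, dur * fs, mont, cfg0, speed = 1.0)
  expect_lt(diff(range(br0$envelopes)), 1e-12)
})

test_that("per-speed brain gain scales source band power as gain^2", {
  fs <- 256; dur <- 30
  cfg <- small_cfg(brain = list(speed_gain = list(x = c(0.5, 2.0),
                                                  y = c(1.0, 0.6)),
                                mod_depth = 0, pink_rms = 0, bg_rms = 1e-9,
                                beta_amp = 0))
  mont <- duallayer:::make_montage(16, 6)
  pow <- sapply(c(0.5, 2.0), function(sp) {
    ev <- make_gait_events(sp, dur, fs, seed = 4)
    set.seed(21)
    br <- make_brain_sources(ev, fs, dur * fs, mont, cfg, speed = sp)
    p <- welch_psd(br$signals[1, ], fs)
    sum(p$power[p$freq >= 8 & p$freq <= 13])
  })
  expect_equal(pow[2] / pow[1], 0.36, tolerance = 0.05)
})

test_that("motion artifact couples the two layers as programmed", {
  fs <- 256; dur <- 20
  ev <- make_gait_events(1.0, dur, fs, seed = 5)
  mont <- duallayer:::make_montage(16, 6)
  pairing <- attr(mont, "pairing")

  ## perfect coupling: no decorrelation, unit gain range
  cfg1 <- small_cfg(motion = list(decorr = 0, gain_range = c(1, 1)))
  set.seed(31)
  mo <- make_motion_artifact(ev, fs, dur * fs, mont, pairing, cfg1,
                             speed = 1.0)
  expect_lt(max(abs(mo$scalp[pairing[2], ] - mo$noise_layer[2, ])), 1e-9)

  ## default coupling: paired channels correlate strongly
  set.seed(32)
  mo2 <- make_motion_artifact(ev, fs, dur * fs, mont, pairing, small_cfg(),
                              speed = 1.0)
  r <- vapply(seq_along(pairing), function(j)
    cor(mo2$scalp[pairing[j], ], mo2$noise_layer[j, ]), 0)
  expect_gt(min(r), 0.9)

  ## doubling the amplitude doubles the RMS
  cfgA <- small_cfg(motion = list(burst_amp = 20))
  cfgB <- small_cfg(motion = list(burst_amp = 40))
  set.seed(33); moA <- make_motion_artifact(ev, fs, dur * fs, mont, pairing,
                                            cfgA, speed = 1.0)
  set.seed(33); moB <- make_motion_artifact(ev, fs, dur * fs, mont, pairing,
                                            cfgB, speed = 1.0)
  expect_equal(sqrt(mean(moB$noise_layer^2)) / sqrt(mean(moA$noise_layer^2)),
               2, tolerance = 1e-6)
})

test_that("EMG artifacts are band-limited with double-support envelopes", {
  fs <- 256; dur <- 20
  ev <- make_gait_events(1.0, dur, fs, seed = 6)
  mont <- duallayer:::make_montage(16, 6)
  set.seed(41)
  em <- make_emg_artifact(ev, fs, dur * fs, mont, small_cfg(), n_emg = 2,
                          speed = 1.0)
  ## >80% of EMG channel power above 20 Hz
  p <- welch_psd(em$emg[1, ], fs)
  frac_hi <- sum(p$power[p$freq > 20]) / sum(p$power)
  expect_gt(frac_hi, 0.8)

  ## left-muscle envelope peaks in right-lead double support (phase ~0.06)
  phase <- duallayer:::gait_phase(ev, dur * fs, fs)
  in_rds <- phase > 0.0 & phase < 0.12
  in_swing <- phase > 0.3 & phase < 0.45
  expect_gt(mean(em$envelopes[1, in_rds]), mean(em$envelopes[1, in_swing]))

  ## zero leakage gain -> zero scalp contribution
  cfg0 <- small_cfg(emg = list(leak_gain = 0))
  set.seed(42)
  em0 <- make_emg_artifact(ev, fs, dur * fs, mont, cfg0, n_emg = 2,
                           speed = 1.0)
  expect_equal(max(abs(em0$scalp_leak)), 0)
})
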