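test_that("GRF threshold crossing recovers programmed gait events", {
  fs <- 256
  g <- tiny_walk(seed = 70, duration = 20)
  ev <- g$ground_truth$events
  det <- detect_gait_events(g$grf$left, g$grf$right, fs)
  k <- length(det$rhs)
  expect_true(all(abs(det$rhs - ev$rhs[seq_len(k)]) <= 1))
  kl <- length(det$lhs)
  expect_true(all(abs(det$lhs - ev$lhs[seq_len(kl)]) <= 1))

  expect_error(detect_gait_events(numeric(1000), numeric(1000), fs),
               "no gait events")
  expect_error(detect_gait_events(g$grf$left, g$grf$right, fs,
                                  thresh_N = 1e6), "no gait events")
})

test_that("stride epoching delimits by right heel strike", {
  ## 10 valid strides -> 9 epochs (fencepost)
  ev <- make_gait_events(1.0, 14, 256, seed = 71, cv = 0)
  x <- rnorm(14 * 256)
  ep <- epoch_strides(x, ev)
  expect_equal(length(ep$epochs), sum(ev$strides$valid))
  ## epochs reproduce the original samples over their spans
  for (i in c(1, length(ep$epochs))) {
    a <- ep$starts[i]
    expect_identical(ep$epochs[[i]], x[a:(a + length(ep$epochs[[i]]) - 1)])
  }
  ## invalid strides are excluded
  ev2 <- ev
  ev2$strides$valid[2] <- FALSE
  ep2 <- epoch_strides(x, ev2)
  expect_equal(length(ep2$epochs), length(ep$epochs) - 1)

  expect_error(epoch_strides(x, gait_event_table(rhs = c(10, 300), lhs = 150,
                                                 rto = 200, lto = 50,
                                                 fs = 256)), "3 valid")
})

test_that("Morlet transform localizes tones and tracks amplitude steps", {
  fs <- 256
  t <- (0:(2 * fs - 1)) / fs
  tfr <- single_trial_tfr(sin(2 * pi * 10 * t), freqs = c(10, 40), fs = fs)
  mid <- 100:(2 * fs - 100)
  expect_gt(mean(tfr[1, mid]) - mean(tfr[2, mid]), 20)

  xstep <- c(sin(2 * pi * 10 * t[1:fs]), 2 * sin(2 * pi * 10 * t[(fs + 1):(2 * fs)]))
  tfr2 <- single_trial_tfr(xstep, freqs = 10, fs = fs)
  step_db <- mean(tfr2[1, 380:480]) - mean(tfr2[1, 30:130])
  expect_equal(step_db, 20 * log10(2), tolerance = 0.3)

  expect_error(single_trial_tfr(rnorm(10), freqs = c(3, 30), fs = fs),
               "shorter")
})

test_that("time warping is identity at target latencies and stretch-invariant", {
  fs <- 256
  set.seed(72)
  tfr <- matrix(rnorm(5 * 257), 5)
  lat <- list(lto = 30, lhs = 128, rto = 160, end = 256)
  w <- time_warp(tfr, lat, lat, n_grid = 257)
  expect_lt(max(abs(w - tfr)), 1e-9)

  ## uniform stretch of the underlying signal warps to the same output
  t0 <- seq(0, 1, length.out = 256)
  f <- function(u) sin(2 * pi * 3 * u) + 0.5 * cos(2 * pi * 5 * u)
  base <- matrix(f(t0), 1)
  stretched <- matrix(f(seq(0, 1, length.out = round(256 * 1.1))), 1)
  latb <- list(lto = 0.12 * 255, lhs = 0.5 * 255, rto = 0.62 * 255, end = 255)
  lats <- lapply(latb, function(v) v * 1.1)
  targets <- latb
  wb <- time_warp(base, latb, targets)
  ws <- time_warp(stretched, lats, targets)
  expect_gt(cor(wb[1, ], ws[1, ]), 0.999)

  expect_error(time_warp(base, list(lto = 100, lhs = 50, rto = 160,
                                    end = 255), targets), "increasing")
})

test_that("ERSP mask is calibrated on stationary input", {
  ## stationary log-power epochs: masked ERSP ~ 0, false-positive rate ~ alpha
  set.seed(73)
  hits <- 0; cells <- 0
  for (s in 1:30) {
    tfrs <- replicate(10, matrix(rnorm(6 * 40), 6), simplify = FALSE)
    er <- ersp(tfrs, n_boot = 200, alpha = 0.05, seed = s)
    hits <- hits + sum(er$mask)
    cells <- cells + length(er$mask)
  }
  rate <- hits / cells
  ci <- qbinom(c(0.025, 0.975), cells, 0.05) / cells
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("ERSP recovers programmed gait-locked modulation", {
  fs <- 256
  run_depth <- function(depth, seed = 74) {
    ## quiet in-band background so the programmed modulation dominates
    cfg <- small_cfg(brain = list(mod_depth = depth, alpha_amp = 3,
                                  bg_rms = 0.3, pink_rms = 0.3))
    g <- generate_recording(1.0, 30, seed = seed, cfg = cfg)
    topo <- g$ground_truth$brain_topographies
    chL <- which.max(topo[, 1])
    ep <- epoch_strides(g$ground_truth$brain[chL, ], g$ground_truth$events,
                        margin_sec = 0.3)
    freqs <- c(6, 8, 10, 12, 14, 20)
    er <- ersp(ep, freqs = freqs, n_boot = 200, seed = seed)
    alpha_t <- colMeans(er$power[freqs >= 8 & freqs <= 13, , drop = FALSE])
    ## programmed left-source envelope peaks at 50% of the cycle
    template <- cos(2 * pi * (er$pct / 100 - 0.5))
    list(r = cor(alpha_t, template), amp = diff(range(alpha_t)),
         masked = er$masked, alpha_t = alpha_t)
  }
  strong <- run_depth(0.6)
  expect_gt(strong$r, 0.7)
  ## sign and phase: positive around left heel strike, negative in swing
  none <- run_depth(0)
  expect_gt(strong$amp, 3 * none$amp)
})

test_that("speed comparison has calibrated size and detects programmed gains", {
  set.seed(75)
  ## type-I calibration under an exchangeable null
  hits <- 0; cells <- 0
  for (s in 1:25) {
    spectra <- lapply(1:4, function(i) matrix(rnorm(8 * 10), 8))
    sc <- speed_comparison(spectra, n_perm = 400, seed = s)
    hits <- hits + sum(sc$mask)
    cells <- cells + length(sc$mask)
  }
  rate <- hits / cells
  ci <- qbinom(c(0.025, 0.975), cells, 0.05) / cells
  expect_gte(rate, ci[1] * 0.8)
  expect_lte(rate, ci[2] * 1.4)

  ## programmed alpha-band power decreasing across four conditions
  set.seed(76)
  gains <- c(1.0, 0.9, 0.8, 0.7)
  freqs <- c(4, 8, 10, 12, 20, 40)
  spectra <- lapply(gains, function(g)
    t(replicate(10, {
      base <- rnorm(length(freqs), sd = 0.5)
      base[freqs >= 8 & freqs <= 13] <- base[freqs >= 8 & freqs <= 13] +
        20 * log10(g)
      base
    })))
  sc <- speed_comparison(spectra, freqs = freqs, n_perm = 600, seed = 9)
  alpha_idx <- which(freqs >= 8 & freqs <= 13)
  expect_true(all(sc$mask[alpha_idx]))
  ## condition means ordered with the programmed gain
  for (i in alpha_idx)
    expect_true(all(diff(sc$means[, i]) < 0))
})

test_that("channel-level analysis shows stride-locked noise-layer power", {
  g <- tiny_walk(seed = 77, duration = 25)
  res <- channel_level_analysis(g$recording, g$ground_truth$events,
                                role = "noise", channels = 1:3,
                                freqs = c(4, 6, 8, 12), n_boot = 100,
                                seed = 1)
  ## low-frequency power elevated just after heel strikes (double support:
  ## 0-12% and 50-62%) relative to swing
  lowf <- colMeans(res$power)
  ds <- res$pct < 14 | (res$pct > 50 & res$pct < 64)
  swing <- (res$pct > 25 & res$pct < 45) | res$pct > 75
  expect_gt(mean(lowf[ds]), mean(lowf[swing]))

  ## baseline condition: no strides -> clean error
  gb <- generate_recording(duration = 10, seed = 78, cfg = small_cfg(),
                           baseline = TRUE)
  expect_error(channel_level_analysis(gb$recording, gait_event_table(
    rhs = numeric(0), lhs = numeric(0), rto = numeric(0), lto = numeric(0),
    fs = 256), role = "noise"), "strides")
})
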