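test_that("full-rank PCA window reconstruction is lossless", {
  set.seed(30)
  fs <- 256
  X <- matrix(rnorm(12 * 1024), 12)
  out <- pca_window_clean(X, rnorm(1024), fs,
                          pca_clean_config(score_z = Inf,
                                           corr_enabled = FALSE))
  expect_lt(max(abs(out - X)), 1e-8)
})

test_that("PCA cleaning suppresses an injected spike", {
  set.seed(31)
  fs <- 256
  X <- matrix(rnorm(12 * 1024), 12)
  Xs <- X
  Xs[3, 500] <- Xs[3, 500] + 20
  out <- pca_window_clean(Xs, rnorm(1024), fs)
  spike_before <- Xs[3, 500] - X[3, 500]
  spike_after <- out[3, 500] - X[3, 500]
  expect_lt(abs(spike_after), 0.2 * abs(spike_before))
})

test_that("noise-correlated components are cleaned, others untouched", {
  set.seed(32)
  fs <- 256
  nwin <- 128
  ## construct one window whose first source IS the noise trace
  noise_tr <- 5 * sin(2 * pi * 6 * (1:nwin) / fs) +
    0.5 * rnorm(nwin)
  S <- rbind(noise_tr, matrix(rnorm(7 * nwin), 7))
  A <- diag(8); A[, 1] <- A[, 1] + 0.1
  X <- A %*% S
  cfg <- pca_clean_config(score_z = Inf, noise_corr_z = 1.5)
  out <- duallayer:::clean_pca_window(X, noise_tr, fs, cfg)
  ## the artifact direction is attenuated in the 6 Hz band
  bp <- function(M) mean(apply(M, 1, function(v)
    duallayer:::band_power(v, fs, 5, 7)))
  expect_lt(bp(out), bp(X))
})

test_that("lag-1 CCA matches an independent canonical-correlation oracle", {
  set.seed(33)
  fs <- 256
  for (nch in c(3, 5)) {
    X <- matrix(rnorm(nch * 1500), nch)
    X[1, ] <- sin(2 * pi * 2 * (1:1500) / fs) + 0.2 * rnorm(1500)
    cs <- cca_components(X)
    ## oracle: stats::cancor on the two lagged views
    v1 <- t(X[, -1500]); v2 <- t(X[, -1])
    oracle <- cancor(v1, v2)$cor
    expect_equal(cs$cancor, oracle, tolerance = 1e-8)
    ## canonical correlations non-increasing
    expect_true(all(diff(cs$cancor) <= 1e-12))
    ## reconstruction identity
    rec <- cs$mixing %*% cs$activations + cs$center
    expect_lt(max(abs(rec - X)), 1e-8)
  }
  ## first component of a tone + noise mixture: autocorrelation near the
  ## tone's analytic lag-1 value, last near zero
  X <- matrix(rnorm(2 * 4000), 2)
  X[1, ] <- X[1, ] * 0.05 + sin(2 * pi * 2 * (1:4000) / fs)
  cs <- cca_components(X)
  expect_equal(cs$autocorr[1], cos(2 * pi * 2 / fs), tolerance = 0.01)
  expect_lt(abs(cs$autocorr[2]), 0.1)
})

test_that("autocorrelation knee separates the shoulder from the tail", {
  ## worked example: knee after the first three values
  k <- autocorr_knee(c(0.99, 0.98, 0.97, 0.30, 0.10))
  expect_equal(k, 3)
  ## linear profile: ties resolve to the last index, nothing flagged
  expect_equal(autocorr_knee(seq(1, 0, length.out = 6)), 6)
  ## constant profile: nothing flagged
  expect_equal(autocorr_knee(rep(0.5, 5)), 5)
  ## fewer than 3 values: nothing flagged
  expect_equal(autocorr_knee(c(0.9, 0.1)), 2)
})

test_that("CCA cleaning is conservative on artifact-free pink channels", {
  fs <- 256
  fracs <- vapply(1:5, function(s) {
    set.seed(40 + s)
    X <- t(replicate(8, 3 * duallayer:::pink_noise(8 * fs)))
    out <- cca_window_clean(X, 0.3 * rnorm(8 * fs), fs)
    sum((out - X)^2) / sum(X^2)
  }, 0)
  expect_lt(median(fracs), 0.05)
})

test_that("CCA cleaning removes broadband muscle content, spares a probe", {
  ## native acquisition rate: the 30-100 Hz muscle band is then a minority of
  ## the spectrum, so the median-relative cutoffs can flag it
  fs <- 512
  set.seed(46)
  n <- 10 * fs
  t <- (0:(n - 1)) / fs
  probe <- 1.5 * sin(2 * pi * 10 * t)
  brain <- t(replicate(8, 3 * duallayer:::pink_noise(n)))
  brain[4, ] <- brain[4, ] + probe
  bf <- signal::butter(4, c(30, 100) / (fs / 2), "pass")
  emg_src <- signal::filtfilt(bf, rnorm(n)) * 6
  mix <- runif(8, 0.3, 1)
  X <- brain + outer(mix, emg_src)
  ## noise reference carrying the muscle band content
  noise_tr <- emg_src + 0.5 * rnorm(n)
  out <- cca_window_clean(X, noise_tr, fs)
  bp <- function(v, lo, hi) duallayer:::band_power(v, fs, lo, hi)
  emg_att <- 10 * log10(mean(apply(X - brain, 1, bp, 30, 100)) /
                          mean(apply(out - brain, 1, bp, 30, 100)))
  expect_gt(emg_att, 3)
  probe_change <- abs(10 * log10(bp(out[4, ], 9.5, 10.5) /
                                   bp(brain[4, ], 9.5, 10.5)))
  expect_lt(probe_change, 1)
})

test_that("ASR calibration thresholds behave as specified", {
  set.seed(50)
  fs <- 256
  base <- matrix(rnorm(12 * 20 * fs), 12)
  m7 <- asr_calibrate(base, fs = fs, k = 7)
  expect_true(all(is.finite(m7$thresholds) & m7$thresholds > 0))
  m3 <- asr_calibrate(base, fs = fs, k = 3)
  expect_true(all(m3$thresholds < m7$thresholds))
  expect_error(asr_calibrate(base[, 1:(4 * fs)], fs = fs), "10 windows")

  ## stationary Gaussian data almost never exceeds k = 7 thresholds
  set.seed(51)
  exceed <- 0; total <- 0
  for (i in 1:20) {
    fresh <- matrix(rnorm(12 * 2 * fs), 12)
    Z <- t(m7$basis) %*% (fresh - m7$center)
    for (w in 1:7) {
      idx <- ((w - 1) * 64 + 1):(w * 64)
      rms <- sqrt(rowMeans(Z[, idx]^2))
      exceed <- exceed + sum(rms > m7$thresholds)
      total <- total + length(rms)
    }
  }
  expect_lt(exceed / total, 1e-3)
})

test_that("ASR cleaning removes bursts and approaches identity as k grows", {
  set.seed(52)
  fs <- 256
  base <- matrix(rnorm(12 * 20 * fs), 12)
  model <- asr_calibrate(base, fs = fs, k = 7)

  ## self-consistency: cleaning baseline-like data changes almost nothing
  fresh <- matrix(rnorm(12 * 4 * fs), 12)
  cl <- asr_clean(fresh, model)
  expect_lt(mean(abs(cl - fresh) > 1e-6), 0.01)

  ## a large burst is strongly attenuated
  burst <- fresh
  burst[, 300:350] <- burst[, 300:350] + 200
  clb <- asr_clean(burst, model)
  rms_before <- sqrt(mean(burst[, 300:350]^2))
  rms_after <- sqrt(mean(clb[, 300:350]^2))
  expect_lt(rms_after, 0.1 * rms_before)

  ## unreachable thresholds: identity
  mInf <- model
  mInf$thresholds <- rep(Inf, length(mInf$thresholds))
  expect_lt(max(abs(asr_clean(burst, mInf) - burst)), 1e-9)

  expect_error(asr_clean(burst[1:5, ], model), "channel count")
})
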