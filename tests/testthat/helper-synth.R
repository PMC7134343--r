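# Reduced-geometry generator configurations used across the suite: small
# montages and short durations keep runtimes down while exercising every
# code path at the full 256 Hz analysis rate.

small_cfg <- function(...) {
  synth_config(n_eeg = 16, n_noise = 6, n_emg = 2, fs = 256, ...)
}

tiny_walk <- function(seed = 1, duration = 20, speed = 1.0, cfg = small_cfg()) {
  generate_recording(speed, duration, seed = seed, cfg = cfg)
}

# median channel-wise correlation with a reference block
median_chan_cor <- function(x, ref) {
  median(vapply(seq_len(nrow(x)), function(i) cor(x[i, ], ref[i, ]), 0))
}
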