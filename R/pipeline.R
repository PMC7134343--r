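## End-to-end orchestration of the six processing variants:
##   1 single      : single-layer preprocessing only
##   2 asr         : single layer + ASR
##   3 dual        : dual layer, stacked ICA, no extra preprocessing
##   4 noise_cancel: frequency-domain noise cancellation + stacked ICA
##   5 dual_asr    : ASR + stacked ICA
##   6 pca_cca     : windowed PCA + CCA cleaning + stacked ICA

#' Pipeline configuration
#'
#' Defaults carry the standard parameter set: 1 Hz high-pass, robust z = 5
#' channel rejection, 256 Hz analysis rate, 0.5 s / 94% cancellation windows
#' with 6x/2x cutoffs, 0.5 s / 50% PCA windows (2 SD scores, 5 SD noise
#' correlation), 3 s / 50% CCA windows, ASR k = 7, slope -0.06 dB/Hz and
#' R^2 0.99 rejection, alpha 0.05.
#'
#' @param method one of "single", "asr", "dual", "noise_cancel", "dual_asr",
#'   "pca_cca".
#' @param highpass_hz,reject_z,resample_hz channel conditioning parameters.
#' @param asr_k ASR standard-deviation cutoff.
#' @param cancellation a [cancellation_config()].
#' @param pca a [pca_clean_config()].
#' @param cca a [cca_clean_config()].
#' @param ica list: `n_dims` (NULL = scalp + EMG channel count), `seed`.
#' @param rejection list: `slope_thresh`, `r2_thresh`, `poly_order`.
#' @param ersp list: `freqs`, `n_boot`, `alpha`, `n_grid`.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(method = "pca_cca", highpass_hz = 1, reject_z = 5,
                            resample_hz = 256, asr_k = 7,
                            cancellation = cancellation_config(),
                            pca = pca_clean_config(),
                            cca = cca_clean_config(),
                            ica = list(n_dims = NULL, seed = 1),
                            rejection = list(slope_thresh = -0.06,
                                             r2_thresh = 0.99,
                                             poly_order = 2),
                            ersp = list(freqs = exp(seq(log(3), log(100),
                                                        length.out = 30)),
                                        n_boot = 200, alpha = 0.05,
                                        n_grid = 200),
                            seed = 1) {
  method <- match.arg(method, c("single", "asr", "dual", "noise_cancel",
                                "dual_asr", "pca_cca"))
  stopifnot(highpass_hz > 0, reject_z > 0, resample_hz > 0, asr_k > 0)
  structure(list(method = method, highpass_hz = highpass_hz,
                 reject_z = reject_z, resample_hz = resample_hz,
                 asr_k = asr_k, cancellation = cancellation, pca = pca,
                 cca = cca, ica = ica, rejection = rejection, ersp = ersp,
                 seed = seed), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; nested blocks
#' (`cancellation`, `pca`, `cca`, `ica`, `rejection`, `ersp`) override the
#' corresponding sub-config fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("method", "highpass_hz", "reject_z", "resample_hz", "asr_k",
              "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$cancellation))
    args$cancellation <- do.call(cancellation_config, y$cancellation)
  if (!is.null(y$pca)) args$pca <- do.call(pca_clean_config, y$pca)
  if (!is.null(y$cca)) args$cca <- do.call(cca_clean_config, y$cca)
  cfg <- do.call(pipeline_config, args)
  for (k in c("ica", "rejection", "ersp"))
    if (!is.null(y[[k]])) cfg[[k]][names(y[[k]])] <- y[[k]]
  cfg
}

preprocess_condition <- function(rec, cfg, reference) {
  rec <- highpass(rec, cfg$highpass_hz)
  rej <- reject_channels(rec, cfg$reject_z)
  rec <- rereference(rej$recording, reference)
  rec
}

## analysis channels: scalp electrodes nearest left/right motor-cortex
## positions (fall back to two mid-array channels without a montage)
motor_channels <- function(rec) {
  if (is.null(rec$montage)) {
    n <- nrow(rec$eeg)
    return(unique(c(max(1, round(n / 3)), min(n, round(2 * n / 3)))))
  }
  pos <- as.matrix(rec$montage[grepl("^EEG", rec$montage$label),
                               c("x", "y", "z")])
  targets <- rbind(c(-0.55, 0.05, 0.83), c(0.55, 0.05, 0.83))
  targets <- targets / sqrt(rowSums(targets^2))
  vapply(1:2, function(i)
    which.min(rowSums((pos - matrix(targets[i, ], nrow(pos), 3,
                                    byrow = TRUE))^2)), 0L)
}

#' Run a processing variant end to end on a multi-speed dataset
#'
#' Preprocesses each walking condition (high-pass, channel rejection,
#' referencing), applies the variant's cleaning, downsamples, and for the
#' dual-layer variants runs stacked-channel ICA across concatenated
#' conditions followed by spectral component rejection and back-projection.
#' Gait ERSPs at left/right motor-area channels and a permutation comparison
#' of spectra across speeds close the run. Every threshold and seed is logged
#' in the returned manifest.
#'
#' @param dataset output of [generate_dataset()] (or an equally shaped named
#'   list of conditions with `recording` and either `grf` or
#'   `ground_truth$events`; a "baseline" element is required for the ASR
#'   variants).
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param ersp_channels scalp channels to analyze (default: left/right
#'   motor-area channels from the montage).
#' @return object of class `dl_pipeline`: `cleaned` (scalp block per walking
#'   condition on the analysis clock), `events` (rescaled), `ersp` (per
#'   condition), `comparison` (a `speed_comparison`), `ica`, `rejection`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         ersp_channels = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  method <- cfg$method
  t0 <- Sys.time()
  walking <- setdiff(names(dataset), "baseline")
  if (!length(walking)) stop("dataset contains no walking conditions")
  reference <- if (method %in% c("single", "dual")) "common" else "robust"
  needs_asr <- method %in% c("asr", "dual_asr")
  if (needs_asr && !"baseline" %in% names(dataset))
    stop("method '", method, "' requires a standing baseline condition ",
         "('baseline' element) for ASR calibration")
  asr_model <- NULL
  if (needs_asr) {
    base <- preprocess_condition(dataset$baseline$recording, cfg, reference)
    base$bad_channels <- integer(0)    # calibration uses the full montage
    asr_model <- asr_calibrate(base, k = cfg$asr_k)
  }
  manifest <- list(method = method, config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("duallayer")),
                   conditions = walking, stages = list())
  cleaned <- list(); events <- list(); matched_noise <- list(); emg <- list()
  for (cond in walking) {
    rec0 <- dataset[[cond]]$recording
    ev <- dataset[[cond]]$ground_truth$events %||% {
      grf <- dataset[[cond]]$grf
      if (is.null(grf)) stop("condition ", cond, " has neither events nor GRF")
      detect_gait_events(grf$left, grf$right, rec0$fs)
    }
    rec <- preprocess_condition(rec0, cfg, reference)
    stage <- list(bad_channels = rec$bad_channels)
    if (method == "noise_cancel") {
      vn <- interpolate_noise_layer(rec)
      cc <- cancel_recording(rec, vn, cfg$cancellation)
      rec <- cc$recording
      stage$flagged_bins <- sum(cc$flag_counts)
    } else if (method == "pca_cca") {
      gc_ <- good_channels(rec)
      nm <- colMeans(rec$noise)
      rec$eeg[gc_, ] <- pca_window_clean(rec$eeg[gc_, , drop = FALSE], nm,
                                         rec$fs, cfg$pca)
      rec$eeg[gc_, ] <- cca_window_clean(rec$eeg[gc_, , drop = FALSE], nm,
                                         rec$fs, cfg$cca)
    } else if (method %in% c("asr", "dual_asr")) {
      rec <- asr_clean(rec, asr_model)
    }
    if (cfg$resample_hz < rec$fs) {
      ev <- rescale_events(ev, cfg$resample_hz)
      rec <- resample_recording(rec, cfg$resample_hz)
    }
    if (method %in% c("dual", "noise_cancel", "dual_asr", "pca_cca")) {
      mn <- matrix(0, nrow(rec$noise), ncol(rec$noise))
      for (j in seq_len(nrow(rec$noise)))
        mn[j, ] <- amplitude_matched_noise(rec$eeg[rec$pairing[j], ],
                                           rec$noise[j, ], rec$fs,
                                           cfg$cancellation)
      matched_noise[[cond]] <- mn
    }
    cleaned[[cond]] <- rec
    events[[cond]] <- ev
    emg[[cond]] <- rec$emg
    manifest$stages[[cond]] <- stage
  }
  ica <- NULL; rejection <- NULL
  dual_method <- method %in% c("dual", "noise_cancel", "dual_asr", "pca_cca")
  gc_ <- Reduce(intersect, lapply(cleaned, good_channels))
  if (dual_method) {
    stack <- do.call(cbind, lapply(walking, function(cond)
      rbind(cleaned[[cond]]$eeg[gc_, , drop = FALSE],
            matched_noise[[cond]], emg[[cond]])))
    n_dims <- cfg$ica$n_dims %||% min(nrow(stack),
                                      length(gc_) + nrow(emg[[walking[1]]]))
    ica <- run_ica(stack, n_dims = n_dims, fs = cfg$resample_hz,
                   seed = cfg$ica$seed %||% cfg$seed)
    noise_rows <- length(gc_) + seq_len(nrow(matched_noise[[walking[1]]]))
    emg_rows <- length(gc_) + nrow(matched_noise[[walking[1]]]) +
      seq_len(nrow(emg[[walking[1]]]))
    ref_noise <- component_spectra(stack[noise_rows, , drop = FALSE],
                                   fs = cfg$resample_hz)
    ref_emg <- component_spectra(stack[emg_rows, , drop = FALSE],
                                 fs = cfg$resample_hz)
    rejection <- reject_components(ica, ref_noise$db, ref_emg$db,
                                   slope_thresh = cfg$rejection$slope_thresh,
                                   r2_thresh = cfg$rejection$r2_thresh,
                                   poly_order = cfg$rejection$poly_order)
    manifest$stages$ica <- list(n_dims = n_dims,
                                rejected = rejection$rejected,
                                reasons = rejection$report$reason)
    kept <- rejection$kept
    if (!length(kept)) kept <- seq_len(n_dims)  # degenerate: keep everything
    proj <- back_project(ica, kept, rows = seq_along(gc_))
    lens <- vapply(walking, function(cond) ncol(cleaned[[cond]]$eeg), 0L)
    off <- cumsum(c(0, lens))
    for (i in seq_along(walking)) {
      cond <- walking[i]
      cleaned[[cond]]$eeg[gc_, ] <- proj[, (off[i] + 1):off[i + 1],
                                         drop = FALSE]
    }
  }
  ersp_channels <- ersp_channels %||% motor_channels(cleaned[[walking[1]]])
  ersp_res <- list(); spectra <- list()
  freqs <- cfg$ersp$freqs
  freqs <- freqs[freqs < cfg$resample_hz / 2]
  for (cond in walking) {
    tfrs <- list(); spec <- NULL; targets <- NULL
    for (ch in ersp_channels) {
      ep <- epoch_strides(cleaned[[cond]]$eeg[ch, ], events[[cond]],
                          margin_sec = 0.3)
      if (is.null(targets)) {
        lat <- do.call(rbind, ep$latencies)
        targets <- as.list(apply(lat, 2, median))
      }
      for (i in seq_along(ep$epochs)) {
        tfr <- duallayer:::stride_tfr(ep, i, freqs, cleaned[[cond]]$fs)
        tfrs[[length(tfrs) + 1L]] <- time_warp(tfr, ep$latencies[[i]],
                                               targets, cfg$ersp$n_grid)
        spec <- rbind(spec, rowMeans(tfr))
      }
    }
    er <- ersp(tfrs, freqs = freqs, n_boot = cfg$ersp$n_boot,
               alpha = cfg$ersp$alpha, seed = cfg$seed)
    er$targets <- targets
    ersp_res[[cond]] <- er
    spectra[[cond]] <- spec
  }
  comparison <- if (length(walking) >= 2)
    speed_comparison(spectra, freqs = freqs, alpha = cfg$ersp$alpha,
                     seed = cfg$seed) else NULL
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(cleaned = lapply(cleaned, function(r)
    r$eeg), events = events, good_channels = gc_,
    ersp_channels = ersp_channels, ersp = ersp_res, comparison = comparison,
    ica = ica, rejection = rejection, fs = cfg$resample_hz,
    manifest = manifest), class = "dl_pipeline")
}

#' @export
print.dl_pipeline <- function(x, ...) {
  cat("Dual-layer EEG pipeline run\n")
  cat("  method    :", x$manifest$method, "\n")
  cat("  conditions:", paste(x$manifest$conditions, collapse = ", "), "\n")
  if (!is.null(x$rejection))
    cat(sprintf("  components: %d kept, %d rejected\n",
                length(x$rejection$kept), length(x$rejection$rejected)))
  if (!is.null(x$comparison))
    cat(sprintf("  speed comparison: %d significant frequencies\n",
                sum(x$comparison$mask)))
  cat(sprintf("  elapsed   : %.1f s\n", x$manifest$elapsed_sec))
  invisible(x)
}
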