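#' Dual-layer EEG recording container
#'
#' Bundles the three synchronized channel blocks of a dual-layer walking-EEG
#' session: scalp EEG, the mechanically coupled noise-only layer, and neck EMG.
#' All blocks are channels x samples matrices in microvolts and share a common
#' sample clock. The pairing map links each noise channel to the scalp channel
#' it is mechanically coupled with.
#'
#' @param eeg numeric matrix, scalp channels x samples (microvolts).
#' @param noise numeric matrix, noise-layer channels x samples (microvolts).
#' @param emg numeric matrix, EMG channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param montage optional data frame with columns `label`, `x`, `y`, `z`
#'   giving 3-D positions (head-centered frame) for scalp and noise channels.
#' @param pairing integer vector, one entry per noise channel, giving the index
#'   of the mechanically coupled scalp channel; must be injective.
#' @param channel_labels optional character vector of labels for all channels
#'   in block order (EEG, noise, EMG).
#' @param bad_channels integer vector of rejected scalp-channel indices.
#' @return object of class `dual_layer_recording`.
#' @export
dual_layer_recording <- function(eeg, noise, emg, fs, montage = NULL,
                                 pairing = NULL, channel_labels = NULL,
                                 bad_channels = integer(0)) {
  eeg <- as.matrix(eeg); noise <- as.matrix(noise); emg <- as.matrix(emg)
  if (is.null(pairing) && nrow(noise) > 0) {
    ## default pairing: noise channels coupled to evenly spaced scalp channels
    pairing <- round(seq(1, nrow(eeg), length.out = nrow(noise)))
  }
  if (is.null(channel_labels)) {
    channel_labels <- c(sprintf("EEG%03d", seq_len(nrow(eeg))),
                        sprintf("NZ%03d", seq_len(nrow(noise))),
                        sprintf("EMG%03d", seq_len(nrow(emg))))
  }
  rec <- structure(list(eeg = eeg, noise = noise, emg = emg, fs = fs,
                        montage = montage, pairing = as.integer(pairing),
                        channel_labels = channel_labels,
                        bad_channels = sort(unique(as.integer(bad_channels)))),
                   class = "dual_layer_recording")
  validate_recording(rec)
  rec
}

#' Validate a dual-layer recording
#'
#' Checks block shape agreement, a positive sampling rate, injectivity of the
#' noise-to-scalp pairing, and that flagged bad channels are scalp indices.
#'
#' @param rec a `dual_layer_recording`.
#' @return the recording, invisibly; errors on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "dual_layer_recording"))
  ns <- ncol(rec$eeg)
  if (nrow(rec$noise) > 0 && ncol(rec$noise) != ns)
    stop("noise block sample count (", ncol(rec$noise),
         ") differs from EEG block (", ns, ")")
  if (nrow(rec$emg) > 0 && ncol(rec$emg) != ns)
    stop("EMG block sample count (", ncol(rec$emg),
         ") differs from EEG block (", ns, ")")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (length(rec$pairing) != nrow(rec$noise))
    stop("pairing must map every noise channel")
  if (length(rec$pairing) > 0) {
    if (anyDuplicated(rec$pairing))
      stop("pairing must be injective into scalp-channel indices")
    if (any(rec$pairing < 1 | rec$pairing > nrow(rec$eeg)))
      stop("pairing indices out of scalp-channel range")
  }
  if (length(rec$bad_channels) &&
      any(rec$bad_channels < 1 | rec$bad_channels > nrow(rec$eeg)))
    stop("bad_channels outside scalp-channel range")
  invisible(rec)
}

#' @export
print.dual_layer_recording <- function(x, ...) {
  cat("Dual-layer EEG recording\n")
  cat(sprintf("  scalp EEG : %d channels\n", nrow(x$eeg)))
  cat(sprintf("  noise     : %d channels\n", nrow(x$noise)))
  cat(sprintf("  EMG       : %d channels\n", nrow(x$emg)))
  cat(sprintf("  samples   : %d (%.1f s at %g Hz)\n",
              ncol(x$eeg), ncol(x$eeg) / x$fs, x$fs))
  if (length(x$bad_channels))
    cat("  bad scalp channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Indices of non-rejected scalp channels
#' @param rec a `dual_layer_recording`.
#' @return integer vector of good scalp-channel indices.
#' @export
good_channels <- function(rec) {
  setdiff(seq_len(nrow(rec$eeg)), rec$bad_channels)
}

#' Gait-event table
#'
#' Per-stride heel-strike and toe-off sample indices for both limbs. Indices
#' are 1-based samples on the recording clock. A stride is delimited by
#' consecutive right heel strikes; within a stride the expected event order is
#' rhs < lto < lhs < rto. Strides violating this order are flagged invalid and
#' excluded from epoching.
#'
#' @param rhs,lhs,rto,lto sorted integer sample indices of right/left heel
#'   strikes and right/left toe offs.
#' @param fs sampling rate in Hz.
#' @param n_samples optional recording length for range validation.
#' @return object of class `gait_event_table` with a `strides` data frame
#'   (columns rhs, lto, lhs, rto, rhs_next, valid).
#' @export
gait_event_table <- function(rhs, lhs, rto, lto, fs, n_samples = NULL) {
  ev <- list(rhs = sort(as.numeric(rhs)), lhs = sort(as.numeric(lhs)),
             rto = sort(as.numeric(rto)), lto = sort(as.numeric(lto)))
  for (nm in names(ev)) {
    if (anyDuplicated(ev[[nm]])) stop("duplicate ", nm, " events")
    if (!is.null(n_samples) && length(ev[[nm]]) &&
        (min(ev[[nm]]) < 1 || max(ev[[nm]]) > n_samples))
      stop(nm, " event index outside recording length")
  }
  strides <- NULL
  if (length(ev$rhs) >= 2) {
    k <- length(ev$rhs) - 1L
    pick_in <- function(x, a, b) {
      hit <- x[x > a & x < b]
      if (length(hit)) hit[1] else NA_real_
    }
    strides <- data.frame(rhs = ev$rhs[seq_len(k)],
                          lto = NA_real_, lhs = NA_real_, rto = NA_real_,
                          rhs_next = ev$rhs[seq_len(k) + 1L])
    for (i in seq_len(k)) {
      strides$lto[i] <- pick_in(ev$lto, strides$rhs[i], strides$rhs_next[i])
      strides$lhs[i] <- pick_in(ev$lhs, strides$rhs[i], strides$rhs_next[i])
      strides$rto[i] <- pick_in(ev$rto, strides$rhs[i], strides$rhs_next[i])
    }
    strides$valid <- with(strides, !is.na(lto) & !is.na(lhs) & !is.na(rto) &
                            rhs < lto & lto < lhs & lhs < rto &
                            rto < rhs_next)
  }
  structure(c(ev, list(fs = fs, strides = strides)),
            class = "gait_event_table")
}

#' @export
print.gait_event_table <- function(x, ...) {
  nv <- if (is.null(x$strides)) 0L else sum(x$strides$valid)
  cat(sprintf("Gait events: %d rhs, %d lhs, %d rto, %d lto at %g Hz; %d valid strides\n",
              length(x$rhs), length(x$lhs), length(x$rto), length(x$lto),
              x$fs, nv))
  invisible(x)
}

#' Read a gait-event table from TSV
#'
#' Expects columns `event_type` (one of rhs, lhs, rto, lto) and
#' `sample_index` (1-based).
#'
#' @param path TSV file path.
#' @param fs sampling rate in Hz.
#' @param n_samples optional recording length for range checks.
#' @return a `gait_event_table`.
#' @export
read_gait_events <- function(path, fs, n_samples = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("event_type", "sample_index") %in% names(tab)))
    stop("event TSV must have columns event_type and sample_index")
  bad <- setdiff(unique(tab$event_type), c("rhs", "lhs", "rto", "lto"))
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  pick <- function(t) tab$sample_index[tab$event_type == t]
  gait_event_table(rhs = pick("rhs"), lhs = pick("lhs"),
                   rto = pick("rto"), lto = pick("lto"),
                   fs = fs, n_samples = n_samples)
}

#' Write a gait-event table to TSV
#' @param events a `gait_event_table`.
#' @param path output TSV path.
#' @export
write_gait_events <- function(events, path) {
  rows <- do.call(rbind, lapply(c("rhs", "lhs", "rto", "lto"), function(t) {
    if (!length(events[[t]])) return(NULL)
    data.frame(event_type = t, sample_index = events[[t]])
  }))
  rows <- rows[order(rows$sample_index), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an electrode montage
#'
#' Whitespace-delimited file with columns `label x y z` (head-centered frame,
#' arbitrary length units).
#'
#' @param path montage file path.
#' @return data frame with columns label, x, y, z.
#' @export
read_montage <- function(path) {
  m <- read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(m[, 2:4])))) stop("non-finite montage position")
  m
}

#' Write an electrode montage
#' @param montage data frame with columns label, x, y, z.
#' @param path output file path.
#' @export
write_montage <- function(montage, path) {
  write.table(montage, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
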