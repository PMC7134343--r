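## BDF (BioSemi 24-bit) and EDF (16-bit) readers/writers, plus the package's
## internal serialized container. Channel roles are carried in the labels
## ("EEG", "NZ", "EMG" prefixes) because neither format stores role metadata.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(formatC(x, format = "fg", width = 1), width)

## signed integers -> little-endian 24-bit raw triples
int_to_raw24 <- function(v) {
  u <- as.numeric(v)
  u[u < 0] <- u[u < 0] + 16777216
  b0 <- u %% 256; u <- (u - b0) / 256
  b1 <- u %% 256; b2 <- (u - b1) / 256
  as.raw(rbind(b0, b1, b2))
}

raw24_to_int <- function(r) {
  m <- matrix(as.integer(r), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  v[v >= 8388608] <- v[v >= 8388608] - 16777216
  v
}

write_biosig <- function(dat, labels, fs, path, bits) {
  n_ch <- nrow(dat); n <- ncol(dat)
  dig_max <- if (bits == 24) 8388607 else 32767
  dig_min <- -dig_max - 1
  pmax_ch <- pmax(apply(abs(dat), 1, max), 1e-6)
  phys_max <- ceiling(pmax_ch)
  phys_min <- -phys_max
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 24) {
    writeBin(as.raw(255), con)
    writeChar("BIOSEMI", con, 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, 8, eos = NULL)
  }
  writeChar(pad_field("local patient", 80), con, 80, eos = NULL)
  writeChar(pad_field("local recording", 80), con, 80, eos = NULL)
  writeChar(pad_field("01.01.26", 8), con, 8, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, 8, eos = NULL)
  writeChar(pad_field(256 * (n_ch + 1), 8), con, 8, eos = NULL)
  writeChar(pad_field(if (bits == 24) "24BIT" else "", 44), con, 44, eos = NULL)
  writeChar(pad_field(1, 8), con, 8, eos = NULL)            # one data record
  writeChar(pad_field(format(n / fs, digits = 7), 8), con, 8, eos = NULL)
  writeChar(pad_field(n_ch, 4), con, 4, eos = NULL)
  wr <- function(vals, width)
    for (v in vals) writeChar(pad_field(v, width), con, width, eos = NULL)
  wr(labels, 16)
  wr(rep("", n_ch), 80)                                     # transducer
  wr(rep("uV", n_ch), 8)
  wr(format(phys_min, digits = 7), 8)
  wr(format(phys_max, digits = 7), 8)
  wr(rep(dig_min, n_ch), 8)
  wr(rep(dig_max, n_ch), 8)
  wr(rep("", n_ch), 80)                                     # prefiltering
  wr(rep(n, n_ch), 8)                                       # samples per record
  wr(rep("", n_ch), 32)
  for (i in seq_len(n_ch)) {
    dig <- round((dat[i, ] - phys_min[i]) / gain[i] + dig_min)
    if (bits == 24) writeBin(int_to_raw24(dig), con)
    else writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_biosig <- function(path, bits) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  readBin(con, "raw", 8)                                    # version field
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                                     # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  dims <- rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(nsamp)) != 1)
    stop("non-uniform sampling across channels is not supported")
  ns <- nsamp[1]
  fs <- ns / (dur / 1)                                      # per record
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- matrix(0, n_ch, ns * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      dig <- if (bits == 24) raw24_to_int(readBin(con, "raw", 3 * ns))
             else readBin(con, "integer", ns, size = 2, signed = TRUE,
                          endian = "little")
      cols <- ((r - 1) * ns + 1):(r * ns)
      dat[i, cols] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  scale_uV <- vapply(dims, function(d)
    switch(tolower(d), "uv" = 1, "mv" = 1e3, "v" = 1e6, 1), 1)
  dat <- dat * scale_uV
  list(data = dat, labels = labels, fs = fs)
}

infer_roles <- function(labels) {
  role <- rep(NA_character_, length(labels))
  role[grepl("^EEG", labels)] <- "eeg"
  role[grepl("^NZ",  labels)] <- "noise"
  role[grepl("^EMG", labels)] <- "emg"
  if (anyNA(role))
    stop("cannot infer channel roles from labels; supply `roles`")
  role
}

#' Read a dual-layer recording
#'
#' Reads a multichannel recording from BDF (BioSemi 24-bit), EDF (16-bit), or
#' the package's internal serialized container, and splits channels into
#' scalp-EEG, noise-layer, and EMG blocks. Role assignment uses an explicit
#' `roles` count vector when given, otherwise the label prefixes
#' ("EEG", "NZ", "EMG"). Samples are returned in microvolts.
#'
#' @param path input file.
#' @param format one of "bdf", "edf", "rds"; default inferred from extension.
#' @param roles optional named vector/list with counts `eeg`, `noise`, `emg`
#'   (channels assumed stored in that block order); must sum to the channel
#'   count in the file.
#' @param montage,pairing optional montage data frame and pairing map passed
#'   to [dual_layer_recording()].
#' @return a `dual_layer_recording`.
#' @export
read_recording <- function(path, format = NULL, roles = NULL,
                           montage = NULL, pairing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tools::file_ext(path)
  format <- match.arg(tolower(format), c("bdf", "edf", "rds"))
  if (format == "rds") {
    obj <- readRDS(path)
    rec <- dual_layer_recording(obj$eeg, obj$noise, obj$emg, obj$fs,
                                montage = obj$montage, pairing = obj$pairing,
                                channel_labels = obj$channel_labels,
                                bad_channels = obj$bad_channels %||% integer(0))
    return(rec)
  }
  raw <- read_biosig(path, bits = if (format == "bdf") 24 else 16)
  n_ch <- nrow(raw$data)
  if (!is.null(roles)) {
    cnt <- c(eeg = as.integer(roles[["eeg"]]),
             noise = as.integer(roles[["noise"]]),
             emg = as.integer(roles[["emg"]]))
    if (sum(cnt) != n_ch)
      stop("role map claims ", sum(cnt), " channels but file has ", n_ch)
    role <- rep(c("eeg", "noise", "emg"), times = cnt)
  } else {
    role <- infer_roles(raw$labels)
  }
  dual_layer_recording(eeg = raw$data[role == "eeg", , drop = FALSE],
                       noise = raw$data[role == "noise", , drop = FALSE],
                       emg = raw$data[role == "emg", , drop = FALSE],
                       fs = raw$fs, montage = montage, pairing = pairing,
                       channel_labels = raw$labels)
}

#' Write a dual-layer recording
#'
#' @param rec a `dual_layer_recording`.
#' @param path output file.
#' @param format one of "bdf", "edf", "rds"; default from extension. The
#'   internal "rds" container round-trips every field exactly; BDF/EDF
#'   quantize samples to the 24-/16-bit integer grid.
#' @export
write_recording <- function(rec, path, format = NULL) {
  validate_recording(rec)
  format <- format %||% tools::file_ext(path)
  format <- match.arg(tolower(format), c("bdf", "edf", "rds"))
  if (format == "rds") {
    saveRDS(unclass(rec), path)
    return(invisible(path))
  }
  dat <- rbind(rec$eeg, rec$noise, rec$emg)
  write_biosig(dat, rec$channel_labels, rec$fs, path,
               bits = if (format == "bdf") 24 else 16)
  invisible(path)
}
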