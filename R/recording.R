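#' Multichannel polysomnography recording
#'
#' A `nap_recording` holds a continuous multichannel EEG signal in microvolts
#' together with its sampling rate, channel labels (10-20 names), reference
#' state and nap-level metadata. Signals are stored as a samples x channels
#' numeric matrix with channel labels as column names. All event and stimulus
#' times throughout the package are seconds from recording start, 0-based,
#' with half-open `[onset, offset)` intervals.
#'
#' @param data Numeric matrix, samples x channels, in microvolts. Column
#'   names are used as channel labels when `channels` is `NULL`.
#' @param fs Sampling rate in Hz (must be > 0).
#' @param channels Character vector of channel labels; must be unique.
#' @param reference Reference state: one of `"online_FCz"`,
#'   `"linked_mastoids"`, `"contralateral_mastoids"`.
#' @param meta Named list of metadata (subject id, condition, visit, ...).
#'
#' @return An object of class `nap_recording`.
#' @export
#' @examples
#' rec <- nap_recording(cbind(Cz = sin(2 * pi * 10 * seq(0, 1, by = 1 / 250))),
#'                      fs = 250)
#' rec
nap_recording <- function(data, fs, channels = NULL,
                          reference = c("online_FCz", "linked_mastoids",
                                        "contralateral_mastoids"),
                          meta = list()) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (is.null(channels)) channels <- colnames(data)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(channels) != ncol(data)) {
    abort("`channels` length must match the number of data columns.")
  }
  if (anyDuplicated(channels)) abort("Channel labels must be unique.")
  if (ncol(data) < 1L) abort("Recording must have at least one channel.")
  if (nrow(data) < 1L) abort("Recording must have at least one sample.")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         reference = reference, meta = meta),
    class = "nap_recording"
  )
}

#' @export
print.nap_recording <- function(x, ...) {
  cat(sprintf("<nap_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), nrow(x$data), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' @rdname nap_recording
#' @param x A `nap_recording`.
#' @export
n_samples <- function(x) nrow(x$data)

#' Duration of a recording in seconds
#' @param x A `nap_recording`.
#' @return Length in seconds.
#' @export
duration_s <- function(x) n_samples(x) / x$fs

## ---------------------------------------------------------------------------
## EDF (European Data Format) reader/writer.
##
## Minimal 16-bit EDF: fixed 256-byte header, one 256-byte signal header per
## channel, then data records of little-endian int16, scaled channelwise by
## the physical/digital min/max in the header. Record duration is 1 s; the
## signal is zero-padded to a whole number of records on write and trimmed on
## read using the stored sample count.
## ---------------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with 1-second data records. Physical min/max are set per
#' channel to span the data symmetrically so that quantization error is below
#' 0.5% of the signal amplitude.
#'
#' @param rec A [nap_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "nap_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer requires an integer sampling rate.")
  fs <- as.integer(round(fs))
  n <- n_samples(rec)
  n_rec <- as.integer(ceiling(n / fs))
  n_ch <- length(rec$channels)

  phys_max <- vapply(seq_len(n_ch), function(j) {
    m <- max(abs(rec$data[, j]), na.rm = TRUE)
    max(m, 1)
  }, numeric(1))
  # symmetric digital range so that 0 uV maps exactly to digital 0
  dig_max <- 32767; dig_min <- -32767

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(edf_pad("0", 8), con, eos = NULL)
  writeChar(edf_pad(rec$meta$subject %||% "X", 80), con, eos = NULL)
  writeChar(edf_pad(sprintf("ref:%s cond:%s", rec$reference,
                            rec$meta$condition %||% "NA"), 80), con, eos = NULL)
  writeChar(edf_pad("01.01.26", 8), con, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, eos = NULL)
  writeChar(edf_pad(256L * (1L + n_ch), 8), con, eos = NULL)
  writeChar(edf_pad(sprintf("nsamp=%d", n), 44), con, eos = NULL)  # reserved
  writeChar(edf_pad(n_rec, 8), con, eos = NULL)
  writeChar(edf_pad(1L, 8), con, eos = NULL)
  writeChar(edf_pad(n_ch, 4), con, eos = NULL)

  field <- function(vals, width) {
    for (v in vals) writeChar(edf_pad(v, width), con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("EEG", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(sprintf("%.6g", -phys_max), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(dig_min, n_ch), 8)
  field(rep(dig_max, n_ch), 8)
  field(rep("", n_ch), 80)
  field(rep(fs, n_ch), 8)
  field(rep("", n_ch), 32)

  pad_len <- n_rec * fs - n
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):min(r * fs, n)
    for (j in seq_len(n_ch)) {
      x <- rec$data[idx, j]
      if (r == n_rec && pad_len > 0L) x <- c(x, numeric(pad_len))
      d <- round(x / phys_max[j] * dig_max)
      d <- as.integer(pmin(pmax(d, dig_min), dig_max))
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path Path to an EDF/EDF+ file.
#' @param meta Optional metadata list attached to the returned recording.
#' @return A [nap_recording()] with microvolt-scaled signals. The reference
#'   is `"online_FCz"` unless the header's recording-id field states another
#'   scheme (as written by [write_edf()]).
#' @export
read_edf <- function(path, meta = list()) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < width) {
      abort("Corrupt or truncated EDF header.")
    }
    trimws(raw)
  }
  rd(8)                      # version
  rd(80)                     # patient id
  recid <- rd(80)
  rd(8); rd(8)               # date, time
  rd(8)                      # header bytes
  reserved <- rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  n_ch <- suppressWarnings(as.integer(rd(4)))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(n_ch)) {
    abort("Corrupt EDF header: non-numeric record fields.")
  }
  if (n_ch < 1L) abort("EDF file contains zero signals.")

  fields <- function(width) vapply(seq_len(n_ch), function(i) rd(width), character(1))
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (anyDuplicated(labels)) abort("EDF file has duplicate channel labels.")
  if (length(unique(spr)) != 1L) {
    abort("EDF reader requires a single sampling rate across signals.")
  }
  fs <- spr[1] / rec_dur

  total <- n_rec * spr[1]
  data <- matrix(0, nrow = total, ncol = n_ch)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(n_ch)) {
      d <- readBin(con, integer(), n = spr[j], size = 2L,
                   signed = TRUE, endian = "little")
      if (length(d) < spr[j]) abort("Corrupt EDF: truncated data record.")
      g <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
      data[((r - 1L) * spr[1] + 1L):(r * spr[1]), j] <- (d - dig_min[j]) * g + phys_min[j]
    }
  }
  nsamp <- total
  m <- regmatches(reserved, regexec("nsamp=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) nsamp <- min(total, as.integer(m[2]))
  data <- data[seq_len(nsamp), , drop = FALSE]
  colnames(data) <- labels

  ref <- "online_FCz"
  mref <- regmatches(recid, regexec("ref:([A-Za-z_]+)", recid))[[1]]
  if (length(mref) == 2L &&
      mref[2] %in% c("online_FCz", "linked_mastoids", "contralateral_mastoids")) {
    ref <- mref[2]
  }
  nap_recording(data, fs = fs, channels = labels, reference = ref, meta = meta)
}
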