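#' Band-pass filter specification
#'
#' Defaults follow the pre-processing chain used for infant nap EEG: a
#' first-order Butterworth band-pass from 0.2 to 40 Hz applied zero-phase
#' (forward-backward), plus notch filters at the 50-Hz line frequency and
#' its harmonics. Notch frequencies at or above the band-pass upper edge (or
#' the Nyquist frequency) are no-ops and skipped with a message.
#'
#' @param band_low,band_high Band edges in Hz.
#' @param order Butterworth order (default 1).
#' @param notch_freqs Notch frequencies in Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 0.2, band_high = 40, order = 1,
                        notch_freqs = c(50, 100, 150, 200)) {
  if (band_low <= 0 || band_high <= band_low) {
    abort("Require 0 < band_low < band_high.")
  }
  if (order < 1) abort("Filter order must be >= 1.")
  structure(list(band_low = band_low, band_high = band_high,
                 order = order, notch_freqs = notch_freqs),
            class = "filter_spec")
}

butter_filtfilt <- function(x, fs, low, high, order) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Zero-phase Butterworth band-pass of a recording
#'
#' Applies the band-pass forward and backward (zero phase, so event peak
#' latencies are not shifted; the squared magnitude response is the
#' effective attenuation). Notch filters are applied as second-order
#' band-stops where applicable.
#'
#' @param rec A [nap_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "nap_recording"))
  fs <- rec$fs
  if (spec$band_high >= fs / 2) {
    abort("band_high must be below the Nyquist frequency fs/2.")
  }
  out <- rec
  for (j in seq_len(ncol(rec$data))) {
    out$data[, j] <- butter_filtfilt(rec$data[, j], fs,
                                     spec$band_low, spec$band_high,
                                     spec$order)
  }
  live <- spec$notch_freqs[spec$notch_freqs < fs / 2 &
                             spec$notch_freqs < spec$band_high]
  skipped <- setdiff(spec$notch_freqs, live)
  if (length(skipped)) {
    inform(sprintf(
      "Notch at %s Hz skipped (at/above band edge or Nyquist).",
      paste(skipped, collapse = ", ")))
  }
  for (f0 in live) {
    bs <- signal::butter(2, c(f0 - 1, f0 + 1) / (fs / 2), type = "stop")
    for (j in seq_len(ncol(out$data))) {
      out$data[, j] <- signal::filtfilt(bs, out$data[, j])
    }
  }
  out
}

#' Re-reference a recording to the mastoids
#'
#' `linked_mastoids` subtracts the mean of the two mastoid channels from
#' every channel; `contralateral_mastoids` subtracts the opposite-side
#' mastoid from each lateral channel (odd 10-20 digits are left, even are
#' right) and the linked average from midline (`z`) channels. Recordings
#' with a bad mastoid are excluded, mirroring the handling of naps with
#' bad-quality mastoid channels.
#'
#' @param rec A [nap_recording()].
#' @param scheme `"linked_mastoids"` or `"contralateral_mastoids"`.
#' @param mastoids Labels of the left and right mastoid channels.
#' @param bad_channels Channels flagged bad (input metadata); if either
#'   mastoid is listed, an exclusion error is raised.
#' @return The re-referenced recording with its `reference` field updated.
#' @export
rereference <- function(rec, scheme = c("linked_mastoids",
                                        "contralateral_mastoids"),
                        mastoids = c("TP9", "TP10"),
                        bad_channels = character()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rec, "nap_recording"))
  if (!all(mastoids %in% rec$channels)) {
    abort(sprintf("Mastoid channel(s) missing: %s",
                  paste(setdiff(mastoids, rec$channels), collapse = ", ")))
  }
  if (any(mastoids %in% bad_channels)) {
    abort(class = "napscape_exclusion",
          message = "Recording excluded: one or both mastoid channels flagged bad.")
  }
  m_left <- rec$data[, mastoids[1]]
  m_right <- rec$data[, mastoids[2]]
  linked <- (m_left + m_right) / 2
  out <- rec
  if (scheme == "linked_mastoids") {
    out$data <- rec$data - linked
  } else {
    for (j in seq_along(rec$channels)) {
      ch <- rec$channels[j]
      side <- channel_side(ch)
      ref <- switch(side, left = m_right, right = m_left, linked)
      out$data[, j] <- rec$data[, j] - ref
    }
  }
  out$reference <- scheme
  out
}

# 10-20 hemisphere from the trailing digit: odd = left, even = right,
# 'z' (or no digit) = midline.
channel_side <- function(label) {
  d <- regmatches(label, regexpr("[0-9]+$", label))
  if (!length(d)) return("midline")
  if (as.integer(d) %% 2 == 1) "left" else "right"
}

#' Automatic artifact detection on 1-s windows
#'
#' For each 1-s window the root-mean-square amplitude is computed per
#' channel; the cross-channel mean of the log-RMS is standardized within
#' each sleep stage and windows whose |z| exceeds `z_thresh` are flagged.
#' This is a covariance-free per-window detector with a single interpretable
#' knob, operating at the same 1-s granularity as the pre-processing chain
#' it mirrors.
#'
#' @param rec A filtered, re-referenced [nap_recording()].
#' @param hyp A [nap_hypnogram()] covering the recording.
#' @param win_s Window length in seconds (default 1).
#' @param z_thresh Standardized threshold (default 3).
#' @return Logical vector with one element per window, with attribute
#'   `by_stage`: a tibble of flagged fractions per stage.
#' @export
detect_artifacts <- function(rec, hyp, win_s = 1, z_thresh = 3) {
  stopifnot(inherits(rec, "nap_recording"), inherits(hyp, "nap_hypnogram"))
  fs <- rec$fs
  n <- n_samples(rec)
  if (hypnogram_duration(hyp) + hyp$epoch_s < n / fs) {
    abort("Hypnogram does not cover the recording.")
  }
  wlen <- round(win_s * fs)
  n_win <- floor(n / wlen)
  if (n_win < 1) abort("Recording shorter than one window.")
  stage_win <- stage_at_sample(hyp, fs, n)[seq(1, by = wlen,
                                               length.out = n_win)]
  logrms <- vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    mean(log(sqrt(colMeans(rec$data[idx, , drop = FALSE]^2)) + 1e-12))
  }, numeric(1))
  z <- numeric(n_win)
  for (st in unique(stage_win)) {
    i <- stage_win == st
    mu <- mean(logrms[i])
    s <- sd(logrms[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (logrms[i] - mu) / s
  }
  mask <- abs(z) > z_thresh
  by_stage <- tibble(stage = stage_win, flagged = mask) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     n_flagged = sum(.data$flagged),
                     fraction = mean(.data$flagged), .groups = "drop")
  attr(mask, "by_stage") <- by_stage
  attr(mask, "win_s") <- win_s
  mask
}
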