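#' Welch power spectral density with median combining
#'
#' One-sided PSD in uV^2/Hz from Hann-windowed segments (default 4 s, 50%
#' overlap) with the median taken across segment periodograms. Segments are
#' drawn only from the supplied contiguous runs so that no segment spans an
#' excision (artifact/arousal/stage) boundary.
#'
#' @param x Numeric signal in microvolts.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 4; frequency resolution
#'   is `1/seg_s`).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param runs Optional tibble of eligible runs (columns `start`, `end`,
#'   1-based inclusive sample indices, e.g. from [mask_runs()]); default is
#'   the whole signal.
#' @return A tibble of class `nap_psd` with columns `freq` (Hz) and `psd`
#'   (uV^2/Hz); attributes `fs`, `seg_s`, `n_segments`.
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5, runs = NULL) {
  nper <- round(seg_s * fs)
  if (is.null(runs)) runs <- tibble(start = 1L, end = length(x))
  step <- max(1L, round(nper * (1 - overlap)))
  w <- hann_window(nper)
  u <- sum(w^2)  # window energy for density scaling
  segs <- list()
  for (i in seq_len(nrow(runs))) {
    s0 <- runs$start[i]
    e0 <- runs$end[i]
    if (e0 - s0 + 1L < nper) next
    starts <- seq(s0, e0 - nper + 1L, by = step)
    for (st in starts) segs[[length(segs) + 1L]] <- x[st:(st + nper - 1L)]
  }
  if (!length(segs)) {
    abort("Insufficient data: no eligible run is at least one segment long.")
  }
  n_freq <- floor(nper / 2) + 1L
  periodograms <- vapply(segs, function(s) {
    s <- (s - mean(s)) * w
    p <- Mod(fft(s))^2 / (fs * u)
    p <- p[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist when nper is even)
    mult <- rep(2, n_freq)
    mult[1] <- 1
    if (nper %% 2 == 0) mult[n_freq] <- 1
    p * mult
  }, numeric(n_freq))
  psd <- apply(periodograms, 1, median)
  out <- tibble(freq = seq(0, by = 1 / seg_s, length.out = n_freq),
                psd = psd)
  attr(out, "fs") <- fs
  attr(out, "seg_s") <- seg_s
  attr(out, "n_segments") <- length(segs)
  class(out) <- unique(c("nap_psd", class(out)))
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the PSD over `[low, high]`, with linear
#' interpolation at band edges that fall between grid points.
#'
#' @param psd A [welch_psd()] result (or any tibble with `freq`, `psd`).
#' @param band Numeric length-2 vector `c(low, high)` in Hz.
#' @return Absolute band power in uV^2.
#' @export
band_power <- function(psd, band) {
  f <- psd$freq
  p <- psd$psd
  if (band[1] > band[2]) abort("Band low must not exceed band high.")
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9) {
    abort("Band lies outside the PSD frequency grid.")
  }
  if (band[1] == band[2]) return(0)
  inside <- f > band[1] & f < band[2]
  fg <- c(band[1], f[inside], band[2])
  pg <- c(approx(f, p, xout = band[1])$y, p[inside],
          approx(f, p, xout = band[2])$y)
  sum(diff(fg) * (head(pg, -1) + tail(pg, -1)) / 2)
}

#' Stage-restricted band power over a channel region of interest
#'
#' Computes the Welch band power per channel from artifact-free data in the
#' requested stages, then takes the median across the ROI. Slow-wave
#' activity (0.5-2 Hz) uses N2+N3 over the ten-channel ROI; sigma power
#' (9-16 Hz) uses N2 only over the eight-channel ROI.
#'
#' @param rec A preprocessed [nap_recording()].
#' @param hyp A [nap_hypnogram()].
#' @param band `c(low, high)` in Hz.
#' @param stages Stage codes to include.
#' @param roi Channel labels of the region of interest.
#' @param seg_s Welch segment length in seconds.
#' @param artifact_mask Optional 1-s logical mask overriding the hypnogram's.
#' @return A one-row tibble with `roi_value` (median across ROI, uV^2),
#'   `seconds_used`, and a list-column `per_channel`.
#' @export
roi_band_power <- function(rec, hyp, band, stages = c("N2", "N3"),
                           roi = roi_channels("swa"), seg_s = 4,
                           artifact_mask = NULL) {
  missing_ch <- setdiff(roi, rec$channels)
  if (length(missing_ch)) {
    abort(sprintf("ROI channel(s) missing from recording: %s",
                  paste(missing_ch, collapse = ", ")))
  }
  n <- n_samples(rec)
  ok <- eligible_mask(hyp, rec$fs, n, stages = stages,
                      artifact_mask = artifact_mask)
  runs <- mask_runs(ok)
  runs <- runs[runs$length >= round(seg_s * rec$fs), , drop = FALSE]
  if (!nrow(runs)) {
    abort("Insufficient data: no artifact-free run in the requested stages.")
  }
  per_channel <- vapply(roi, function(ch) {
    band_power(welch_psd(rec$data[, ch], rec$fs, seg_s = seg_s, runs = runs),
               band)
  }, numeric(1))
  tibble(band_low = band[1], band_high = band[2],
         roi_value = median(per_channel),
         seconds_used = sum(ok) / rec$fs,
         stages = paste(stages, collapse = "+"),
         per_channel = list(tibble(channel = roi, power = per_channel)))
}

#' Standard channel regions of interest
#'
#' @param which `"swa"` (ten channels, used for slow-wave activity and slow
#'   wave density) or `"sigma"` (eight channels, used for sigma power and
#'   spindle density).
#' @return Character vector of channel labels.
#' @export
roi_channels <- function(which = c("swa", "sigma")) {
  which <- match.arg(which)
  base <- c("F3", "Fz", "F4", "FC1", "FC2", "C3", "Cz", "C4")
  if (which == "swa") c(base, "O1", "Oz") else base
}

#' @export
autoplot.nap_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}
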