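#' Stimulus-locked analysis window geometry
#'
#' Windows are expressed in seconds relative to S1 onset, half-open
#' `[low, high)`. The spindle ON window spans S1 (1 s), the S1-S2 gap
#' (700 ms), S2 (1 s) and a post-S2 interval equal to the gap (700 ms):
#' 3.4 s in total. The OFF window is the mirror-image pre-S1 window. The
#' spindle analysis segment adds a 1-s buffer at each end (8.8 s,
#' -4.4 to +4.4). The K-complex ON window is where the negative peak of an
#' evoked K-complex falls, 450-700 ms after S1; its OFF control window is
#' the equal-length -1250 to -1000 ms window. The K-complex detection
#' segment spans -4.15 to +12.35 s (the minimum-length requirement of the
#' slow-wave detector).
#'
#' @param tone_s Tone duration in seconds.
#' @param gap_s Intra-pair gap in seconds.
#' @param buffer_s Edge buffer of the spindle segment in seconds.
#' @param kc_on K-complex ON window `c(low, high)` relative to S1.
#' @param kc_off K-complex OFF window.
#' @param kc_segment K-complex detection segment relative to S1.
#' @return A list of class `window_spec` with elements `sp_on`, `sp_off`,
#'   `sp_segment`, `kc_on`, `kc_off`, `kc_segment`.
#' @export
window_spec <- function(tone_s = 1, gap_s = 0.7, buffer_s = 1,
                        kc_on = c(0.45, 0.7), kc_off = c(-1.25, -1.0),
                        kc_segment = c(-4.15, 12.35)) {
  on_len <- 2 * tone_s + 2 * gap_s
  structure(list(
    sp_on = c(0, on_len),
    sp_off = c(-on_len, 0),
    sp_segment = c(-(on_len + buffer_s), on_len + buffer_s),
    kc_on = kc_on, kc_off = kc_off, kc_segment = kc_segment,
    tone_s = tone_s, gap_s = gap_s, buffer_s = buffer_s),
    class = "window_spec")
}

#' Select stimuli whose analysis segment is clean N2
#'
#' An S1 is eligible iff every sample of `[s1 + segment[1], s1 + segment[2])`
#' lies in the requested stage with no artifact or arousal sample, and the
#' segment lies inside the recording.
#'
#' @param train A [stimulus_train()].
#' @param hyp A [nap_hypnogram()].
#' @param fs Sampling rate in Hz.
#' @param n Number of samples in the recording.
#' @param segment `c(low, high)` seconds relative to S1.
#' @param stages Eligible stage codes (default N2).
#' @param artifact_mask Optional 1-s mask overriding the hypnogram's.
#' @return Numeric vector of eligible S1 onsets (seconds).
#' @export
select_eligible_stimuli <- function(train, hyp, fs, n,
                                    segment = window_spec()$sp_segment,
                                    stages = "N2", artifact_mask = NULL) {
  ok <- eligible_mask(hyp, fs, n, stages = stages,
                      artifact_mask = artifact_mask)
  keep <- vapply(train$s1_onset, function(s1) {
    i0 <- floor((s1 + segment[1]) * fs) + 1L
    i1 <- ceiling((s1 + segment[2]) * fs)
    if (i0 < 1L || i1 > n) return(FALSE)
    all(ok[i0:i1])
  }, logical(1))
  train$s1_onset[keep]
}

#' Stimulus-locked evoked average
#'
#' Time-locked mean across eligible stimuli, then across channels, with
#' baseline correction by the mean of the pre-S1 part of the window.
#'
#' @param rec A preprocessed [nap_recording()].
#' @param s1_onsets Eligible S1 onsets in seconds.
#' @param channels Channels to average (default central: C3, Cz, C4).
#' @param window `c(low, high)` seconds relative to S1.
#' @return A tibble of class `nap_erp` with columns `time` (s, relative to
#'   S1) and `amplitude` (uV); attribute `n_stimuli`.
#' @export
evoked_average <- function(rec, s1_onsets, channels = c("C3", "Cz", "C4"),
                           window = c(-1, 3)) {
  if (!length(s1_onsets)) {
    abort("Insufficient data: no eligible stimuli for the evoked average.")
  }
  channels <- intersect(channels, rec$channels)
  if (!length(channels)) abort("No requested channel present.")
  fs <- rec$fs
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  t_rel <- rel / fs
  acc <- matrix(0, nrow = length(rel), ncol = length(channels))
  used <- 0L
  for (s1 in s1_onsets) {
    i <- round(s1 * fs) + 1L + rel
    if (i[1] < 1L || i[length(i)] > n_samples(rec)) next
    acc <- acc + rec$data[i, channels, drop = FALSE]
    used <- used + 1L
  }
  if (!used) abort("Insufficient data: no stimulus window inside recording.")
  epochs <- acc / used
  base <- colMeans(epochs[t_rel < 0, , drop = FALSE])
  epochs <- sweep(epochs, 2, base)
  out <- tibble(time = t_rel, amplitude = rowMeans(epochs))
  attr(out, "n_stimuli") <- used
  class(out) <- unique(c("nap_erp", class(out)))
  out
}

#' Histogram of slow-wave negative-peak latencies around tone onsets
#'
#' Counts negative peaks of detected slow waves in latency bins relative to
#' S1 and to S2, to visualise the enrichment of evoked K-complexes in the
#' 450-700 ms window.
#'
#' @param events Event tibble with `neg_peak_time` populated.
#' @param train A [stimulus_train()].
#' @param bin_s Bin width in seconds.
#' @param span `c(low, high)` latency span in seconds.
#' @return Tibble with columns `tone` (`"S1"`/`"S2"`), `bin_mid`, `count`.
#' @export
peak_latency_histogram <- function(events, train, bin_s = 0.05,
                                   span = c(-1.5, 2)) {
  breaks <- seq(span[1], span[2], by = bin_s)
  mids <- head(breaks, -1) + bin_s / 2
  peaks <- events$neg_peak_time[!is.na(events$neg_peak_time)]
  one <- function(onsets, label) {
    lat <- as.vector(outer(peaks, onsets, "-"))
    lat <- lat[lat >= span[1] & lat < span[2]]
    counts <- if (length(lat)) {
      tabulate(findInterval(lat, breaks), nbins = length(mids))
    } else rep(0L, length(mids))
    tibble(tone = label, bin_mid = mids, count = counts)
  }
  dplyr::bind_rows(one(train$s1_onset, "S1"), one(train$s2_onset, "S2"))
}

count_in_windows <- function(times, s1_onsets, window) {
  sum(vapply(s1_onsets, function(s1) {
    sum(times >= s1 + window[1] & times < s1 + window[2])
  }, numeric(1)))
}

#' K-complex likelihood in the ON and OFF windows
#'
#' Counts detected slow waves (channel Cz) whose negative peak falls in the
#' window relative to each eligible S1 and divides by the number of
#' eligible stimuli. Only S1 responses are counted (refractory period after
#' an evoked K-complex). Windows are half-open `[low, high)`.
#'
#' @param events Slow-wave event tibble (Cz).
#' @param s1_onsets Eligible S1 onsets.
#' @param windows A [window_spec()].
#' @return Tibble with one row per window (`"on"`, `"off"`): `count`,
#'   `n_stimuli`, `likelihood`.
#' @export
kcomplex_likelihood <- function(events, s1_onsets, windows = window_spec()) {
  if (!length(s1_onsets)) {
    abort("Insufficient data: no eligible stimuli.")
  }
  peaks <- events$neg_peak_time[!is.na(events$neg_peak_time)]
  tibble(
    window = c("on", "off"),
    count = c(count_in_windows(peaks, s1_onsets, windows$kc_on),
              count_in_windows(peaks, s1_onsets, windows$kc_off)),
    n_stimuli = length(s1_onsets)) |>
    dplyr::mutate(likelihood = .data$count / .data$n_stimuli)
}

#' Sleep-spindle likelihood in the ON and OFF windows
#'
#' As [kcomplex_likelihood()], but membership is decided by the spindle's
#' start time in the 3.4-s ON window after S1 (or the mirror OFF window).
#'
#' @param events Spindle event tibble (Cz).
#' @param s1_onsets Eligible S1 onsets.
#' @param windows A [window_spec()].
#' @return Tibble with one row per window: `count`, `n_stimuli`,
#'   `likelihood`.
#' @export
spindle_likelihood <- function(events, s1_onsets, windows = window_spec()) {
  if (!length(s1_onsets)) {
    abort("Insufficient data: no eligible stimuli.")
  }
  starts <- events$onset
  tibble(
    window = c("on", "off"),
    count = c(count_in_windows(starts, s1_onsets, windows$sp_on),
              count_in_windows(starts, s1_onsets, windows$sp_off)),
    n_stimuli = length(s1_onsets)) |>
    dplyr::mutate(likelihood = .data$count / .data$n_stimuli)
}

#' @export
autoplot.nap_erp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from S1 onset (s)",
                  y = expression(Amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
}

#' Plot a stimulus-locked peak-latency histogram
#'
#' @param hist Output of [peak_latency_histogram()].
#' @param highlight Window to shade (default the K-complex ON window).
#' @return A ggplot object.
#' @export
plot_latency_histogram <- function(hist, highlight = window_spec()$kc_on) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::annotate("rect", xmin = highlight[1], xmax = highlight[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "blue") +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~tone, ncol = 1) +
    ggplot2::labs(x = "Negative-peak latency from tone onset (s)",
                  y = "Count") +
    ggplot2::theme_minimal()
}
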