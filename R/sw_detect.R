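#' Slow-wave detection parameters
#'
#' Infant-adapted criteria for discrete slow-wave events: the signal is
#' band-passed to 0.5-2 Hz and candidate events are a negative half-wave
#' followed by a positive half-wave between consecutive zero crossings. A
#' candidate is accepted when the negative half-wave lasts 0.3-1.5 s, the
#' positive half-wave 0.1-1 s, the negative peak exceeds 40 uV in magnitude,
#' the positive peak exceeds 10 uV and the peak-to-peak amplitude exceeds
#' 75 uV. There are no upper amplitude limits (infant slow waves are larger
#' than adults'). Amplitudes are measured on the band-passed signal.
#'
#' @param band Frequency band in Hz.
#' @param neg_dur,pos_dur Allowed negative/positive half-wave durations (s).
#' @param min_neg_amp,min_pos_amp,min_ptp Amplitude thresholds in uV
#'   (strict `>`).
#' @param filter_order Butterworth order for the band-pass (zero-phase).
#' @return A list of class `sw_params`.
#' @export
sw_params <- function(band = c(0.5, 2), neg_dur = c(0.3, 1.5),
                      pos_dur = c(0.1, 1), min_neg_amp = 40,
                      min_pos_amp = 10, min_ptp = 75, filter_order = 2) {
  stopifnot(band[1] > 0, band[2] > band[1],
            all(c(neg_dur, pos_dur) > 0),
            min_neg_amp > 0, min_pos_amp > 0, min_ptp > 0)
  structure(list(band = band, neg_dur = neg_dur, pos_dur = pos_dur,
                 min_neg_amp = min_neg_amp, min_pos_amp = min_pos_amp,
                 min_ptp = min_ptp, filter_order = filter_order),
            class = "sw_params")
}

#' Detect slow waves on one channel
#'
#' Event onset is the negative-going zero crossing, offset the end of the
#' positive half-wave; `neg_peak_time` is the minimum within the negative
#' half-wave. Candidates that touch an ineligible sample are discarded
#' rather than clipped.
#'
#' @param x One-channel signal in uV (linked-mastoid referenced).
#' @param fs Sampling rate in Hz.
#' @param params A [sw_params()].
#' @param eligible Logical per-sample mask of artifact-free N2/N3 samples
#'   (default: all eligible). Must have the same length as `x`.
#' @param channel,stage Labels recorded on the output rows.
#' @return An [event_table()] of `slow_wave` events.
#' @export
detect_slow_waves <- function(x, fs, params = sw_params(), eligible = NULL,
                              channel = NA_character_, stage = NA_character_) {
  if (is.null(eligible)) eligible <- rep(TRUE, length(x))
  if (length(eligible) != length(x)) {
    abort("`eligible` mask must have the same length as the signal.")
  }
  xf <- butter_filtfilt(x, fs, params$band[1], params$band[2],
                        params$filter_order)
  neg <- xf < 0
  # crossing indices: i such that sign changes between i-1 and i
  down <- which(!neg[-length(neg)] & neg[-1]) + 1L  # + -> -
  up <- which(neg[-length(neg)] & !neg[-1]) + 1L    # - -> +
  rows <- list()
  for (d in down) {
    u <- up[up > d]
    if (!length(u)) break
    u <- u[1]
    d2 <- down[down > u]
    if (!length(d2)) break
    d2 <- d2[1]
    neg_dur <- (u - d) / fs
    pos_dur <- (d2 - u) / fs
    if (neg_dur < params$neg_dur[1] || neg_dur > params$neg_dur[2]) next
    if (pos_dur < params$pos_dur[1] || pos_dur > params$pos_dur[2]) next
    i_neg <- d - 1L + which.min(xf[d:(u - 1L)])
    i_pos <- u - 1L + which.max(xf[u:(d2 - 1L)])
    neg_amp <- xf[i_neg]
    pos_amp <- xf[i_pos]
    if (-neg_amp <= params$min_neg_amp) next
    if (pos_amp <= params$min_pos_amp) next
    if (pos_amp - neg_amp <= params$min_ptp) next
    if (!all(eligible[d:(d2 - 1L)])) next
    rows[[length(rows) + 1L]] <- tibble(
      type = "slow_wave", channel = channel,
      onset = (d - 1L) / fs, offset = (d2 - 1L) / fs,
      neg_peak_time = (i_neg - 1L) / fs,
      neg_peak_amp = neg_amp, pos_peak_amp = pos_amp, stage = stage)
  }
  if (!length(rows)) return(event_table())
  validate_events(dplyr::bind_rows(rows))
}

#' Slow-wave density across a region of interest
#'
#' Per-channel event count divided by artifact-free N2+N3 minutes, then the
#' median across the ROI.
#'
#' @param events Event tibble containing `slow_wave` rows with a `channel`
#'   column covering the ROI.
#' @param eligible_seconds Artifact-free N2+N3 seconds (> 0).
#' @param roi Channels to aggregate over.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return A list with `density` (events/min, one value per nap) and
#'   `per_channel` (tibble).
#' @export
sw_density <- function(events, eligible_seconds, roi = roi_channels("swa"),
                       aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (eligible_seconds <= 0) {
    abort("Insufficient data: zero eligible N2+N3 time.")
  }
  counts <- vapply(roi, function(ch) {
    sum(events$type == "slow_wave" & events$channel == ch)
  }, numeric(1))
  dens <- counts / (eligible_seconds / 60)
  list(density = if (aggregate == "median") median(dens) else mean(dens),
       per_channel = tibble(channel = roi, count = counts, density = dens))
}
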