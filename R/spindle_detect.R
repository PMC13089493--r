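#' Spindle detection parameters
#'
#' Three-feature sigma-band detector adapted for infant naps: a wide sigma
#' band (9-16 Hz), durations 0.5-4 s, a 750-ms minimum distance between
#' spindles (closer events are merged), and soft thresholds on three moving
#' features: the sigma-band RMS (in SD units above its mean over eligible
#' sleep), the moving broadband-sigma correlation, and the relative sigma
#' power from a short-time spectrum. A sample votes for "spindle" when a
#' feature is above threshold; the summed votes are smoothed over 0.1 s and
#' candidate events are maximal runs with at least 2 of 3 votes.
#'
#' The adjusted thresholds are 85%, 80% and 65% of the detector family's
#' defaults (1.5, 0.65, 0.2), i.e. 1.275, 0.52 and 0.13.
#'
#' @param sigma_band Sigma band in Hz.
#' @param dur_range Allowed event durations in seconds.
#' @param min_gap Minimum distance between spindles in seconds; closer
#'   events are merged.
#' @param thr_rms RMS threshold in SD units above the mean of the moving
#'   RMS over eligible sleep.
#' @param thr_corr Moving-correlation threshold.
#' @param thr_relpow Relative sigma power threshold.
#' @param rms_win,corr_win Moving-window lengths in seconds.
#' @param stft_win,stft_step Short-time spectrum window and step in seconds.
#' @param smooth_win Vote-smoothing window in seconds.
#' @param votes_required Votes needed (2 of 3 by default).
#' @param broad_band Broadband range for the moving correlation and the
#'   relative-power denominator (the preprocessed band).
#' @return A list of class `spindle_params`.
#' @export
spindle_params <- function(sigma_band = c(9, 16), dur_range = c(0.5, 4),
                           min_gap = 0.75, thr_rms = 1.275, thr_corr = 0.52,
                           thr_relpow = 0.13, rms_win = 0.3, corr_win = 0.3,
                           stft_win = 2, stft_step = 0.2, smooth_win = 0.1,
                           votes_required = 2, broad_band = c(0.2, 40)) {
  stopifnot(dur_range[1] < dur_range[2], thr_rms >= 0, thr_corr >= 0,
            thr_relpow >= 0, votes_required %in% 1:3)
  structure(list(sigma_band = sigma_band, dur_range = dur_range,
                 min_gap = min_gap, thr_rms = thr_rms, thr_corr = thr_corr,
                 thr_relpow = thr_relpow, rms_win = rms_win,
                 corr_win = corr_win, stft_win = stft_win,
                 stft_step = stft_step, smooth_win = smooth_win,
                 votes_required = votes_required, broad_band = broad_band),
            class = "spindle_params")
}

#' Detector-family default thresholds
#'
#' The unadjusted thresholds of the detector family (RMS 1.5 SD,
#' correlation 0.65, relative power 0.2).
#' @return A [spindle_params()] with default thresholds.
#' @export
spindle_params_default <- function() {
  spindle_params(thr_rms = 1.5, thr_corr = 0.65, thr_relpow = 0.2)
}

moving_mean <- function(x, win) {
  # centered moving average via cumulative sums, O(n)
  n <- length(x)
  half <- floor(win / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

moving_corr <- function(x, y, win) {
  mx <- moving_mean(x, win); my <- moving_mean(y, win)
  mxy <- moving_mean(x * y, win)
  mxx <- moving_mean(x * x, win)
  myy <- moving_mean(y * y, win)
  num <- mxy - mx * my
  den <- sqrt(pmax(mxx - mx^2, 0) * pmax(myy - my^2, 0))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Sigma-band spindle features
#'
#' Computes the three detection features on a common per-sample time grid:
#' the moving RMS of the sigma-filtered signal, the moving correlation
#' between the broadband and sigma-filtered signal, and the relative sigma
#' power (sigma / broadband) from a Hann short-time spectrum interpolated to
#' the sample grid.
#'
#' @param x One-channel broadband (preprocessed) signal in uV.
#' @param fs Sampling rate in Hz.
#' @param params A [spindle_params()].
#' @return Tibble with columns `time`, `rms`, `corr`, `relpow`.
#' @export
sigma_features <- function(x, fs, params = spindle_params()) {
  n <- length(x)
  if (n < round(params$stft_win * fs)) {
    abort("Insufficient data: signal shorter than the short-time window.")
  }
  sig <- butter_filtfilt(x, fs, params$sigma_band[1], params$sigma_band[2], 4)
  wr <- max(3L, round(params$rms_win * fs))
  wc <- max(3L, round(params$corr_win * fs))
  rms <- sqrt(pmax(moving_mean(sig^2, wr), 0))
  rr <- moving_corr(x, sig, wc)

  nwin <- round(params$stft_win * fs)
  step <- max(1L, round(params$stft_step * fs))
  w <- hann_window(nwin)
  starts <- seq(1L, n - nwin + 1L, by = step)
  freqs <- seq(0, by = 1 / params$stft_win, length.out = floor(nwin / 2) + 1L)
  in_sigma <- freqs >= params$sigma_band[1] & freqs <= params$sigma_band[2]
  in_broad <- freqs >= params$broad_band[1] &
    freqs <= min(params$broad_band[2], fs / 2)
  rel <- vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1L)]
    p <- Mod(fft((seg - mean(seg)) * w))^2
    p <- p[seq_along(freqs)]
    tot <- sum(p[in_broad])
    if (tot <= 0) 0 else sum(p[in_sigma]) / tot
  }, numeric(1))
  t_rel <- (starts - 1L + nwin / 2) / fs
  t_all <- (seq_len(n) - 1L) / fs
  relpow <- approx(t_rel, rel, xout = t_all, rule = 2)$y
  out <- tibble(time = t_all, rms = rms, corr = rr,
                relpow = pmin(pmax(relpow, 0), 1))
  # short-window sigma envelope, used for event boundary refinement
  attr(out, "envelope") <-
    sqrt(pmax(moving_mean(sig^2, max(3L, round(0.05 * fs))), 0))
  out
}

#' Detect sleep spindles on one channel
#'
#' Applies the three soft thresholds to [sigma_features()], smooths the vote
#' count over 0.1 s, takes maximal runs with at least `votes_required`
#' votes, merges events closer than `min_gap`, discards events with a
#' duration outside `dur_range`, and keeps only events lying fully inside
#' eligible runs. The RMS threshold is `mean + thr_rms * SD` of the moving
#' RMS computed over eligible samples.
#'
#' @inheritParams sigma_features
#' @param eligible Logical per-sample mask (artifact-free N2 by default
#'   usage); `NULL` means all samples.
#' @param channel,stage Labels for the output rows.
#' @param features Optional precomputed [sigma_features()] tibble (used by
#'   the threshold grid search to avoid recomputation).
#' @return An [event_table()] of `spindle` events.
#' @export
detect_spindles <- function(x, fs, params = spindle_params(),
                            eligible = NULL, channel = NA_character_,
                            stage = NA_character_, features = NULL) {
  if (is.null(features)) features <- sigma_features(x, fs, params)
  n <- nrow(features)
  if (is.null(attr(features, "envelope"))) {
    sig <- butter_filtfilt(x, fs, params$sigma_band[1],
                           params$sigma_band[2], 4)
    attr(features, "envelope") <-
      sqrt(pmax(moving_mean(sig^2, max(3L, round(0.05 * fs))), 0))
  }
  env <- attr(features, "envelope")
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  if (length(eligible) != n) {
    abort("`eligible` mask must have the same length as the signal.")
  }
  if (!any(eligible)) return(event_table())
  mu <- mean(features$rms[eligible])
  s <- sd(features$rms[eligible])
  thr_abs <- mu + params$thr_rms * (if (is.na(s)) 0 else s)
  raw_votes <- (features$rms > thr_abs) + (features$corr > params$thr_corr) +
    (features$relpow > params$thr_relpow)
  votes <- moving_mean(raw_votes, max(1L, round(params$smooth_win * fs)))
  active <- votes >= params$votes_required
  runs <- mask_runs(active)
  if (!nrow(runs)) return(event_table())
  # merge runs separated by less than min_gap
  gap <- params$min_gap * fs
  merged <- list(c(runs$start[1], runs$end[1]))
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (runs$start[i] - last[2] - 1L < gap) {
      merged[[length(merged)]][2] <- runs$end[i]
    } else {
      merged[[length(merged) + 1L]] <- c(runs$start[i], runs$end[i])
    }
  }
  # moving-window features smear an event's edges by about half a feature
  # window; candidate boundaries are therefore refined to the extent of the
  # short-window sigma envelope, so the duration rule sees the burst itself
  env_thr <- mu + 0.5 * params$thr_rms * (if (is.na(s)) 0 else s)
  rows <- list()
  for (m in merged) {
    hot <- which(env[m[1]:m[2]] > env_thr)
    if (!length(hot)) next
    m <- c(m[1] + hot[1] - 1L, m[1] + hot[length(hot)] - 1L)
    dur <- (m[2] - m[1] + 1L) / fs
    if (dur < params$dur_range[1] || dur > params$dur_range[2]) next
    if (!all(eligible[m[1]:m[2]])) next
    rows[[length(rows) + 1L]] <- tibble(
      type = "spindle", channel = channel,
      onset = (m[1] - 1L) / fs, offset = m[2] / fs,
      neg_peak_time = NA_real_, neg_peak_amp = NA_real_,
      pos_peak_amp = max(features$rms[m[1]:m[2]]), stage = stage)
  }
  if (!length(rows)) return(event_table())
  validate_events(dplyr::bind_rows(rows))
}

#' Spindle density across the ROI
#'
#' Per-channel spindle count divided by artifact-free N2 minutes, aggregated
#' across the eight-channel ROI (median by default; mean available since the
#' aggregation convention is not uniquely determined for this measure).
#'
#' @param events Event tibble with `spindle` rows.
#' @param n2_seconds Artifact-free N2 seconds (> 0).
#' @param roi Channels to aggregate over.
#' @param aggregate `"median"` or `"mean"`.
#' @return A list with `density` and `per_channel`.
#' @export
spindle_density <- function(events, n2_seconds, roi = roi_channels("sigma"),
                            aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (n2_seconds <= 0) abort("Insufficient data: zero eligible N2 time.")
  counts <- vapply(roi, function(ch) {
    sum(events$type == "spindle" & events$channel == ch)
  }, numeric(1))
  dens <- counts / (n2_seconds / 60)
  list(density = if (aggregate == "median") median(dens) else mean(dens),
       per_channel = tibble(channel = roi, count = counts, density = dens))
}
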