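# Independent oracles and small fixture builders used across the suite.

# Analytic magnitude response of an order-1 Butterworth band-pass
# (|H(jw)|^2 = 1 / (1 + ((f^2 - fl*fh) / ((fh - fl) f))^2)), giving the
# expected RMS ratio of the forward-backward (two-pass) application.
butter1_bp_gain2 <- function(f, low, high) {
  x <- (f^2 - low * high) / ((high - low) * f)
  1 / (1 + x^2)
}

# Exhaustive slow-wave enumerator: applies the five printed criteria to
# every negative-then-positive half-wave pair of the band-passed signal.
# Deliberately written as a flat scan over sign changes, independent of the
# detector's control flow.
oracle_slow_waves <- function(x, fs, params = sw_params(), eligible = NULL) {
  if (is.null(eligible)) eligible <- rep(TRUE, length(x))
  bf <- signal::butter(params$filter_order,
                       params$band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  s <- xf >= 0
  # all indices where the sign flips; classify each flip
  flips <- which(s[-1] != s[-length(s)]) + 1L
  out <- list()
  if (length(flips) >= 3) {
    for (k in seq_len(length(flips) - 2L)) {
      a <- flips[k]; b <- flips[k + 1L]; cc <- flips[k + 2L]
      if (s[a]) next                     # need + -> - first
      neg_dur <- (b - a) / fs
      pos_dur <- (cc - b) / fs
      if (neg_dur < params$neg_dur[1] || neg_dur > params$neg_dur[2]) next
      if (pos_dur < params$pos_dur[1] || pos_dur > params$pos_dur[2]) next
      neg_amp <- min(xf[a:(b - 1L)])
      pos_amp <- max(xf[b:(cc - 1L)])
      if (!(-neg_amp > params$min_neg_amp)) next
      if (!(pos_amp > params$min_pos_amp)) next
      if (!(pos_amp - neg_amp > params$min_ptp)) next
      if (!all(eligible[a:(cc - 1L)])) next
      out[[length(out) + 1L]] <- c(onset = (a - 1L) / fs,
                                   offset = (cc - 1L) / fs)
    }
  }
  if (!length(out)) {
    return(data.frame(onset = numeric(), offset = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Signal with planted slow-wave templates at known spots in 1/f noise,
# amplitudes straddling the acceptance thresholds.
make_sw_test_signal <- function(fs, dur_s, seed) {
  set.seed(seed)
  n <- dur_s * fs
  x <- napscape:::one_over_f_noise(n, 2, fs = fs) * 25
  k <- sample(3:6, 1)
  onsets <- sort(runif(k, 2, dur_s - 3))
  onsets <- onsets[c(TRUE, diff(onsets) > 2.5)]
  for (t0 in onsets) {
    w <- napscape:::sw_template(fs, runif(1, 0.25, 1.0), runif(1, 0.1, 0.8),
                                runif(1, 30, 150), runif(1, 8, 60))
    i0 <- round(t0 * fs) + 1L
    x[i0:(i0 + length(w) - 1L)] <- x[i0:(i0 + length(w) - 1L)] + w
  }
  x
}

# Single-channel spindle nap for detector-evaluation tests: returns the
# preprocessed C4 signal, the eligible N2 mask and the recoverable ground
# truth (planted spindles fully inside the eligible mask). Advances the
# seed until the nap contains at least `min_events` recoverable spindles.
make_spindle_nap <- function(seed, minutes = 5, snr = 3, min_events = 1) {
  for (s in seed + 1000L * (0:19)) {
    nap <- make_spindle_nap_once(s, minutes, snr)
    if (nrow(nap$annotations) >= min_events) return(nap)
  }
  stop("no spindle-bearing nap found")
}

make_spindle_nap_once <- function(seed, minutes, snr) {
  spec <- cohort_spec(nap_minutes = minutes, channels = "C4",
                      spindle_snr = snr)
  nap <- simulate_nap(spec, condition = "baseline", seed = seed)
  rec <- suppressMessages(bandpass(nap$recording))
  rec <- rereference(rec)
  m2 <- eligible_mask(nap$hypnogram, rec$fs, n_samples(rec), "N2")
  gt <- nap$events[nap$events$type == "spindle", ]
  keep <- vapply(seq_len(nrow(gt)), function(i) {
    i0 <- round(gt$onset[i] * rec$fs) + 1L
    i1 <- round(gt$offset[i] * rec$fs)
    i1 <= length(m2) && all(m2[i0:i1])
  }, logical(1))
  list(x = rec$data[, "C4"], fs = rec$fs, eligible = m2,
       annotations = gt[keep, ], channel = "C4")
}

quiet_bandpass <- function(rec, spec = filter_spec()) {
  suppressMessages(bandpass(rec, spec))
}
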