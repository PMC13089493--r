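#' Event tables
#'
#' Detected or annotated events (spindles, slow waves, K-complexes counted as
#' slow waves, artifacts, arousals, manual spindle annotations) live in a
#' plain tibble with one row per event. Times are seconds from recording
#' start; intervals are half-open `[onset, offset)`.
#'
#' @param type Event type: one of `"spindle"`, `"slow_wave"`, `"artifact"`,
#'   `"arousal"`, `"manual_spindle"`.
#' @param channel Channel label.
#' @param onset,offset Event boundaries in seconds (`onset < offset`).
#' @param neg_peak_time Time of the negative peak in seconds (`NA` if not
#'   applicable); must lie inside `[onset, offset]` when present.
#' @param neg_peak_amp,pos_peak_amp Peak amplitudes in microvolts.
#' @param stage Stage code at the event, or `NA`.
#' @return A tibble of class `nap_events`.
#' @export
#' @examples
#' event_table(type = "spindle", channel = "C4", onset = 10, offset = 11.2)
event_table <- function(type = character(), channel = character(),
                        onset = numeric(), offset = numeric(),
                        neg_peak_time = NA_real_, neg_peak_amp = NA_real_,
                        pos_peak_amp = NA_real_, stage = NA_character_) {
  tb <- tibble(type = as.character(type), channel = as.character(channel),
               onset = as.numeric(onset), offset = as.numeric(offset),
               neg_peak_time = as.numeric(neg_peak_time),
               neg_peak_amp = as.numeric(neg_peak_amp),
               pos_peak_amp = as.numeric(pos_peak_amp),
               stage = as.character(stage))
  validate_events(tb)
}

event_types <- function() {
  c("spindle", "slow_wave", "artifact", "arousal", "manual_spindle")
}

#' @rdname event_table
#' @param events A data frame of events to validate.
#' @export
validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("type", "channel", "onset", "offset", "neg_peak_time",
            "neg_peak_amp", "pos_peak_amp", "stage")
  for (col in setdiff(need, names(events))) events[[col]] <- NA
  events <- events[need]
  if (nrow(events)) {
    bad_type <- !events$type %in% event_types()
    if (any(bad_type)) {
      abort(sprintf("Unknown event type: %s",
                    paste(unique(events$type[bad_type]), collapse = ", ")))
    }
    if (any(events$onset >= events$offset)) {
      abort("Every event must satisfy onset < offset.")
    }
    pt <- events$neg_peak_time
    in_range <- is.na(pt) | (pt >= events$onset & pt <= events$offset)
    if (!all(in_range)) {
      abort("neg_peak_time must lie within [onset, offset] when present.")
    }
  }
  class(events) <- unique(c("nap_events", class(events)))
  events
}

#' Read / write event tables as CSV
#'
#' Lossless round trip of all [event_table()] fields; times are written with
#' sub-millisecond precision.
#'
#' @param events An event tibble.
#' @param path CSV file path.
#' @return For `read_events()`, a validated event tibble.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          type = "c", channel = "c", onset = "d",
                          offset = "d", neg_peak_time = "d",
                          neg_peak_amp = "d", pos_peak_amp = "d",
                          stage = "c"))
  validate_events(tb)
}

## ---- stimulus trains -------------------------------------------------------

#' Paired-tone stimulus train
#'
#' Tone pairs (S1 then S2) as used in the auditory stimulation condition:
#' two 1-s tones separated by a 700-ms gap, with the interval between pairs
#' drawn uniformly from 12-18 s.
#'
#' @param s1_onset,s2_onset Onset times of the first and second tone of each
#'   pair, seconds. Must satisfy `s2 = s1 + tone_duration + intra_pair_gap`.
#' @param tone_duration Tone length in seconds (default 1).
#' @param intra_pair_gap Within-pair silent gap in seconds (default 0.7).
#' @param inter_pair_range Range of the random between-pair interval
#'   (default `c(12, 18)` s, measured from S2 offset to the next S1 onset).
#' @param tone_hz,level_db Tone frequency (225 Hz) and level (60 dBA).
#' @return A tibble of class `nap_stimuli` with columns `pair`, `s1_onset`,
#'   `s2_onset` and the train parameters as attributes.
#' @export
stimulus_train <- function(s1_onset, s2_onset, tone_duration = 1,
                           intra_pair_gap = 0.7,
                           inter_pair_range = c(12, 18),
                           tone_hz = 225, level_db = 60) {
  if (length(s1_onset) != length(s2_onset)) {
    abort("s1_onset and s2_onset must have equal length.")
  }
  if (length(s1_onset)) {
    gap <- s2_onset - s1_onset
    if (any(abs(gap - (tone_duration + intra_pair_gap)) > 1e-9)) {
      abort("Every pair must satisfy s2 = s1 + tone_duration + intra_pair_gap.")
    }
    if (is.unsorted(s1_onset, strictly = TRUE) && length(s1_onset) > 1) {
      abort("S1 onsets must be strictly increasing.")
    }
  }
  tb <- tibble(pair = seq_along(s1_onset),
               s1_onset = as.numeric(s1_onset),
               s2_onset = as.numeric(s2_onset))
  attr(tb, "tone_duration") <- tone_duration
  attr(tb, "intra_pair_gap") <- intra_pair_gap
  attr(tb, "inter_pair_range") <- inter_pair_range
  attr(tb, "tone_hz") <- tone_hz
  attr(tb, "level_db") <- level_db
  class(tb) <- unique(c("nap_stimuli", class(tb)))
  tb
}

#' Generate a random paired-tone stimulus train
#'
#' Pairs of 1-s tones with a 700-ms intra-pair gap; the silent interval
#' between the end of one pair and the next S1 is i.i.d. uniform on
#' `inter_pair_range`. Deterministic given `seed`.
#'
#' @param total_s Total duration to fill with pairs (must exceed 20 s).
#' @param seed Optional integer seed.
#' @param start_s Earliest S1 onset (default 0).
#' @inheritParams stimulus_train
#' @return A [stimulus_train()] tibble.
#' @export
generate_stimulus_train <- function(total_s, seed = NULL, start_s = 0,
                                    tone_duration = 1, intra_pair_gap = 0.7,
                                    inter_pair_range = c(12, 18)) {
  if (!is.numeric(total_s) || total_s <= 20) {
    abort("`total_s` must be a duration greater than 20 s.")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  span <- 2 * tone_duration + intra_pair_gap  # S1 onset -> S2 offset
  s1 <- numeric(0)
  t <- start_s
  repeat {
    if (t + span > total_s) break
    s1 <- c(s1, t)
    t <- t + span + runif(1, inter_pair_range[1], inter_pair_range[2])
  }
  stimulus_train(s1, s1 + tone_duration + intra_pair_gap,
                 tone_duration = tone_duration,
                 intra_pair_gap = intra_pair_gap,
                 inter_pair_range = inter_pair_range)
}

#' Read / write stimulus trains as CSV
#'
#' @param train A [stimulus_train()] tibble.
#' @param path CSV path.
#' @return For `read_stimuli()`, a [stimulus_train()] tibble.
#' @export
write_stimuli <- function(train, path) {
  meta <- tibble(
    pair = train$pair, s1_onset = train$s1_onset, s2_onset = train$s2_onset,
    tone_duration = attr(train, "tone_duration"),
    intra_pair_gap = attr(train, "intra_pair_gap"),
    inter_min = attr(train, "inter_pair_range")[1],
    inter_max = attr(train, "inter_pair_range")[2],
    tone_hz = attr(train, "tone_hz"), level_db = attr(train, "level_db"))
  readr::write_csv(meta, path)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stimulus_train(tb$s1_onset, tb$s2_onset,
                 tone_duration = tb$tone_duration[1] %||% 1,
                 intra_pair_gap = tb$intra_pair_gap[1] %||% 0.7,
                 inter_pair_range = c(tb$inter_min[1] %||% 12,
                                      tb$inter_max[1] %||% 18),
                 tone_hz = tb$tone_hz[1] %||% 225,
                 level_db = tb$level_db[1] %||% 60)
}
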