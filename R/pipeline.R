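#' Pipeline configuration
#'
#' Bundles every stage's parameters with the printed defaults: 0.2-40 Hz
#' first-order Butterworth band-pass, linked-mastoid reference, 1-s
#' artifact windows at z = 3, the slow-wave and spindle criteria, the
#' stimulus window geometry, and the detection channels (Cz for slow
#' waves/K-complexes, C4 for spindle-annotation comparisons).
#'
#' @param filter A [filter_spec()].
#' @param sw A [sw_params()].
#' @param spindle A [spindle_params()].
#' @param windows A [window_spec()].
#' @param artifact_z Artifact threshold in SD units.
#' @param bad_channels Channels flagged bad (input metadata).
#' @param sw_channel,spindle_channel Single-channel detection channels for
#'   the stimulus-locked analyses.
#' @param detect_artifacts Whether to run automatic artifact detection and
#'   combine it with the hypnogram's mask.
#' @return A list of class `nap_config`.
#' @export
nap_config <- function(filter = filter_spec(), sw = sw_params(),
                       spindle = spindle_params(), windows = window_spec(),
                       artifact_z = 3, bad_channels = character(),
                       sw_channel = "Cz", spindle_channel = "Cz",
                       detect_artifacts = TRUE) {
  structure(list(filter = filter, sw = sw, spindle = spindle,
                 windows = windows, artifact_z = artifact_z,
                 bad_channels = bad_channels, sw_channel = sw_channel,
                 spindle_channel = spindle_channel,
                 detect_artifacts = detect_artifacts),
            class = "nap_config")
}

#' Run the full per-nap pipeline
#'
#' Preprocesses (band-pass, linked-mastoid re-reference, artifact mask),
#' computes slow-wave activity and sigma power, detects slow waves and
#' spindles over their ROIs, summarises macroarchitecture and arousal
#' density, and - when a stimulus train is present - the stimulus-locked
#' ON/OFF likelihoods. Deterministic given inputs and config.
#'
#' @param rec A [nap_recording()].
#' @param hyp A [nap_hypnogram()].
#' @param train Optional [stimulus_train()] (stimulation naps).
#' @param config A [nap_config()].
#' @return A one-row tibble of nap features (class `nap_features`), with
#'   detected event tables in list-columns `sw_events`, `spindle_events`.
#' @export
run_nap <- function(rec, hyp, train = NULL, config = nap_config()) {
  rec <- bandpass(rec, config$filter)
  rec <- rereference(rec, "linked_mastoids",
                     bad_channels = config$bad_channels)
  amask <- hyp$artifact_mask
  if (config$detect_artifacts) {
    auto <- detect_artifacts(rec, hyp, z_thresh = config$artifact_z)
    len <- max(length(amask), length(auto))
    pad <- function(m) c(m, rep(FALSE, len - length(m)))
    amask <- pad(amask) | pad(auto)
  }
  fs <- rec$fs
  n <- n_samples(rec)

  swa <- roi_band_power(rec, hyp, band = c(0.5, 2), stages = c("N2", "N3"),
                        roi = intersect(roi_channels("swa"), rec$channels),
                        artifact_mask = amask)
  sigma <- roi_band_power(rec, hyp, band = c(9, 16), stages = "N2",
                          roi = intersect(roi_channels("sigma"),
                                          rec$channels),
                          artifact_mask = amask)

  m_n2n3 <- eligible_mask(hyp, fs, n, c("N2", "N3"), artifact_mask = amask)
  m_n2 <- eligible_mask(hyp, fs, n, "N2", artifact_mask = amask)

  roi_sw <- intersect(roi_channels("swa"), rec$channels)
  sw_events <- dplyr::bind_rows(lapply(roi_sw, function(ch) {
    detect_slow_waves(rec$data[, ch], fs, config$sw, eligible = m_n2n3,
                      channel = ch)
  }))
  swd <- sw_density(sw_events, sum(m_n2n3) / fs, roi = roi_sw)

  roi_sp <- intersect(roi_channels("sigma"), rec$channels)
  sp_events <- dplyr::bind_rows(lapply(roi_sp, function(ch) {
    detect_spindles(rec$data[, ch], fs, config$spindle, eligible = m_n2,
                    channel = ch)
  }))
  spd <- spindle_density(sp_events, sum(m_n2) / fs, roi = roi_sp)

  macro <- macro_summary(hyp)
  adens <- tryCatch(arousal_density(hyp), error = function(e) NA_real_)

  out <- dplyr::bind_cols(
    tibble(subject = rec$meta$subject %||% NA_character_,
           condition = rec$meta$condition %||% NA_character_,
           swa = swa$roi_value, sigma = sigma$roi_value,
           sw_density = swd$density, spindle_density = spd$density,
           arousal_density = adens),
    macro)

  if (!is.null(train) && nrow(train)) {
    w <- config$windows
    s1_kc <- select_eligible_stimuli(train, hyp, fs, n,
                                     segment = w$kc_segment,
                                     artifact_mask = amask)
    s1_sp <- select_eligible_stimuli(train, hyp, fs, n,
                                     segment = w$sp_segment,
                                     artifact_mask = amask)
    sw_cz <- detect_slow_waves(rec$data[, config$sw_channel], fs, config$sw,
                               eligible = m_n2, channel = config$sw_channel)
    sp_cz <- detect_spindles(rec$data[, config$spindle_channel], fs,
                             config$spindle, eligible = m_n2,
                             channel = config$spindle_channel)
    kc <- if (length(s1_kc)) kcomplex_likelihood(sw_cz, s1_kc, w) else NULL
    sp <- if (length(s1_sp)) spindle_likelihood(sp_cz, s1_sp, w) else NULL
    out$kc_likelihood_on <- if (is.null(kc)) NA_real_ else {
      kc$likelihood[kc$window == "on"]
    }
    out$kc_likelihood_off <- if (is.null(kc)) NA_real_ else {
      kc$likelihood[kc$window == "off"]
    }
    out$sp_likelihood_on <- if (is.null(sp)) NA_real_ else {
      sp$likelihood[sp$window == "on"]
    }
    out$sp_likelihood_off <- if (is.null(sp)) NA_real_ else {
      sp$likelihood[sp$window == "off"]
    }
    out$n_stimuli_kc <- length(s1_kc)
    out$n_stimuli_sp <- length(s1_sp)
  }
  out$sw_events <- list(sw_events)
  out$spindle_events <- list(sp_events)
  class(out) <- unique(c("nap_features", class(out)))
  out
}

#' Run a study: per-nap features, descriptives and models
#'
#' Maps [run_nap()] over a cohort, records exclusions (bad mastoids,
#' premature waking, insufficient data) with machine-readable reason
#' codes, joins subject covariates, Winsorizes each outcome at 4 SD, and
#' produces per-condition descriptives plus mixed-model report tables for
#' the requested outcomes. Naps flagged as prematurely ended are excluded
#' from the nap-duration analysis only.
#'
#' @param naps List of naps; each element a list with `recording`,
#'   `hypnogram`, optional `train`, optional logical `premature_wake`.
#' @param subjects Tibble with `subject`, `reactivity`, `sex`, `age`
#'   columns (plus optional `autism_likelihood`, `sleep_arrangement`).
#' @param config A [nap_config()].
#' @param outcomes Outcome columns to model.
#' @return A list with `features`, `descriptives`, `models` (named list of
#'   [lmm_report()] tibbles or skip reasons), `exclusions`.
#' @export
run_study <- function(naps, subjects, config = nap_config(),
                      outcomes = c("swa", "sw_density", "sigma",
                                   "spindle_density", "nap_min")) {
  if (length(naps) < 2) abort("Need at least two naps.")
  feats <- list()
  excl <- list()
  for (k in seq_along(naps)) {
    nap <- naps[[k]]
    res <- tryCatch(
      run_nap(nap$recording, nap$hypnogram, nap$train, config),
      napscape_exclusion = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      code <- if (inherits(res, "napscape_exclusion")) {
        "bad_mastoid"
      } else "stage_error"
      subj <- nap$recording$meta$subject %||% NA_character_
      excl[[length(excl) + 1L]] <- tibble(
        nap_index = k, subject = subj, reason = code,
        message = conditionMessage(res))
      next
    }
    res$premature_wake <- isTRUE(nap$premature_wake)
    feats[[length(feats) + 1L]] <- res
  }
  if (!length(feats)) abort("All naps were excluded.")
  features <- dplyr::bind_rows(feats) |>
    dplyr::select(-dplyr::any_of(c("sw_events", "spindle_events")))
  features <- dplyr::left_join(features, subjects, by = "subject")
  features$stimulation <- as.numeric(features$condition == "stimulation")
  features$age <- features$age %||% features$age_days

  for (out in intersect(outcomes, names(features))) {
    keep <- !is.na(features[[out]])
    if (sum(keep) >= 3) {
      features[[out]][keep] <- winsorize(features[[out]][keep])$values
    }
  }

  descriptives <- features |>
    tidyr::pivot_longer(dplyr::any_of(c(outcomes, "sol_min", "waso_min",
                                        "efficiency_pct",
                                        "arousal_density")),
                        names_to = "measure") |>
    dplyr::group_by(.data$condition, .data$measure) |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     .groups = "drop")

  models <- list()
  both_cond <- length(unique(features$condition)) == 2
  for (out in outcomes) {
    dat <- features
    if (out == "nap_min") dat <- dat[!dat$premature_wake, ]
    models[[out]] <- if (!both_cond) {
      "skipped: only one condition present"
    } else if (!out %in% names(dat) || all(is.na(dat[[out]]))) {
      "skipped: outcome unavailable"
    } else {
      tryCatch(lmm_report(dat, out), error = function(e) {
        sprintf("skipped: %s", conditionMessage(e))
      })
    }
  }
  list(features = features, descriptives = descriptives, models = models,
       exclusions = dplyr::bind_rows(excl))
}
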