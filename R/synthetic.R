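#' Cohort specification for synthetic nap polysomnography
#'
#' Defines the study conditions the generator emulates: a cohort of infants
#' seen in two counterbalanced nap visits (baseline and auditory
#' stimulation), 500-Hz multichannel EEG with 1/f background and
#' stage-dependent amplitude, embedded sleep spindles and slow waves,
#' K-complexes evoked 450-700 ms after S1 tones with probability
#' `p_evoked`, paired-tone stimulus trains, arousals, 1-s artifacts,
#' per-subject sensory-reactivity scores, and planted fixed/random effects
#' on the nap-level outcomes.
#'
#' Nap durations are lognormal, calibrated to observed condition means of
#' 62.2 min (SD 23.5) at baseline and 50.9 min (SD 16.7) under
#' stimulation; `nap_minutes` fixes the duration instead (used to scale
#' simulations down). Sensory reactivity is drawn as
#' `1.1 + 1.7 * Beta(2, 4)`, matching the observed composite range of
#' roughly 1.1-2.8.
#'
#' @param n_subjects Number of subjects.
#' @param fs Sampling rate in Hz.
#' @param nap_minutes Fixed nap duration in minutes, or `NULL` to draw from
#'   the calibrated lognormal.
#' @param channels Channel labels to synthesise (mastoids TP9/TP10 are
#'   appended automatically if missing).
#' @param base_rms Broadband background RMS in uV for wake.
#' @param one_over_f_exponent Spectral slope of the background (power
#'   proportional to `1/f^exponent`). The default of 2 gives the
#'   low-frequency-dominated spectrum of NREM sleep, with most variance in
#'   the slow-wave band and about 1% relative sigma power, so the
#'   relative-power detection feature is discriminative as it is on real
#'   sleep EEG.
#' @param stage_amp Named stage multipliers of `base_rms`.
#' @param spindle_rate Spontaneous spindle rate in N2, per minute.
#' @param spindle_snr Planted spindle peak amplitude as a multiple of the
#'   broadband background RMS of the surrounding stage.
#' @param spindle_amp_jitter Per-event multiplicative amplitude range
#'   (uniform), giving a spread of easy and hard events.
#' @param sw_rate_n2,sw_rate_n3 Spontaneous slow-wave rates per minute.
#' @param p_evoked Probability that an S1 tone in N2 evokes a K-complex.
#' @param evoked_latency_mean,evoked_latency_sd Truncated-normal parameters
#'   of the evoked negative-peak latency on [0.45, 0.70] s.
#' @param arousal_rate Arousals per hour of sleep.
#' @param artifact_prob Probability that a 1-s window carries an artifact.
#' @param effects Planted linear-model coefficients per outcome; see
#'   [default_effects()].
#' @param na_prob_base,na_prob_flagged Questionnaire "not applicable"
#'   probabilities for ordinary and age-inappropriate items.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 35, fs = 500, nap_minutes = NULL,
                        channels = c("F3", "Fz", "F4", "FC1", "FC2",
                                     "C3", "Cz", "C4", "O1", "Oz"),
                        base_rms = 20, one_over_f_exponent = 2,
                        stage_amp = c(W = 1, N1 = 1.2, N2 = 1.5,
                                      N3 = 2.2, REM = 1.2),
                        spindle_rate = 3, spindle_snr = 3,
                        spindle_amp_jitter = c(0.7, 1.3),
                        sw_rate_n2 = 3, sw_rate_n3 = 6,
                        p_evoked = 0.3,
                        evoked_latency_mean = 0.55,
                        evoked_latency_sd = 0.04,
                        arousal_rate = 5, artifact_prob = 0.02,
                        effects = default_effects(),
                        na_prob_base = 0.02, na_prob_flagged = 0.25) {
  channels <- union(channels, c("TP9", "TP10"))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Planted fixed-effect structure for nap-level outcomes
#'
#' Coefficients of `y = intercept + condition * b_cond + reactivity *
#' b_react + condition x reactivity * b_inter + sex * b_sex + age_c *
#' b_age + u_subject + e`, per outcome (age centred at 300 days).
#' Magnitudes echo the scale of the reported mixed-model estimates
#' (e.g. a spindle-density interaction near -1.28 per reactivity unit).
#'
#' @return Named list of coefficient vectors.
#' @export
default_effects <- function() {
  mk <- function(intercept, cond, react, inter, sex = 0, age = 0,
                 subject_sd, resid_sd) {
    c(intercept = intercept, condition = cond, reactivity = react,
      interaction = inter, sex = sex, age = age,
      subject_sd = subject_sd, resid_sd = resid_sd)
  }
  list(
    swa = mk(2500, 130, -380, -165, subject_sd = 400, resid_sd = 500),
    sw_density = mk(12, -0.5, -3.7, -4.3, subject_sd = 3, resid_sd = 4),
    sigma = mk(15, 0.9, 1.0, -3.8, subject_sd = 4, resid_sd = 7),
    spindle_density = mk(3, -0.19, 0.44, -1.279, subject_sd = 0.5,
                         resid_sd = 0.8),
    nap_min = mk(62, -12.2, -0.4, 7.1, subject_sd = 10, resid_sd = 18),
    arousal_density = mk(0.12, 0.002, -0.003, -0.007, subject_sd = 0.03,
                         resid_sd = 0.05),
    kc_likelihood = mk(0.25, 0.38, -0.56, 0.34, subject_sd = 0.1,
                       resid_sd = 0.3),
    sp_likelihood = mk(0.3, -0.05, 0.34, 0.18, subject_sd = 0.1,
                       resid_sd = 0.3)
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Spectrally shaped Gaussian noise with power ~ 1/f^alpha above a
# low-frequency knee (flat below it, so variance is not dominated by
# drift slower than the analysis band), unit RMS. `fs` gives the knee a
# physical frequency; without it the knee is skipped.
one_over_f_noise <- function(n, alpha = 1, fs = NULL, f_knee = 0.3) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  if (!is.null(fs)) f <- pmax(f * fs / n, f_knee)
  amp <- f^(-alpha / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(spec[nf]))
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

simulate_hypnogram <- function(n_epochs, epoch_s = 30) {
  trans <- list(
    W = c(W = 0.3, N1 = 0.7, N2 = 0, N3 = 0, REM = 0),
    N1 = c(W = 0.02, N1 = 0.45, N2 = 0.5, N3 = 0, REM = 0.03),
    N2 = c(W = 0.01, N1 = 0.02, N2 = 0.84, N3 = 0.10, REM = 0.03),
    N3 = c(W = 0.005, N1 = 0, N2 = 0.115, N3 = 0.88, REM = 0),
    REM = c(W = 0.02, N1 = 0.08, N2 = 0.10, N3 = 0, REM = 0.80))
  stages <- character(n_epochs)
  sol <- min(sample(1:3, 1), n_epochs)
  stages[seq_len(sol)] <- "W"
  cur <- "N1"
  for (i in seq_len(n_epochs)[-seq_len(sol)]) {
    stages[i] <- cur
    cur <- sample(names(trans[[cur]]), 1, prob = trans[[cur]])
  }
  stages
}

sw_template <- function(fs, neg_dur, pos_dur, neg_amp, pos_amp) {
  t_neg <- seq(0, neg_dur, by = 1 / fs)
  t_pos <- seq(1 / fs, pos_dur, by = 1 / fs)
  c(-neg_amp * sin(pi * t_neg / neg_dur),
    pos_amp * sin(pi * t_pos / pos_dur))
}

spindle_template <- function(fs, dur, freq, amp) {
  t <- seq(0, dur, by = 1 / fs)
  env <- 0.5 - 0.5 * cos(2 * pi * t / dur)  # raised cosine
  amp * env * sin(2 * pi * freq * t)
}

#' Simulate one nap recording with ground truth
#'
#' Generates a multichannel 1/f-background recording with stage-dependent
#' amplitude, planted spindles (sigma bursts with raised-cosine envelopes),
#' slow waves (half-wave pairs satisfying the detection criteria), evoked
#' K-complexes after S1 tones (stimulation condition only), arousals, 1-s
#' artifacts, a hypnogram, and the exact ground-truth event table. Planted
#' event times are identical across EEG channels (with small per-channel
#' amplitude jitter); ground-truth rows are recorded on Cz for slow waves
#' and C4 for spindles, the channels the corresponding analyses use.
#'
#' @param spec A [cohort_spec()].
#' @param condition `"baseline"` or `"stimulation"`.
#' @param seed Integer seed; identical seeds give identical naps.
#' @param subject Subject id recorded in the metadata.
#' @param nap_minutes Optional duration override.
#' @return A list with elements `recording`, `hypnogram`, `events`
#'   (ground truth), `train` (`NULL` for baseline naps).
#' @export
simulate_nap <- function(spec = cohort_spec(), condition = "baseline",
                         seed = NULL, subject = "s01",
                         nap_minutes = NULL) {
  with_seed(seed, {
    fs <- spec$fs
    nap_min <- nap_minutes %||% spec$nap_minutes %||% {
      cv <- if (condition == "baseline") 23.5 / 62.2 else 16.7 / 50.9
      mu <- if (condition == "baseline") 62.2 else 50.9
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
    }
    n_epochs <- max(6L, round(nap_min * 2))
    stages <- simulate_hypnogram(n_epochs)
    n <- n_epochs * 30L * fs
    stage_s <- rep(stages, each = 30L * fs)

    channels <- spec$channels
    eeg_ch <- setdiff(channels, c("TP9", "TP10"))
    amp <- spec$base_rms * spec$stage_amp[stage_s]

    data <- matrix(0, nrow = n, ncol = length(channels),
                   dimnames = list(NULL, channels))
    for (ch in channels) {
      scale_ch <- if (ch %in% c("TP9", "TP10")) 0.3 else 1
      data[, ch] <- one_over_f_noise(n, spec$one_over_f_exponent, fs = fs) *
        amp * scale_ch
    }

    events <- list()
    add_event <- function(wave, i0, type, channel_gt, neg_peak_time = NA,
                          neg_amp = NA, pos_amp = NA) {
      i1 <- i0 + length(wave) - 1L
      if (i0 < 1L || i1 > n) return(invisible(NULL))
      for (ch in eeg_ch) {
        data[i0:i1, ch] <<- data[i0:i1, ch] + wave * runif(1, 0.9, 1.1)
      }
      events[[length(events) + 1L]] <<- tibble(
        type = type, channel = channel_gt,
        onset = (i0 - 1L) / fs, offset = i1 / fs,
        neg_peak_time = neg_peak_time, neg_peak_amp = neg_amp,
        pos_peak_amp = pos_amp, stage = stage_s[i0])
    }

    place_times <- function(stage_set, rate_per_min, margin_s) {
      idx <- which(stage_s %in% stage_set)
      minutes <- length(idx) / fs / 60
      k <- rpois(1, rate_per_min * minutes)
      if (!k || !length(idx)) return(numeric(0))
      cand <- sort((sample(idx, min(k * 3, length(idx))) - 1L) / fs)
      keep <- numeric(0)
      for (t in cand) {
        if (length(keep) >= k) break
        if (!length(keep) || t - keep[length(keep)] > margin_s) {
          keep <- c(keep, t)
        }
      }
      keep
    }

    # spontaneous spindles in N2
    for (t0 in place_times("N2", spec$spindle_rate, 4)) {
      dur <- runif(1, 0.6, 2)
      a <- spec$spindle_snr * spec$base_rms * spec$stage_amp[["N2"]] *
        runif(1, spec$spindle_amp_jitter[1], spec$spindle_amp_jitter[2])
      wave <- spindle_template(fs, dur, runif(1, 11, 15), a)
      add_event(wave, round(t0 * fs) + 1L, "spindle", "C4")
    }
    # spontaneous slow waves in N2 and N3
    for (st in c("N2", "N3")) {
      rate <- if (st == "N2") spec$sw_rate_n2 else spec$sw_rate_n3
      for (t0 in place_times(st, rate, 3)) {
        nd <- runif(1, 0.4, 0.9)
        pd <- runif(1, 0.3, 0.7)
        na_ <- runif(1, 90, 150)
        pa <- runif(1, 35, 60)
        wave <- sw_template(fs, nd, pd, na_, pa)
        add_event(wave, round(t0 * fs) + 1L, "slow_wave", "Cz",
                  neg_peak_time = t0 + nd / 2, neg_amp = -na_, pos_amp = pa)
      }
    }

    # stimulus train + evoked K-complexes
    train <- NULL
    if (condition == "stimulation") {
      sleep_start <- (which(stages != "W")[1] - 1L) * 30
      train <- generate_stimulus_train(n / fs, start_s = sleep_start + 120)
      for (s1 in train$s1_onset) {
        i_s1 <- round(s1 * fs) + 1L
        if (i_s1 > n || stage_s[i_s1] != "N2") next
        if (runif(1) > spec$p_evoked) next
        lat <- rtruncnorm1(1, spec$evoked_latency_mean,
                           spec$evoked_latency_sd, 0.45, 0.70)
        nd <- 0.5
        pd <- runif(1, 0.3, 0.5)
        na_ <- runif(1, 120, 160)
        pa <- runif(1, 40, 60)
        onset <- s1 + lat - nd / 2
        wave <- sw_template(fs, nd, pd, na_, pa)
        add_event(wave, round(onset * fs) + 1L, "slow_wave", "Cz",
                  neg_peak_time = onset + nd / 2, neg_amp = -na_,
                  pos_amp = pa)
      }
    }

    # arousals (>= 3 s) and artifacts (1-s windows)
    sleep_min <- sum(stages != "W") / 2
    n_arousal <- rpois(1, spec$arousal_rate * sleep_min / 60)
    ar_onsets <- place_times(c("N1", "N2", "N3", "REM"),
                             n_arousal / max(sleep_min, 1), 30)
    arousals <- tibble(onset = ar_onsets,
                       duration = runif(length(ar_onsets), 3, 10),
                       external = runif(length(ar_onsets)) < 0.1)
    n_sec <- n_epochs * 30L
    artifact_mask <- runif(n_sec) < spec$artifact_prob
    for (s in which(artifact_mask)) {
      i0 <- (s - 1L) * fs + 1L
      burst <- rnorm(fs) * 8 * spec$base_rms
      for (ch in eeg_ch) data[i0:(i0 + fs - 1L), ch] <-
        data[i0:(i0 + fs - 1L), ch] + burst
    }

    hyp <- nap_hypnogram(stages, arousals = arousals,
                         artifact_mask = artifact_mask, lights_off = 0)
    rec <- nap_recording(data, fs = fs, channels = channels,
                         reference = "online_FCz",
                         meta = list(subject = subject,
                                     condition = condition))
    ev <- if (length(events)) {
      validate_events(dplyr::bind_rows(events))
    } else event_table()
    list(recording = rec, hypnogram = hyp, events = ev, train = train)
  })
}

#' Simulate a cohort of naps with planted effect structure
#'
#' Draws the subject table (sensory reactivity shared across conditions,
#' sex, age, autism likelihood, sleeping arrangement, counterbalanced
#' condition order), then generates nap-level outcome rows from the planted
#' linear model `y = Xb + u_subject + e` so that mixed-model parameter
#' recovery is well defined, plus questionnaire item responses and, for the
#' stimulation naps, ON/OFF likelihood rows. Full EEG recordings are
#' generated on demand with `signals = TRUE` (scaled-down durations are
#' recommended; see `nap_minutes` in [cohort_spec()]).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param signals If `TRUE`, also simulate the EEG of every nap via
#'   [simulate_nap()] (list-column `nap`).
#' @return A list with `subjects`, `features` (one row per nap),
#'   `likelihoods` (one row per stimulation nap x window), and
#'   `questionnaire`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            signals = FALSE) {
  with_seed(seed, {
    ns <- spec$n_subjects
    subjects <- tibble(
      subject = sprintf("s%03d", seq_len(ns)),
      reactivity = 1.1 + 1.7 * rbeta(ns, 2, 4),
      sex = rbinom(ns, 1, 0.5),
      age_days = round(rnorm(ns, 300, 30)),
      autism_likelihood = rbinom(ns, 1, 8 / 41),
      sleep_arrangement = rbinom(ns, 1, 12 / 41),
      first_condition = rep_len(c("baseline", "stimulation"), ns))

    eff <- spec$effects
    u <- lapply(eff, function(e) rnorm(ns, 0, e[["subject_sd"]]))

    rows <- list()
    for (i in seq_len(ns)) {
      conds <- if (subjects$first_condition[i] == "baseline") {
        c("baseline", "stimulation")
      } else c("stimulation", "baseline")
      for (v in seq_along(conds)) {
        cond01 <- as.numeric(conds[v] == "stimulation")
        row <- tibble(subject = subjects$subject[i],
                      condition = conds[v], visit = v,
                      stimulation = cond01,
                      reactivity = subjects$reactivity[i],
                      sex = subjects$sex[i],
                      age = subjects$age_days[i],
                      autism_likelihood = subjects$autism_likelihood[i],
                      sleep_arrangement = subjects$sleep_arrangement[i])
        for (out in names(eff)) {
          e <- eff[[out]]
          row[[out]] <- e[["intercept"]] + e[["condition"]] * cond01 +
            e[["reactivity"]] * subjects$reactivity[i] +
            e[["interaction"]] * cond01 * subjects$reactivity[i] +
            e[["sex"]] * subjects$sex[i] +
            e[["age"]] * (subjects$age_days[i] - 300) +
            u[[out]][i] + rnorm(1, 0, e[["resid_sd"]])
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    features <- dplyr::bind_rows(rows)

    # ON/OFF likelihood rows within stimulation naps
    lik <- features |>
      dplyr::filter(.data$condition == "stimulation") |>
      dplyr::select("subject", "reactivity", "sex", "age",
                    "autism_likelihood")
    likelihoods <- dplyr::bind_rows(
      dplyr::mutate(lik, window = "off", stimulation = 0),
      dplyr::mutate(lik, window = "on", stimulation = 1))
    for (out in c("kc_likelihood", "sp_likelihood")) {
      e <- spec$effects[[out]]
      idx <- match(likelihoods$subject, subjects$subject)
      likelihoods[[out]] <- pmax(0,
        e[["intercept"]] + e[["condition"]] * likelihoods$stimulation +
          e[["reactivity"]] * likelihoods$reactivity +
          e[["interaction"]] * likelihoods$stimulation *
            likelihoods$reactivity +
          u[[out]][idx] +
          rnorm(nrow(likelihoods), 0, e[["resid_sd"]]))
    }

    questionnaire <- simulate_questionnaire(subjects, spec)

    naps <- NULL
    if (signals) {
      naps <- purrr::pmap(
        list(features$subject, features$condition, seq_len(nrow(features))),
        function(sub, cond, k) {
          simulate_nap(spec, condition = cond, subject = sub,
                       seed = sample.int(.Machine$integer.max, 1))
        })
    }
    list(subjects = subjects, features = features,
         likelihoods = likelihoods, questionnaire = questionnaire,
         naps = naps, spec = spec)
  })
}

#' Simulate questionnaire item responses
#'
#' Items on the 1-5 frequency scale are generated from the latent
#' reactivity (raw = `6 - reactivity` plus item noise, clipped to 1-5).
#' Three designated "age-inappropriate" items carry an elevated
#' "not applicable" probability, emulating the missingness pattern of
#' infant questionnaires (median 1 NA per respondent).
#'
#' @param subjects Tibble with `subject` and `reactivity` columns.
#' @param spec A [cohort_spec()].
#' @return Tibble with `subject` and item columns `I01`-`I24`.
#' @export
simulate_questionnaire <- function(subjects, spec = cohort_spec()) {
  ns <- nrow(subjects)
  flagged <- c(7, 15, 22)
  items <- matrix(NA_real_, nrow = ns, ncol = 24)
  for (j in seq_len(24)) {
    raw <- round(6 - (subjects$reactivity + rnorm(ns, 0, 0.7)))
    raw <- pmin(pmax(raw, 1), 5)
    p_na <- if (j %in% flagged) spec$na_prob_flagged else spec$na_prob_base
    raw[runif(ns) < p_na] <- NA
    items[, j] <- raw
  }
  colnames(items) <- sprintf("I%02d", seq_len(24))
  dplyr::bind_cols(tibble(subject = subjects$subject), as_tibble(items))
}
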