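test_that("window geometry derives from the tone and gap durations", {
  w <- window_spec()
  expect_equal(unname(diff(w$sp_on)), 3.4)     # 1 + 0.7 + 1 + 0.7
  expect_equal(unname(diff(w$sp_off)), 3.4)
  expect_equal(unname(diff(w$sp_segment)), 8.8)  # ON + OFF + 2 x 1-s buffer
  expect_equal(unname(diff(w$kc_on)), 0.25)
  expect_equal(unname(diff(w$kc_off)), 0.25)
  expect_equal(w$sp_segment, c(-4.4, 4.4))
})

test_that("generated trains respect the pair geometry and bounds", {
  tr <- generate_stimulus_train(60, seed = 7)
  expect_gte(nrow(tr), 3)
  expect_lte(nrow(tr), 4)
  expect_equal(tr$s2_onset - tr$s1_onset, rep(1.7, nrow(tr)))
  gaps <- diff(tr$s1_onset) - 2.7
  expect_true(all(gaps >= 12 & gaps <= 18))
  expect_identical(generate_stimulus_train(60, seed = 7), tr)
  expect_error(generate_stimulus_train(10), "greater than 20")
})

test_that("stimulus eligibility equals the brute-force per-sample check", {
  set.seed(71)
  fs <- 100
  stages <- sample(c("N2", "N3", "W"), 60, replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
  n_sec <- 60 * 30
  amask <- runif(n_sec) < 0.02
  hyp <- nap_hypnogram(stages, artifact_mask = amask)
  n <- n_sec * fs
  tr <- generate_stimulus_train(n_sec, seed = 72)
  seg <- window_spec()$sp_segment
  got <- select_eligible_stimuli(tr, hyp, fs, n, segment = seg)
  ok <- eligible_mask(hyp, fs, n, "N2")
  want <- tr$s1_onset[vapply(tr$s1_onset, function(s1) {
    i <- (floor((s1 + seg[1]) * fs) + 1L):ceiling((s1 + seg[2]) * fs)
    all(i >= 1) && all(i <= n) && all(ok[i])
  }, logical(1))]
  expect_identical(got, want)
  # crossing a stage boundary disqualifies
  hyp2 <- nap_hypnogram(c("N2", "N3"))
  tr2 <- stimulus_train(29, 30.7)
  expect_length(select_eligible_stimuli(tr2, hyp2, fs, 60 * fs,
                                        segment = seg), 0)
  tr3 <- stimulus_train(15, 16.7)
  hyp3 <- nap_hypnogram(c("N2", "N2"))
  expect_equal(select_eligible_stimuli(tr3, hyp3, fs, 60 * fs,
                                       segment = seg), 15)
})

test_that("evoked average recovers an injected template", {
  set.seed(73)
  fs <- 250
  n_s <- 600
  n <- n_s * fs
  tmpl_t <- seq(0, 1, by = 1 / fs)
  tmpl <- -40 * sin(pi * tmpl_t)      # 1-s negative deflection
  x <- matrix(rnorm(n * 2, sd = 15), ncol = 2,
              dimnames = list(NULL, c("Cz", "C4")))
  tr <- generate_stimulus_train(n_s, seed = 74)
  for (s1 in tr$s1_onset) {
    i0 <- round((s1 + 0.3) * fs) + 1L
    idx <- i0:(i0 + length(tmpl) - 1L)
    x[idx, ] <- x[idx, ] + tmpl
  }
  rec <- nap_recording(x, fs)
  erp <- evoked_average(rec, tr$s1_onset, channels = c("Cz", "C4"),
                        window = c(-1, 2))
  n_stim <- attr(erp, "n_stimuli")
  sem <- 15 / sqrt(2 * n_stim)
  full <- numeric(nrow(erp))
  i0 <- which.min(abs(erp$time - 0.3))
  full[i0:(i0 + length(tmpl) - 1L)] <- tmpl
  expect_lt(max(abs(erp$amplitude - full)), 4 * sem + 1)

  # a single stimulus reproduces that epoch exactly (baseline-corrected)
  s1_mid <- tr$s1_onset[3]   # away from the recording edges
  one <- evoked_average(rec, s1_mid, channels = "Cz",
                        window = c(-0.5, 1))
  idx <- round(s1_mid * fs) + 1L + seq(round(-0.5 * fs), fs)
  raw <- x[idx, "Cz"]
  expect_equal(one$amplitude, unname(raw - mean(raw[one$time < 0])),
               tolerance = 1e-9)

  expect_error(evoked_average(rec, numeric(0)), "Insufficient")
})

test_that("peak-latency histograms localise planted evoked peaks", {
  set.seed(75)
  tr <- generate_stimulus_train(1200, seed = 76)
  lat <- napscape:::rtruncnorm1(nrow(tr), 0.55, 0.04, 0.45, 0.70)
  ev <- event_table(type = rep("slow_wave", nrow(tr)), channel = "Cz",
                    onset = tr$s1_onset + lat - 0.25,
                    offset = tr$s1_onset + lat + 0.4,
                    neg_peak_time = tr$s1_onset + lat)
  h <- peak_latency_histogram(ev, tr)
  s1 <- h[h$tone == "S1", ]
  modal <- s1$bin_mid[which.max(s1$count)]
  expect_gte(modal, 0.45)
  expect_lte(modal, 0.70)
  # all-empty events give an all-zero histogram
  h0 <- peak_latency_histogram(event_table(), tr)
  expect_true(all(h0$count == 0))
})

test_that("uniform spontaneous peaks give a flat S1-locked histogram", {
  set.seed(77)
  tr <- generate_stimulus_train(4000, seed = 78)
  peaks <- runif(2000, 0, 4000)
  ev <- event_table(type = rep("slow_wave", length(peaks)), channel = "Cz",
                    onset = peaks - 0.2, offset = peaks + 0.2,
                    neg_peak_time = peaks)
  h <- peak_latency_histogram(ev, tr, bin_s = 0.25)
  s1 <- h[h$tone == "S1", ]
  expect_gt(stats::chisq.test(s1$count)$p.value, 0.01)
})

test_that("likelihoods count events per stimulus with half-open windows", {
  w <- window_spec()
  s1 <- seq(0, by = 20, length.out = 10)
  # slow waves: peaks at +0.5 s after four stimuli
  ev <- event_table(type = rep("slow_wave", 4), channel = "Cz",
                    onset = s1[1:4] + 0.2, offset = s1[1:4] + 1,
                    neg_peak_time = s1[1:4] + 0.5)
  kc <- kcomplex_likelihood(ev, s1, w)
  expect_equal(kc$likelihood[kc$window == "on"], 0.4)
  expect_equal(kc$likelihood[kc$window == "off"], 0)

  # boundary: a peak exactly at +0.45 is inside, at +0.70 outside
  evb <- event_table(type = rep("slow_wave", 2), channel = "Cz",
                     onset = c(s1[1] + 0.2, s1[2] + 0.4),
                     offset = c(s1[1] + 1, s1[2] + 1.2),
                     neg_peak_time = c(s1[1] + 0.45, s1[2] + 0.70))
  kcb <- kcomplex_likelihood(evb, s1, w)
  expect_equal(kcb$count[kcb$window == "on"], 1)

  expect_equal(kcomplex_likelihood(event_table(), s1, w)$likelihood,
               c(0, 0))
  expect_error(kcomplex_likelihood(ev, numeric(0), w), "Insufficient")

  # spindles: start-time membership; 5 ON, 3 OFF over 20 stimuli
  s1_20 <- seq(0, by = 20, length.out = 20)
  sp <- event_table(type = rep("spindle", 8), channel = "Cz",
                    onset = c(s1_20[1:5] + 1.0, s1_20[6:8] - 2.0),
                    offset = c(s1_20[1:5] + 2.0, s1_20[6:8] - 0.5))
  spl <- spindle_likelihood(sp, s1_20, w)
  expect_equal(spl$likelihood[spl$window == "on"], 0.25)
  expect_equal(spl$likelihood[spl$window == "off"], 0.15)

  # a spindle starting exactly at 0 is ON (half-open [0, 3.4))
  sp0 <- event_table(type = "spindle", channel = "Cz", onset = s1_20[1],
                     offset = s1_20[1] + 1)
  sp0l <- spindle_likelihood(sp0, s1_20, w)
  expect_equal(sp0l$count[sp0l$window == "on"], 1)
  expect_equal(sp0l$count[sp0l$window == "off"], 0)
})

test_that("ON/OFF windows are disjoint and translation-invariant", {
  w <- window_spec()
  expect_lte(w$sp_off[2], w$sp_on[1])
  expect_lte(w$kc_off[2], w$kc_on[1])
  s1 <- seq(10, by = 15, length.out = 6)
  ev <- event_table(type = rep("spindle", 3), channel = "Cz",
                    onset = s1[1:3] + 1, offset = s1[1:3] + 2)
  base <- spindle_likelihood(ev, s1, w)
  shift <- 123.456
  ev2 <- ev
  ev2$onset <- ev2$onset + shift
  ev2$offset <- ev2$offset + shift
  ev2$neg_peak_time <- ev2$neg_peak_time + shift
  moved <- spindle_likelihood(validate_events(ev2), s1 + shift, w)
  expect_equal(moved$likelihood, base$likelihood)
})
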