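make_sine_rec <- function(freq, fs = 500, dur = 20, amp = 1) {
  t <- (0:(dur * fs - 1)) / fs
  nap_recording(cbind(Cz = amp * sin(2 * pi * freq * t)), fs = fs)
}

test_that("band-pass attenuation matches the analytic Butterworth oracle", {
  spec <- filter_spec()
  for (f0 in c(0.05, 10)) {
    rec <- make_sine_rec(f0)
    out <- quiet_bandpass(rec, spec)
    # drop edge transients before comparing steady-state amplitude
    core <- seq(5 * rec$fs, 15 * rec$fs)
    got <- sd(out$data[core, 1]) / sd(rec$data[core, 1])
    want <- butter1_bp_gain2(f0, 0.2, 40)
    expect_lt(abs(got - want), 0.01)
  }
  # the stop-band example: 0.05 Hz comes out below half its input RMS
  rec <- make_sine_rec(0.05, dur = 60)
  out <- quiet_bandpass(rec, spec)
  expect_lt(sd(out$data[, 1]), 0.5 * sd(rec$data[, 1]))
})

test_that("filtering is linear and preserves all-zero signals", {
  set.seed(21)
  fs <- 250
  x <- rnorm(fs * 10)
  y <- rnorm(fs * 10)
  rx <- nap_recording(cbind(Cz = x), fs)
  ry <- nap_recording(cbind(Cz = y), fs)
  rxy <- nap_recording(cbind(Cz = 2 * x - 3 * y), fs)
  fx <- quiet_bandpass(rx)$data[, 1]
  fy <- quiet_bandpass(ry)$data[, 1]
  fxy <- quiet_bandpass(rxy)$data[, 1]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
  zero <- nap_recording(cbind(Cz = numeric(fs * 5)), fs)
  expect_true(all(quiet_bandpass(zero)$data == 0))
  expect_error(bandpass(nap_recording(cbind(Cz = numeric(100)), fs = 60)),
               "Nyquist")
})

test_that("re-referencing subtracts the mastoid combination", {
  n <- 100
  rec <- nap_recording(cbind(Cz = rep(10, n), C3 = rep(10, n),
                             C4 = rep(10, n), TP9 = rep(2, n),
                             TP10 = rep(4, n)), fs = 100)
  lm_ <- rereference(rec, "linked_mastoids")
  expect_equal(unname(lm_$data[1, "Cz"]), 7)   # 10 - (2+4)/2
  expect_equal(lm_$reference, "linked_mastoids")

  cm <- rereference(rec, "contralateral_mastoids")
  expect_equal(unname(cm$data[1, "C3"]), 6)    # left channel - right mastoid
  expect_equal(unname(cm$data[1, "C4"]), 8)    # right channel - left mastoid
  expect_equal(unname(cm$data[1, "Cz"]), 7)    # midline - linked

  # common mode: all channels and mastoids at the same constant -> zero
  rec2 <- nap_recording(matrix(5, n, 3,
                               dimnames = list(NULL, c("Cz", "TP9", "TP10"))),
                        fs = 100)
  expect_true(all(rereference(rec2)$data == 0))

  expect_error(rereference(rec, bad_channels = "TP10"),
               class = "napscape_exclusion")
  expect_error(rereference(nap_recording(cbind(Cz = 1:5), fs = 5)),
               "missing")
})

test_that("artifact detector flags bursts but not stationary noise", {
  set.seed(31)
  fs <- 100
  n_s <- 300
  x <- matrix(rnorm(n_s * fs * 2, sd = 20), ncol = 2,
              dimnames = list(NULL, c("Cz", "C4")))
  hyp <- nap_hypnogram(rep("N2", n_s / 30))
  rec <- nap_recording(x, fs)
  mask <- detect_artifacts(rec, hyp)
  expect_lt(mean(mask), 0.02)

  # inject a 10x amplitude burst into one window
  x2 <- x
  x2[(100 * fs + 1):(101 * fs), ] <- x2[(100 * fs + 1):(101 * fs), ] * 10
  mask2 <- detect_artifacts(nap_recording(x2, fs), hyp)
  expect_true(mask2[101])

  # idempotence and exact masked-duration bookkeeping
  mask3 <- detect_artifacts(nap_recording(x2, fs), hyp)
  expect_identical(mask2, mask3)
  by_stage <- attr(mask2, "by_stage")
  expect_equal(sum(by_stage$n_flagged), sum(mask2))

  zero <- nap_recording(matrix(0, n_s * fs, 1,
                               dimnames = list(NULL, "Cz")), fs)
  expect_equal(sum(detect_artifacts(zero, hyp)), 0)
})
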