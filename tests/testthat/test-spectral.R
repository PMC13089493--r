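test_that("Welch band power matches Parseval for a pure sinusoid", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)         # variance 0.5
  psd <- welch_psd(x, fs)
  expect_lt(abs(band_power(psd, c(9, 16)) - 0.5) / 0.5, 0.1)
  expect_lt(band_power(psd, c(0.5, 2)), 0.01)
})

test_that("white-noise PSD is flat across distant bands", {
  set.seed(41)
  fs <- 200
  x <- rnorm(300 * fs)
  psd <- welch_psd(x, fs)
  lo <- band_power(psd, c(0.5, 2)) / 1.5
  hi <- band_power(psd, c(9, 16)) / 7
  expect_gt(lo / hi, 0.8)
  expect_lt(lo / hi, 1.25)
})

test_that("constant signals carry no power above DC", {
  psd <- welch_psd(rep(3.3, 2000), fs = 100)
  expect_lt(max(psd$psd[psd$freq > 0]), 1e-20)
})

test_that("band_power integrates flat PSDs exactly and checks bounds", {
  flat <- tibble::tibble(freq = seq(0, 50, by = 0.25), psd = 1)
  expect_equal(band_power(flat, c(0.5, 2)), 1.5)
  expect_equal(band_power(flat, c(9, 16)), 7)
  expect_equal(band_power(flat, c(3, 3)), 0)
  expect_error(band_power(flat, c(40, 60)), "outside")
})

test_that("segments never span an excision boundary", {
  fs <- 100
  set.seed(42)
  x <- rnorm(60 * fs)
  # two eligible runs, each 8 s: expect 3 half-overlapping 4-s segments each
  runs <- tibble::tibble(start = c(1L, 3001L), end = c(800L, 3800L))
  psd <- welch_psd(x, fs, runs = runs)
  expect_equal(attr(psd, "n_segments"), 6)
  expect_error(welch_psd(x, fs, runs = tibble::tibble(start = 1, end = 300)),
               "Insufficient")
})

test_that("ROI band power is a channel median with stage restriction", {
  set.seed(43)
  fs <- 200
  n_s <- 120
  t <- (0:(n_s * fs - 1)) / fs
  # two channels with 10-Hz sinusoids of different amplitude (power 2 and 8)
  rec <- nap_recording(cbind(Cz = 2 * sin(2 * pi * 10 * t),
                             C4 = 4 * sin(2 * pi * 10 * t)),
                       fs = fs)
  hyp <- nap_hypnogram(rep("N2", n_s / 30))
  bp <- roi_band_power(rec, hyp, band = c(9, 16), stages = "N2",
                       roi = c("Cz", "C4"))
  expect_equal(bp$roi_value, mean(c(2, 8)), tolerance = 0.05)  # median of two
  one <- roi_band_power(rec, hyp, band = c(9, 16), stages = "N2",
                        roi = "C4")
  expect_equal(one$roi_value, 8, tolerance = 0.4)

  expect_error(roi_band_power(rec, hyp, band = c(9, 16), stages = "N3",
                              roi = "Cz"), "Insufficient")
  expect_error(roi_band_power(rec, hyp, band = c(9, 16), stages = "N2",
                              roi = c("Cz", "F3")), "missing")
})

test_that("band power scales with amplitude squared and ignores other stages", {
  set.seed(44)
  fs <- 200
  n_s <- 150
  x <- rnorm(n_s * fs, sd = 10)
  stages <- rep(c("N2", "N3", "N2", "N3", "N2"), each = 1)
  hyp <- nap_hypnogram(stages)
  rec1 <- nap_recording(cbind(Cz = x), fs)
  rec3 <- nap_recording(cbind(Cz = 3 * x), fs)
  p1 <- roi_band_power(rec1, hyp, c(9, 16), stages = "N2", roi = "Cz")
  p3 <- roi_band_power(rec3, hyp, c(9, 16), stages = "N2", roi = "Cz")
  expect_equal(p3$roi_value / p1$roi_value, 9, tolerance = 1e-6)

  # replacing N3 data cannot change an N2-restricted sigma value
  x2 <- x
  x2[rep(stages, each = 30 * fs) == "N3"] <- 0
  p_alt <- roi_band_power(nap_recording(cbind(Cz = x2), fs), hyp,
                          c(9, 16), stages = "N2", roi = "Cz")
  expect_equal(p_alt$roi_value, p1$roi_value)
})
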