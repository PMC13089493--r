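mk_events <- function(onsets, offsets, ch = "C4", type = "spindle") {
  event_table(type = rep(type, length(onsets)), channel = ch,
              onset = onsets, offset = offsets)
}

test_that("event matching handles identity, misses and double detections", {
  a <- mk_events(c(1, 5, 9), c(2, 6, 10))
  m <- match_events(a, a)
  expect_equal(m$tp, 3); expect_equal(m$fp, 0); expect_equal(m$fn, 0)
  expect_equal(m$f1, 1)

  none <- match_events(mk_events(numeric(), numeric()),
                       mk_events(c(1, 3, 5, 7, 9), c(2, 4, 6, 8, 10)))
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)

  # two detections over one annotation: greedy 1-1 gives tp=1, fp=1
  two <- match_events(mk_events(c(1.0, 1.6), c(1.5, 2.2)),
                      mk_events(1.2, 2.0))
  expect_equal(two$tp, 1); expect_equal(two$fp, 1); expect_equal(two$fn, 0)

  expect_error(match_events(mk_events(1, 2, ch = "Cz"),
                            mk_events(1, 2, ch = "C4")), "single channel")
})

test_that("matching is order-invariant and grows under symmetric enlargement", {
  set.seed(61)
  d_on <- sort(runif(10, 0, 100))
  a_on <- sort(runif(8, 0, 100))
  det <- mk_events(d_on, d_on + runif(10, 0.5, 1.5))
  ann <- mk_events(a_on, a_on + runif(8, 0.5, 1.5))
  m1 <- match_events(det, ann)
  m2 <- match_events(det[sample(10), ], ann[sample(8), ])
  expect_equal(m1, m2)

  fat <- ann
  fat$onset <- fat$onset - 0.5
  fat$offset <- fat$offset + 0.5
  expect_gte(match_events(det, fat)$tp, m1$tp)
})

test_that("grid search returns the single cell trivially and validates input", {
  nap <- make_spindle_nap(seed = 600, minutes = 2)
  g1 <- tibble::tibble(thr_rms = 1.275, thr_corr = 0.52, thr_relpow = 0.13)
  res <- grid_search_thresholds(list(nap), g1)
  expect_equal(res$best$thr_rms, 1.275)
  expect_equal(nrow(res$surface), 1)
  expect_error(grid_search_thresholds(list(nap), g1[0, ]), "empty")
  nap_noann <- nap; nap_noann$annotations <- event_table()
  expect_error(grid_search_thresholds(list(nap_noann), g1), "annotations")
})

test_that("grid search is deterministic with the stated tie-break", {
  nap <- make_spindle_nap(seed = 601, minutes = 2)
  grid <- tidyr::expand_grid(thr_rms = c(1.275, 1.5),
                             thr_corr = c(0.52, 0.65),
                             thr_relpow = 0.13)
  r1 <- grid_search_thresholds(list(nap), grid)
  r2 <- grid_search_thresholds(list(nap), grid)
  expect_identical(r1$surface, r2$surface)
  expect_identical(r1$best_cell, r2$best_cell)
  # the chosen cell attains the maximum pooled F1
  expect_equal(r1$best_cell$f1, max(r1$surface$f1))
})

test_that("Steiger's z is zero under symmetry and finite at small n", {
  s <- compare_dependent_correlations(0.5, 0.5, 0.3, n = 40)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  tiny <- compare_dependent_correlations(0.4, 0.6, 0.5, n = 4)
  expect_true(is.finite(tiny$z))
  expect_gt(tiny$p, 0.3)
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 40), "in \\(-1")
  expect_error(compare_dependent_correlations(0.4, 0.5, 0.3, 3), "n > 3")
})

test_that("Steiger's z agrees with a Monte-Carlo oracle of the z1-z2 spread", {
  # sampling distribution of atanh(r_xy) - atanh(r_xz) under a trivariate
  # normal with the stated correlation structure, simulated directly
  r_xy <- 0.61; r_xz <- 0.73; r_yz <- 0.8; n <- 58
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  L <- chol(R)
  set.seed(62)
  reps <- 40000
  diffs <- replicate(reps, {
    z <- matrix(rnorm(3 * n), n, 3) %*% L
    atanh(cor(z[, 1], z[, 2])) - atanh(cor(z[, 1], z[, 3]))
  })
  z_mc <- (atanh(r_xy) - atanh(r_xz)) / sd(diffs)
  got <- compare_dependent_correlations(r_xy, r_xz, r_yz, n)$z
  expect_lt(abs(got - z_mc), 0.05)
})
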