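test_that("the generator is deterministic under a fixed seed", {
  spec <- cohort_spec(nap_minutes = 3, channels = "Cz")
  a <- simulate_nap(spec, "stimulation", seed = 101)
  b <- simulate_nap(spec, "stimulation", seed = 101)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$hypnogram$epoch_stages, b$hypnogram$epoch_stages)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$train$s1_onset, b$train$s1_onset)
})

test_that("ground-truth tables satisfy the event and train invariants", {
  spec <- cohort_spec(nap_minutes = 4)
  nap <- simulate_nap(spec, "stimulation", seed = 102)
  expect_s3_class(validate_events(nap$events), "nap_events")
  expect_true(all(nap$events$onset < nap$events$offset))
  tr <- nap$train
  expect_equal(tr$s2_onset - tr$s1_onset, rep(1.7, nrow(tr)))
  expect_true(all(diff(tr$s1_onset) >= 12 + 2.7))
  expect_equal(nap$hypnogram$epoch_s * length(nap$hypnogram$epoch_stages),
               duration_s(nap$recording))
})

test_that("planted slow waves pass the detection criteria oracle", {
  # clean templates at the generator's amplitude ranges, no background
  set.seed(103)
  fs <- 500
  accepted <- 0L
  total <- 120L
  for (k in seq_len(total)) {
    w <- napscape:::sw_template(fs, runif(1, 0.4, 0.9), runif(1, 0.3, 0.7),
                                runif(1, 90, 150), runif(1, 35, 60))
    x <- numeric(6 * fs)
    x[fs:(fs + length(w) - 1L)] <- w
    accepted <- accepted + (nrow(oracle_slow_waves(x, fs)) >= 1L)
  }
  expect_gte(accepted / total, 0.99)
})

test_that("planted spindle density matches the requested rate", {
  spec <- cohort_spec(nap_minutes = 8, channels = "C4", spindle_rate = 3)
  counts <- 0; minutes <- 0
  for (s in 104:106) {
    nap <- simulate_nap(spec, "baseline", seed = s)
    n2_min <- sum(nap$hypnogram$epoch_stages == "N2") / 2
    counts <- counts + sum(nap$events$type == "spindle")
    minutes <- minutes + n2_min
  }
  rate <- counts / minutes
  # Poisson tolerance around 3/min
  expect_gt(rate, 3 - 3 * sqrt(3 / minutes))
  expect_lt(rate, 3 + 3 * sqrt(3 / minutes))
})

test_that("cohorts share reactivity across conditions and counterbalance", {
  co <- simulate_cohort(cohort_spec(n_subjects = 12), seed = 107)
  by_sub <- split(co$features$reactivity, co$features$subject)
  expect_true(all(vapply(by_sub, function(v) length(unique(v)) == 1,
                         logical(1))))
  firsts <- co$features$condition[co$features$visit == 1]
  expect_equal(sum(firsts == "baseline"), 6)
  expect_equal(nrow(co$features), 24)
  expect_equal(nrow(co$likelihoods), 24)   # 12 stim naps x ON/OFF
  expect_true(all(co$subjects$reactivity > 1 & co$subjects$reactivity < 3))
})

test_that("a null-effect cohort has equal condition means", {
  eff <- default_effects()
  for (nm in names(eff)) {
    eff[[nm]][c("condition", "reactivity", "interaction", "sex", "age")] <- 0
  }
  co <- simulate_cohort(cohort_spec(n_subjects = 150, effects = eff),
                        seed = 108)
  d <- co$features
  for (out in c("spindle_density", "sw_density")) {
    delta <- mean(d[[out]][d$stimulation == 1]) -
      mean(d[[out]][d$stimulation == 0])
    pooled_se <- sd(d[[out]]) * sqrt(2 / (nrow(d) / 2))
    expect_lt(abs(delta), 3 * pooled_se)
  }
})

test_that("minimum viable cohort of two subjects is well-formed", {
  co <- simulate_cohort(cohort_spec(n_subjects = 2), seed = 109)
  expect_equal(nrow(co$features), 4)
  expect_equal(nrow(co$questionnaire), 2)
  expect_true(all(c("kc_likelihood", "sp_likelihood") %in%
                    names(co$likelihoods)))
})
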