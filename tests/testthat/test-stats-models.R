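test_that("Winsorization replaces 4-SD outliers with boundary + unit", {
  x <- c(1:20, 500)
  w <- winsorize(x)
  expect_equal(w$values[21], 21)     # max non-outlier 20 + unit 1
  expect_equal(w$log$original, 500)
  expect_equal(w$log$replacement, 21)

  benign <- c(3, 5, 7, 9)
  expect_equal(winsorize(benign)$values, benign)
  expect_equal(nrow(winsorize(benign)$log), 0)

  expect_equal(winsorize(c(0, 0, 0, 0))$values, c(0, 0, 0, 0))

  low <- c(-500, 1:20)
  wl <- winsorize(low)
  expect_equal(wl$values[1], 0)      # min non-outlier 1 - unit 1
  expect_equal(winsorize(c(1:20, 500), unit = 0.5)$values[21], 20.5)
  expect_error(winsorize(c(1, 2)), "at least 3")
})

test_that("degenerate random-intercept fits collapse to OLS", {
  set.seed(91)
  n <- 60
  d <- tibble::tibble(
    subject = sprintf("s%02d", 1:n),       # one nap per subject
    stimulation = rep(0:1, n / 2),
    reactivity = runif(n, 1.1, 2.8),
    sex = rbinom(n, 1, 0.5),
    age = rnorm(n, 300, 30))
  d$y <- 2 + 0.5 * d$stimulation + rnorm(n)   # no subject variance
  f <- suppressWarnings(fit_lmm(d, "y", "base"))
  ols <- stats::lm(y ~ stimulation + reactivity + sex + age, data = d)
  # the variance split itself is unidentifiable in this design (one nap per
  # subject), so only the fixed effects are checked
  expect_equal(unname(tidy(f)$estimate), unname(coef(ols)),
               tolerance = 1e-5)
})

test_that("fits are invariant to row permutation and report matched terms", {
  co <- simulate_cohort(cohort_spec(n_subjects = 20), seed = 92)
  d <- co$features
  f1 <- fit_lmm(d, "sw_density", "interaction")
  f2 <- fit_lmm(d[sample(nrow(d)), ], "sw_density", "interaction")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-8)
  expect_true("stimulation:reactivity" %in% tidy(f1)$term)

  fb <- fit_lmm(d, "sw_density", "base")
  fs <- fit_lmm(d, "sw_density", "sensitivity_base")
  expect_equal(setdiff(tidy(fs)$term, tidy(fb)$term), "autism_likelihood")

  # standardized and unstandardized estimates agree in sign (base model;
  # the intercept is excluded since centring legitimately moves it)
  td <- tidy(fb)
  td <- td[td$term != "(Intercept)" & abs(td$estimate) > 1e-6, ]
  expect_true(all(sign(td$std_beta) == sign(td$estimate)))
})

test_that("the report takes main effects from the base model", {
  co <- simulate_cohort(cohort_spec(n_subjects = 25), seed = 93)
  rep_ <- lmm_report(co$features, "spindle_density")
  base <- tidy(fit_lmm(co$features, "spindle_density", "base"))
  expect_equal(rep_$estimate[rep_$term == "reactivity"],
               base$estimate[base$term == "reactivity"])
  expect_true("stimulation:reactivity" %in% rep_$term)
  expect_false("(Intercept)" %in% rep_$term)
})

test_that("arousal-density model accepts the sleep-arrangement covariate", {
  co <- simulate_cohort(cohort_spec(n_subjects = 25), seed = 94)
  rep_ <- lmm_report(co$features, "arousal_density",
                     extra_covariates = "sleep_arrangement")
  expect_true("sleep_arrangement" %in% rep_$term)
})

test_that("stage-proportion model recovers a planted N3 shift and takes zeros", {
  sim_cohort_long <- function(seed, n3_shift = 0.9, ns = 40) {
    set.seed(seed)
    long <- tidyr::expand_grid(subject = sprintf("s%02d", 1:ns),
                               stimulation = 0:1,
                               stage = c("N1", "N2", "N3", "REM"))
    long$reactivity <- rnorm(nrow(long) / 8, 0, 0.5)[
      match(long$subject, sprintf("s%02d", 1:ns))]
    mu <- stats::plogis(-1 + n3_shift * (long$stage == "N3"))
    long$proportion <- rbeta(nrow(long), mu * 30, (1 - mu) * 30)
    long$proportion[long$stage == "REM" &
                      runif(nrow(long)) < 0.15] <- 0
    long
  }
  ests <- vapply(1:8, function(s) {
    f <- fit_stage_proportion_model(sim_cohort_long(s))
    td <- tidy(f)
    td$estimate[td$term == "stageN3"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.9) / 0.9, 0.25)

  # a nap with an exactly-zero proportion fits without error
  d0 <- sim_cohort_long(99)
  d0$proportion[1] <- 0
  expect_s3_class(fit_stage_proportion_model(d0), "nap_zib")
  d_bad <- d0; d_bad$proportion[2] <- 1.4
  expect_error(fit_stage_proportion_model(d_bad), "\\[0, 1\\]")
})

test_that("null stage model keeps stage contrasts small", {
  ok <- vapply(1:10, function(s) {
    set.seed(s + 200)
    ns <- 30
    long <- tidyr::expand_grid(subject = sprintf("s%02d", 1:ns),
                               stimulation = 0:1,
                               stage = c("N1", "N2", "N3", "REM"))
    long$reactivity <- rnorm(ns, 0, 0.5)[
      match(long$subject, sprintf("s%02d", 1:ns))]
    long$proportion <- rbeta(nrow(long), 0.25 * 30, 0.75 * 30)
    long$proportion[runif(nrow(long)) < 0.05] <- 0
    f <- suppressWarnings(fit_stage_proportion_model(long))
    td <- tidy(f)
    stage_terms <- td[td$term %in% c("stageN2", "stageN3", "stageREM"), ]
    all(abs(stage_terms$statistic) < 2)
  }, logical(1))
  expect_gte(mean(ok), 0.7)
})
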