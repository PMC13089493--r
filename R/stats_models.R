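#' Winsorize outliers beyond 4 SD
#'
#' Values more than `sd_limit` standard deviations from the mean are
#' replaced by one unit beyond the most extreme non-outlier value: high
#' outliers become `max(non-outliers) + unit`, low outliers become
#' `min(non-outliers) - unit`. The "unit" is the variable's declared
#' measurement granularity (default 1).
#'
#' @param x Numeric vector (length >= 3).
#' @param sd_limit SD threshold (default 4).
#' @param unit Replacement step beyond the boundary value.
#' @return A list with `values` (adjusted vector) and `log` (tibble of
#'   `index`, `original`, `replacement`).
#' @export
winsorize <- function(x, sd_limit = 4, unit = 1) {
  if (length(x) < 3) abort("Need at least 3 values.")
  s <- sd(x)
  if (is.na(s) || s == 0) {
    return(list(values = x, log = tibble(index = integer(),
                                         original = numeric(),
                                         replacement = numeric())))
  }
  z <- (x - mean(x)) / s
  hi <- which(z > sd_limit)
  lo <- which(z < -sd_limit)
  keep <- setdiff(seq_along(x), c(hi, lo))
  if (!length(keep)) abort("All values are outliers; cannot Winsorize.")
  out <- x
  if (length(hi)) out[hi] <- max(x[keep]) + unit
  if (length(lo)) out[lo] <- min(x[keep]) - unit
  idx <- sort(c(hi, lo))
  list(values = out,
       log = tibble(index = idx, original = x[idx], replacement = out[idx]))
}

lmm_formula <- function(outcome, interaction = FALSE, autism = FALSE,
                        extra = character()) {
  terms <- c("stimulation", "reactivity", "sex", "age", extra)
  if (autism) terms <- c(terms, "autism_likelihood")
  if (interaction) terms <- c(terms, "stimulation:reactivity")
  stats::reformulate(c(terms, "(1 | subject)"), response = outcome)
}

#' Fit the nap-level linear mixed-effects model
#'
#' Fits `outcome ~ stimulation + reactivity + sex + age + (1 | subject)` by
#' maximum likelihood, with Satterthwaite degrees of freedom for the
#' fixed-effect tests. Variants add the stimulation x reactivity
#' interaction and/or autism-likelihood status as a control covariate.
#' `stimulation` is the 0/1 condition code (baseline vs stimulation) or,
#' for ON/OFF likelihood outcomes within stimulation naps, the 0/1 stimulus
#' window code. Standardized coefficients come from refitting with the
#' outcome and all continuous predictors z-scored (binary 0/1 predictors
#' left as is).
#'
#' @param data Data frame of nap feature rows with columns `subject`,
#'   `stimulation` (0/1), `reactivity`, `sex` (0/1), `age`, the outcome,
#'   and optionally `autism_likelihood` (0/1) and extra covariates.
#' @param outcome Name of the outcome column.
#' @param variant One of `"base"`, `"interaction"`, `"sensitivity_base"`,
#'   `"sensitivity_interaction"`.
#' @param extra_covariates Additional fixed-effect column names (e.g.
#'   `"sleep_arrangement"` for the arousal-density model).
#' @return An object of class `nap_lmm` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_lmm <- function(data, outcome,
                    variant = c("base", "interaction", "sensitivity_base",
                                "sensitivity_interaction"),
                    extra_covariates = character()) {
  variant <- match.arg(variant)
  interaction <- variant %in% c("interaction", "sensitivity_interaction")
  autism <- variant %in% c("sensitivity_base", "sensitivity_interaction")
  data <- as_tibble(data)
  need <- c("subject", "stimulation", "reactivity", "sex", "age", outcome,
            extra_covariates, if (autism) "autism_likelihood")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[need]), ]
  if (length(unique(data$subject)) < 2) abort("Need at least 2 subjects.")
  if (sd(data[[outcome]]) == 0) abort("Outcome is constant.")

  form <- lmm_formula(outcome, interaction, autism, extra_covariates)
  fit <- lmerTest::lmer(form, data = data, REML = FALSE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          check.nobs.vs.nlev = "ignore",
                          check.nobs.vs.nRE = "ignore"))

  # standardized refit: z-score outcome + continuous predictors
  binary <- vapply(data, function(col) {
    is.numeric(col) && all(col %in% c(0, 1))
  }, logical(1))
  zdata <- data
  cont <- setdiff(c(outcome, "reactivity", "age", extra_covariates),
                  names(binary)[binary])
  for (col in cont) {
    if (is.numeric(zdata[[col]]) && sd(zdata[[col]]) > 0) {
      zdata[[col]] <- as.numeric(scale(zdata[[col]]))
    }
  }
  fit_std <- lmerTest::lmer(form, data = zdata, REML = FALSE,
                            control = lme4::lmerControl(
                              check.conv.singular = "ignore",
                              check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore"))

  structure(list(model = fit, model_std = fit_std, variant = variant,
                 outcome = outcome, formula = form,
                 n_naps = nrow(data),
                 n_subjects = length(unique(data$subject))),
            class = "nap_lmm")
}

#' @export
print.nap_lmm <- function(x, ...) {
  cat(sprintf("<nap_lmm> %s (%s): %d naps, %d subjects\n",
              x$outcome, x$variant, x$n_naps, x$n_subjects))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `nap_lmm` object.
#' @param ... Unused.
#' @export
tidy.nap_lmm <- function(x, ...) {
  co <- summary(x$model)$coefficients      # Satterthwaite df and p
  co_std <- summary(x$model_std)$coefficients
  tb <- tibble(
    term = rownames(co),
    std_beta = co_std[, "Estimate"],
    std_conf_low = co_std[, "Estimate"] - 1.96 * co_std[, "Std. Error"],
    std_conf_high = co_std[, "Estimate"] + 1.96 * co_std[, "Std. Error"],
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    df = co[, "df"],
    p_value = co[, "Pr(>|t|)"])
  tb
}

#' @rdname fit_lmm
#' @export
glance.nap_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble(n_naps = x$n_naps, n_subjects = x$n_subjects,
         sigma_subject = vc$sdcor[vc$grp == "subject"],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         logLik = as.numeric(stats::logLik(x$model)),
         AIC = stats::AIC(x$model),
         singular = lme4::isSingular(x$model))
}

#' Model report combining base and interaction fits
#'
#' Main-effect rows are taken from the base model and the interaction row
#' from the interaction model, the reporting convention used throughout the
#' results tables.
#'
#' @inheritParams fit_lmm
#' @param sensitivity If `TRUE`, use the autism-likelihood sensitivity
#'   variants of both models.
#' @return A tibble of terms in results-table shape (standardized beta,
#'   95% CI, unstandardized beta, SE, statistic, df, p, n).
#' @export
lmm_report <- function(data, outcome, extra_covariates = character(),
                       sensitivity = FALSE) {
  v_base <- if (sensitivity) "sensitivity_base" else "base"
  v_int <- if (sensitivity) "sensitivity_interaction" else "interaction"
  f_base <- fit_lmm(data, outcome, v_base, extra_covariates)
  f_int <- fit_lmm(data, outcome, v_int, extra_covariates)
  main <- dplyr::filter(tidy(f_base), .data$term != "(Intercept)")
  inter <- dplyr::filter(tidy(f_int),
                         grepl("stimulation:reactivity|reactivity:stimulation",
                               .data$term))
  dplyr::bind_rows(main, inter) |>
    dplyr::mutate(outcome = outcome, n_naps = f_base$n_naps,
                  n_subjects = f_base$n_subjects, .before = 1)
}

#' Zero-inflated beta model for sleep-stage proportions
#'
#' Generalized LMM for per-nap stage proportions (long format, one row per
#' nap x stage): beta-distributed proportions with a logit mean link, a
#' zero-inflation component for naps without a given stage, stage (N1
#' reference) crossed with condition and sensory reactivity, and a subject
#' random intercept.
#'
#' @param data Long data frame with columns `subject`, `stage` (factor or
#'   character; N1 is the reference), `stimulation` (0/1), `reactivity`,
#'   and `proportion` in `[0, 1)` (exact zeros allowed and handled by the
#'   zero-inflation component).
#' @return An object of class `nap_zib` wrapping the `glmmTMB` fit, with a
#'   [tidy()] method.
#' @export
fit_stage_proportion_model <- function(data) {
  data <- as_tibble(data)
  if (any(data$proportion < 0 | data$proportion > 1)) {
    abort("Stage proportions must lie in [0, 1].")
  }
  data$stage <- stats::relevel(factor(data$stage), ref = "N1")
  # proportions of exactly 1 are nudged inside the open interval
  eps <- 1e-6
  data$proportion <- pmin(data$proportion, 1 - eps)
  fit <- glmmTMB::glmmTMB(
    proportion ~ stage * stimulation * reactivity + (1 | subject),
    ziformula = ~1, family = glmmTMB::beta_family(link = "logit"),
    data = data)
  structure(list(model = fit, n = nrow(data)), class = "nap_zib")
}

#' @rdname fit_stage_proportion_model
#' @param x A `nap_zib` object.
#' @param ... Unused.
#' @export
tidy.nap_zib <- function(x, ...) {
  co <- summary(x$model)$coefficients$cond
  tibble(term = rownames(co), estimate = co[, "Estimate"],
         std_error = co[, "Std. Error"], statistic = co[, "z value"],
         p_value = co[, "Pr(>|z|)"])
}

#' @export
print.nap_zib <- function(x, ...) {
  cat(sprintf("<nap_zib> zero-inflated beta stage-proportion model (%d rows)\n",
              x$n))
  print(tidy(x))
  invisible(x)
}
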