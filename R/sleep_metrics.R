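#' Sleep macroarchitecture summary
#'
#' Derives the standard nap descriptives from a hypnogram: sleep onset is
#' the start of the first non-wake epoch after lights-off (configurable to
#' first N2), sleep offset is the end of the last non-wake epoch, sleep
#' onset latency is onset minus lights-off, wake after sleep onset (WASO)
#' is wake time between onset and offset, nap duration is total sleep time
#' (offset - onset - WASO), efficiency is 100 x total sleep time /
#' (offset - lights_off), and per-stage minutes come from 30-s epoch
#' counts. Stage proportions are relative to total sleep time.
#'
#' @param hyp A [nap_hypnogram()] with `lights_off` set.
#' @param onset_rule `"any_sleep"` (default) or `"first_n2"`.
#' @return A one-row tibble: `sol_min`, `nap_min` (total sleep time),
#'   `waso_min`, `efficiency_pct`, `sleep_onset_s`, `sleep_offset_s`,
#'   `n1_min`, `n2_min`, `n3_min`, `rem_min`, and stage proportions
#'   `prop_n1` ... `prop_rem`.
#' @export
macro_summary <- function(hyp, onset_rule = c("any_sleep", "first_n2")) {
  onset_rule <- match.arg(onset_rule)
  st <- hyp$epoch_stages
  ep <- hyp$epoch_s
  t0 <- hyp$lights_off
  first_ok <- floor(t0 / ep) + 1L
  sleepy <- if (onset_rule == "any_sleep") st != "W" else st == "N2"
  sleepy[seq_len(min(first_ok - 1L, length(st)))] <- FALSE
  if (!any(sleepy)) abort("Insufficient data: no sleep epochs after lights-off.")
  i_on <- which(sleepy)[1]
  i_off <- max(which(st != "W"))
  onset <- (i_on - 1L) * ep
  offset <- i_off * ep
  mid <- st[i_on:i_off]
  waso_min <- sum(mid == "W") * ep / 60
  tst_min <- sum(mid != "W") * ep / 60
  sol_min <- (onset - t0) / 60
  eff <- 100 * tst_min / ((offset - t0) / 60)
  stage_min <- vapply(c("N1", "N2", "N3", "REM"),
                      function(s) sum(mid == s) * ep / 60, numeric(1))
  tibble(sol_min = sol_min, nap_min = tst_min, waso_min = waso_min,
         efficiency_pct = eff, sleep_onset_s = onset,
         sleep_offset_s = offset,
         n1_min = stage_min[["N1"]], n2_min = stage_min[["N2"]],
         n3_min = stage_min[["N3"]], rem_min = stage_min[["REM"]],
         prop_n1 = stage_min[["N1"]] / tst_min,
         prop_n2 = stage_min[["N2"]] / tst_min,
         prop_n3 = stage_min[["N3"]] / tst_min,
         prop_rem = stage_min[["REM"]] / tst_min)
}

#' Arousal density per minute
#'
#' Number of arousals divided by the total sleep period (sleep onset to
#' sleep offset) excluding arousal time, in minutes. Arousals flagged as
#' caused by a known external factor are excluded from the count (and,
#' by default, their duration is also excluded from the denominator).
#'
#' @param hyp A [nap_hypnogram()] with arousal annotations.
#' @param sleep_onset_s,sleep_offset_s Sleep period boundaries in seconds;
#'   computed via [macro_summary()] when omitted.
#' @param exclude_external_time Whether external-arousal time is removed
#'   from the denominator as well (default `TRUE`).
#' @return Arousals per minute (scalar).
#' @export
arousal_density <- function(hyp, sleep_onset_s = NULL, sleep_offset_s = NULL,
                            exclude_external_time = TRUE) {
  if (is.null(sleep_onset_s) || is.null(sleep_offset_s)) {
    ms <- macro_summary(hyp)
    sleep_onset_s <- sleep_onset_s %||% ms$sleep_onset_s
    sleep_offset_s <- sleep_offset_s %||% ms$sleep_offset_s
  }
  ar <- hyp$arousals
  counted <- ar[!ar$external, , drop = FALSE]
  excl_s <- if (exclude_external_time) sum(ar$duration) else sum(counted$duration)
  denom_min <- (sleep_offset_s - sleep_onset_s - excl_s) / 60
  if (denom_min <= 0) {
    abort("Sleep period minus arousal time must be positive.")
  }
  nrow(counted) / denom_min
}
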