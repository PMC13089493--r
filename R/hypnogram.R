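#' Hypnogram with arousal and artifact annotations
#'
#' Stage labels at 30-s epoch resolution plus arousal intervals, a 1-s
#' artifact mask and the lights-off time. Valid stage codes are
#' `W`, `N1`, `N2`, `N3`, `REM`.
#'
#' @param epoch_stages Character vector of stage codes, one per 30-s epoch.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param arousals Tibble with columns `onset`, `duration` (seconds) and
#'   optionally `external` (logical; arousal caused by a known external
#'   factor). Arousal durations must be at least 3 s.
#' @param artifact_mask Logical vector at 1-s resolution, or `NULL` for none.
#' @param lights_off Lights-off time in seconds from recording start.
#' @return An object of class `nap_hypnogram`.
#' @export
#' @examples
#' hyp <- nap_hypnogram(c("W", "N1", "N2", "N2", "N3"))
#' hypnogram_duration(hyp)
nap_hypnogram <- function(epoch_stages, epoch_s = 30,
                          arousals = NULL, artifact_mask = NULL,
                          lights_off = 0) {
  epoch_stages <- as.character(epoch_stages)
  bad <- setdiff(unique(epoch_stages), stage_codes())
  if (length(bad)) {
    abort(sprintf("Unknown stage code(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(arousals)) {
    arousals <- tibble(onset = numeric(), duration = numeric(),
                       external = logical())
  }
  arousals <- as_tibble(arousals)
  if (!"external" %in% names(arousals)) arousals$external <- FALSE
  if (nrow(arousals) && any(arousals$duration < 3)) {
    abort("Arousal durations must be >= 3 s.")
  }
  total_s <- epoch_s * length(epoch_stages)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ceiling(total_s))
  structure(
    list(epoch_stages = epoch_stages, epoch_s = epoch_s,
         arousals = arousals, artifact_mask = as.logical(artifact_mask),
         lights_off = lights_off),
    class = "nap_hypnogram"
  )
}

stage_codes <- function() c("W", "N1", "N2", "N3", "REM")

#' @export
print.nap_hypnogram <- function(x, ...) {
  cat(sprintf("<nap_hypnogram> %d x %g-s epochs (%.1f min), %d arousal(s)\n",
              length(x$epoch_stages), x$epoch_s,
              hypnogram_duration(x) / 60, nrow(x$arousals)))
  print(table(factor(x$epoch_stages, levels = stage_codes())))
  invisible(x)
}

#' @rdname nap_hypnogram
#' @param hyp A `nap_hypnogram`.
#' @return Total covered duration in seconds.
#' @export
hypnogram_duration <- function(hyp) hyp$epoch_s * length(hyp$epoch_stages)

#' Read / write plain-text hypnograms
#'
#' One stage code per line (`W`, `N1`, `N2`, `N3`, `REM`). Unknown codes are
#' rejected with the offending line number.
#'
#' @param path File path.
#' @param epoch_s Epoch length in seconds.
#' @param lights_off Lights-off time carried as metadata (not encoded in the
#'   stage file).
#' @return For `read_hypnogram()`, a [nap_hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30, lights_off = 0) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  bad <- which(!lines %in% stage_codes())
  if (length(bad)) {
    abort(sprintf("Unknown stage code '%s' at line %d of %s",
                  lines[bad[1]], bad[1], path))
  }
  nap_hypnogram(lines, epoch_s = epoch_s, lights_off = lights_off)
}

#' @rdname read_hypnogram
#' @param hyp A [nap_hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$epoch_stages, path)
  invisible(path)
}

## ---- sample-level masks ----------------------------------------------------

#' Per-sample stage labels for a recording
#'
#' @param hyp A [nap_hypnogram()].
#' @param fs Sampling rate in Hz.
#' @param n Number of samples to label. The hypnogram must cover the
#'   recording to within one epoch.
#' @return Character vector of length `n` with one stage code per sample.
#' @export
stage_at_sample <- function(hyp, fs, n) {
  covered <- hypnogram_duration(hyp) * fs
  if (n > covered + hyp$epoch_s * fs) {
    abort("Hypnogram is more than one epoch shorter than the recording.")
  }
  idx <- pmin(floor((seq_len(n) - 1) / (fs * hyp$epoch_s)) + 1L,
              length(hyp$epoch_stages))
  hyp$epoch_stages[idx]
}

#' Sample-level eligibility mask
#'
#' A sample is eligible when its epoch's stage is in `stages`, its 1-s window
#' is not flagged as artifact, and it does not fall inside an arousal.
#'
#' @param hyp A [nap_hypnogram()].
#' @param fs Sampling rate in Hz.
#' @param n Number of samples.
#' @param stages Stage codes counted as eligible (default N2 and N3).
#' @param artifact_mask Optional logical 1-s mask overriding the one stored
#'   in the hypnogram.
#' @return Logical vector of length `n`.
#' @export
eligible_mask <- function(hyp, fs, n, stages = c("N2", "N3"),
                          artifact_mask = NULL) {
  ok <- stage_at_sample(hyp, fs, n) %in% stages
  am <- artifact_mask %||% hyp$artifact_mask
  if (length(am)) {
    sec <- pmin(floor((seq_len(n) - 1) / fs) + 1L, length(am))
    ok <- ok & !am[sec]
  }
  if (nrow(hyp$arousals)) {
    t <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(hyp$arousals))) {
      a0 <- hyp$arousals$onset[i]
      ok[t >= a0 & t < a0 + hyp$arousals$duration[i]] <- FALSE
    }
  }
  ok
}

#' Contiguous runs of TRUE in a logical mask
#'
#' @param mask Logical vector.
#' @return Tibble with columns `start`, `end` (1-based inclusive sample
#'   indices) and `length`.
#' @export
mask_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep],
         length = r$lengths[keep])
}
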