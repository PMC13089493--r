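#' Event-level matching of detected vs annotated events
#'
#' Greedy one-to-one matching by overlap amount: candidate pairs with any
#' temporal overlap (optionally at least `min_overlap` fraction of the
#' shorter event) are sorted by decreasing overlap and assigned so that each
#' detected event matches at most one annotation and vice versa.
#'
#' @param detected,annotated Event tibbles on the same channel and time
#'   base.
#' @param min_overlap Minimum overlap as a fraction of the shorter event
#'   (default 0: any overlap counts).
#' @param check_channel If `TRUE` (default), error when the two tables mix
#'   channels.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
match_events <- function(detected, annotated, min_overlap = 0,
                         check_channel = TRUE) {
  if (check_channel) {
    ch <- unique(c(detected$channel, annotated$channel))
    ch <- ch[!is.na(ch)]
    if (length(ch) > 1) {
      abort("Detected and annotated events must be on a single channel.")
    }
  }
  nd <- nrow(detected)
  na_ <- nrow(annotated)
  pairs <- NULL
  if (nd && na_) {
    ov <- outer(seq_len(nd), seq_len(na_), function(i, j) {
      pmin(detected$offset[i], annotated$offset[j]) -
        pmax(detected$onset[i], annotated$onset[j])
    })
    shorter <- outer(seq_len(nd), seq_len(na_), function(i, j) {
      pmin(detected$offset[i] - detected$onset[i],
           annotated$offset[j] - annotated$onset[j])
    })
    cand <- which(ov > 0 & ov >= min_overlap * shorter, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(-ov[cand]), , drop = FALSE]
      used_d <- logical(nd); used_a <- logical(na_)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_d[i] && !used_a[j]) {
          used_d[i] <- TRUE; used_a[j] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- nd - tp
  fn <- na_ - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Grid search over spindle detection thresholds
#'
#' Evaluates every threshold triple on a set of training naps against their
#' manual annotations, pooling true/false positives across naps
#' (micro-averaged F1; the mean of per-nap F1 is also reported). Features
#' are computed once per nap, so grid cells only re-threshold. Ties are
#' broken toward higher precision, then higher thresholds.
#'
#' @param naps A list of training naps, each a list with elements `x`
#'   (signal), `fs`, `eligible` (logical mask), `annotations` (event
#'   tibble), and optionally `channel`.
#' @param grid Tibble with columns `thr_rms`, `thr_corr`, `thr_relpow`;
#'   e.g. from [tidyr::expand_grid()].
#' @param params Base [spindle_params()] supplying everything except the
#'   thresholds.
#' @param min_overlap Passed to [match_events()].
#' @return A list with `best` (a [spindle_params()]), `best_cell` (one-row
#'   tibble) and `surface` (the full per-cell F1 table, for audit).
#' @export
grid_search_thresholds <- function(naps, grid, params = spindle_params(),
                                   min_overlap = 0) {
  grid <- as_tibble(grid)
  if (!nrow(grid)) abort("Threshold grid is empty.")
  if (!length(naps)) abort("No training naps supplied.")
  for (nap in naps) {
    if (is.null(nap$annotations) || !nrow(nap$annotations)) {
      abort("Every training nap needs manual annotations.")
    }
  }
  feats <- lapply(naps, function(nap) sigma_features(nap$x, nap$fs, params))
  cells <- purrr::pmap(grid, function(thr_rms, thr_corr, thr_relpow, ...) {
    p <- params
    p$thr_rms <- thr_rms; p$thr_corr <- thr_corr; p$thr_relpow <- thr_relpow
    per_nap <- purrr::map2(naps, feats, function(nap, ft) {
      det <- detect_spindles(nap$x, nap$fs, p, eligible = nap$eligible,
                             channel = nap$channel %||% NA_character_,
                             features = ft)
      match_events(det, nap$annotations, min_overlap = min_overlap,
                   check_channel = FALSE)
    })
    pooled <- dplyr::bind_rows(per_nap) |>
      dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp),
                       fn = sum(.data$fn),
                       mean_f1 = mean(.data$f1))
    precision <- with(pooled, if (tp + fp == 0) 0 else tp / (tp + fp))
    recall <- with(pooled, if (tp + fn == 0) 0 else tp / (tp + fn))
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    tibble(thr_rms = thr_rms, thr_corr = thr_corr, thr_relpow = thr_relpow,
           tp = pooled$tp, fp = pooled$fp, fn = pooled$fn,
           precision = precision, recall = recall, f1 = f1,
           mean_f1 = pooled$mean_f1)
  })
  surface <- dplyr::bind_rows(cells)
  best_cell <- surface |>
    dplyr::arrange(dplyr::desc(.data$f1), dplyr::desc(.data$precision),
                   dplyr::desc(.data$thr_rms), dplyr::desc(.data$thr_corr),
                   dplyr::desc(.data$thr_relpow)) |>
    dplyr::slice(1)
  best <- params
  best$thr_rms <- best_cell$thr_rms
  best$thr_corr <- best_cell$thr_corr
  best$thr_relpow <- best_cell$thr_relpow
  list(best = best, best_cell = best_cell, surface = surface)
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's (1980) z-test for H0: rho_xy = rho_xz when both correlations
#' are computed on the same sample and share variable x (here: manual
#' spindle density correlated with two detector variants). Uses the Fisher
#' transform and the back-transformed average correlation.
#'
#' @param r_xy,r_xz The two dependent correlations (with the shared
#'   variable x).
#' @param r_yz Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return A one-row tibble with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(r_xy, r_xz, r_yz, n) {
  rs <- c(r_xy, r_xz, r_yz)
  if (any(abs(rs) >= 1)) abort("All correlations must lie in (-1, 1).")
  if (n <= 3) abort("Need n > 3.")
  z1 <- atanh(r_xy)
  z2 <- atanh(r_xz)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_yz * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_yz^2)
  cov_z <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_z))
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}
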