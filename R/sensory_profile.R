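#' Composite sensory-reactivity score from questionnaire items
#'
#' Scores caregiver questionnaire responses on a 1-5 frequency scale
#' (1 = almost always ... 5 = almost never) across the sensory-sensitivity
#' (13 items) and sensation-avoidance (11 items) quadrants. Items are
#' reverse-scored as `6 - raw` so high scores mean greater reactivity, and
#' the composite is the mean of all items not marked "not applicable"
#' (`NA`). Respondents are never excluded by their number of `NA` answers.
#'
#' @param responses A data frame with one row per subject: a `subject`
#'   column plus 24 item columns (any columns matching `item_cols`).
#'   Values must be in 1-5 or `NA`.
#' @param item_cols Tidy-select expression or character vector of the item
#'   columns (default: columns starting with `"I"`).
#' @param bands If `TRUE`, adds a `band` label: `"typical"`,
#'   `"more_reactive"` (> 1.9) or `"much_more_reactive"` (> 2.5).
#' @return A tibble with `subject`, `reactivity`, `n_items`, `n_na`
#'   (and optionally `band`).
#' @export
#' @examples
#' resp <- tibble::tibble(subject = "s1",
#'                        !!!stats::setNames(as.list(rep(4, 24)),
#'                                           sprintf("I%02d", 1:24)))
#' score_reactivity(resp)
score_reactivity <- function(responses, item_cols = dplyr::starts_with("I"),
                             bands = FALSE) {
  responses <- as_tibble(responses)
  items <- dplyr::select(responses, {{ item_cols }})
  if (!ncol(items)) abort("No item columns found.")
  m <- as.matrix(items)
  if (any(!is.na(m) & (m < 1 | m > 5))) {
    abort("Item values must lie in 1..5 or be NA.")
  }
  rev <- 6 - m
  n_na <- rowSums(is.na(m))
  if (any(n_na == ncol(m))) {
    abort("At least one respondent has all items marked not applicable.")
  }
  out <- tibble(subject = responses$subject %||% seq_len(nrow(m)),
                reactivity = rowMeans(rev, na.rm = TRUE),
                n_items = ncol(m) - n_na, n_na = n_na)
  if (bands) {
    out$band <- dplyr::case_when(
      out$reactivity > 2.5 ~ "much_more_reactive",
      out$reactivity > 1.9 ~ "more_reactive",
      TRUE ~ "typical")
  }
  out
}

#' Cronbach's alpha
#'
#' Internal consistency `alpha = k/(k-1) * (1 - sum(item variances) /
#' var(total score))` with listwise deletion of incomplete rows.
#'
#' @param items Numeric matrix or data frame, subjects x items.
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) abort("Need at least 2 items.")
  if (nrow(m) < 3) abort("Need at least 3 complete responses.")
  total_var <- var(rowSums(m))
  if (total_var == 0) abort("Total-score variance is zero; alpha undefined.")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}
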