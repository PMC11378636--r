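#' Call active compounds from predicted sensitivity scores
#'
#' A compound is active in a cell line when its predicted sensitivity
#' score is strictly below the threshold (default -2); a score exactly at
#' the threshold is inactive.
#'
#' @param scores numeric matrix (cell lines x drugs) or vector of
#'   predicted scores; must be finite.
#' @param threshold activity cutoff (default -2).
#' @return Logical object of the same shape as `scores`.
#' @export
#' @examples
#' call_active(c(-3, -2, 0))
call_active <- function(scores, threshold = -2) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  scores < threshold
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric exact test; the two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table, the convention
#' of [stats::fisher.test()]. The reported odds ratio is the sample odds
#' ratio `ad/bc`, with the usual `Inf`/0 conventions when a cell is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts with a positive
#'   grand total.
#' @return List with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("grand total must be positive", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Per-drug selectivity for one cancer group
#'
#' For each drug, cross-tabulates activity (strict score-below-threshold
#' call) against membership in the given cancer group over the whole
#' screen, applies Fisher's exact test, and adjusts the p-values across
#' drugs (Benjamini-Hochberg). A (drug, group) pair is flagged
#' `selective` when the odds ratio exceeds 1 (enrichment of activity in
#' the group) and the adjusted p is below `q_cutoff`.
#'
#' @param screen data frame with columns `cell_line`, `group`, `drug`,
#'   and either `active` (logical) or `score` (numeric, thresholded at
#'   `threshold`).
#' @param group the in-group label to test; all other labels form the
#'   out-group.
#' @param threshold score cutoff when `active` is absent (default -2).
#' @param q_cutoff adjusted-p cutoff for the selectivity flag (default
#'   0.05).
#' @return A tibble of class `selectivity_result`, one row per drug:
#'   counts `active_in`, `active_out`, `inactive_in`, `inactive_out`,
#'   `odds_ratio`, `p_value`, `q_value`, `selective`.
#' @export
drug_selectivity <- function(screen, group, threshold = -2, q_cutoff = 0.05) {
  stopifnot(is.data.frame(screen),
            all(c("cell_line", "group", "drug") %in% names(screen)))
  if (!"active" %in% names(screen)) {
    if (!"score" %in% names(screen)) stop("need an active or score column", call. = FALSE)
    screen$active <- call_active(screen$score, threshold)
  }
  groups <- unique(screen$group)
  if (length(groups) < 2L) stop("need at least two cancer groups", call. = FALSE)
  if (!group %in% groups) stop("unknown group: ", group, call. = FALSE)
  in_grp <- screen$group == group
  res <- screen |>
    dplyr::mutate(in_group = in_grp) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      active_in = sum(.data$active & .data$in_group),
      active_out = sum(.data$active & !.data$in_group),
      inactive_in = sum(!.data$active & .data$in_group),
      inactive_out = sum(!.data$active & !.data$in_group),
      .groups = "drop")
  tests <- purrr::pmap(res[, c("active_in", "active_out",
                               "inactive_in", "inactive_out")],
    function(active_in, active_out, inactive_in, inactive_out) {
      fisher_exact(matrix(c(active_in, inactive_in, active_out, inactive_out), 2L))
    })
  res$odds_ratio <- vapply(tests, `[[`, numeric(1), "odds_ratio")
  res$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  res$q_value <- adjust_pvalues(res$p_value)
  res$group <- group
  res$selective <- !is.nan(res$odds_ratio) & res$odds_ratio > 1 &
    res$q_value < q_cutoff
  class(res) <- c("selectivity_result", class(res))
  res
}

#' Classify drugs by their fraction of active cell lines
#'
#' Screen-wide effectiveness classes: drugs active in more than
#' `effective_frac` of all cell lines are "non-selective effective",
#' drugs active in fewer than `1 - effective_frac` are "ineffective", the
#' rest "intermediate".
#'
#' @param screen data frame as in [drug_selectivity()].
#' @param threshold score cutoff when `active` is absent.
#' @param effective_frac fraction-of-active-lines cutoff (default 0.9).
#' @return Tibble with `drug`, `frac_active`, `class`.
#' @export
classify_drugs <- function(screen, threshold = -2, effective_frac = 0.9) {
  if (!"active" %in% names(screen)) {
    screen$active <- call_active(screen$score, threshold)
  }
  screen |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(frac_active = mean(.data$active), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$frac_active > effective_frac ~ "non_selective_effective",
      .data$frac_active < 1 - effective_frac ~ "ineffective",
      TRUE ~ "intermediate"))
}
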