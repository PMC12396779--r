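# Grading answers against gold letters, accuracy with Wilson intervals,
# and the paired/unpaired exact tests used when comparing models and
# confidence signals.

#' Grade parsed answers against gold letters
#'
#' Joins scored answers to their items and marks correctness by exact
#' letter equality. Records with `parse_status = "failed"` are excluded and
#' tallied; a parsed letter outside the item's option set is counted
#' incorrect with a warning. Where a response log contains several records
#' for one item, the first in log order is graded.
#'
#' @param items item tibble from [read_mcq_dataset()] or [simulate_items()].
#' @param scored scored-answer tibble from [score_responses()].
#' @return Tibble with one row per graded answer: all `scored` columns plus
#'   `gold` and `correct`. Attribute `"exclusions"` carries the exclusion
#'   tally (failed parses plus records whose item is unknown).
#' @export
grade_answers <- function(items, scored) {
  stopifnot(is.data.frame(items), is.data.frame(scored))
  scored <- dplyr::distinct(scored, .data$item_id, .data$model_tag,
                            .data$prompt_variant, .keep_all = TRUE)
  key <- dplyr::select(items, "item_id", "gold", "options")
  graded <- dplyr::inner_join(scored, key, by = "item_id")
  n_unknown_item <- nrow(scored) - nrow(graded)
  if (n_unknown_item > 0) {
    warn(paste0(n_unknown_item,
                " record(s) reference unknown item_id(s); dropped."))
  }
  n_failed <- sum(graded$parse_status == "failed")
  graded <- dplyr::filter(graded, .data$parse_status != "failed")
  bad_letter <- !is.na(graded$letter) &
    !purrr::map2_lgl(graded$letter, graded$options, ~ .x %in% names(.y))
  if (any(bad_letter)) {
    warn(paste0(sum(bad_letter),
                " parsed letter(s) outside the item's options; ",
                "counted incorrect."))
  }
  graded <- dplyr::mutate(graded, correct = .data$letter == .data$gold)
  graded <- dplyr::select(graded, -"options")
  exclusions <- c(
    parse_failed = n_failed,
    unknown_item = n_unknown_item
  )
  prior <- attr(scored, "exclusions")
  if (!is.null(prior)) {
    exclusions <- c(exclusions,
                    prior[setdiff(names(prior), "parse_failed")])
  }
  attr(graded, "exclusions") <- exclusions
  graded
}

#' Accuracy with a Wilson confidence interval
#'
#' @param graded graded-answer tibble from [grade_answers()], or a logical
#'   vector of correctness.
#' @param ci_level confidence level.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
accuracy_ci <- function(graded, ci_level = 0.95) {
  correct <- if (is.data.frame(graded)) graded$correct else graded
  stopifnot(is.logical(correct))
  if (length(correct) == 0) abort("No graded answers; accuracy undefined.")
  wilson_ci(sum(correct), length(correct), ci_level)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing hypergeometric probabilities
#' no larger than that of the observed table (the classic two-sided
#' convention); used to compare accuracies between models.
#'
#' @param a,b,c,d nonnegative cell counts, row-wise
#'   (`a b` / `c d`).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Cell counts must be nonnegative integers.")
  }
  if (sum(counts) == 0) abort("All cells are zero; test undefined.")
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' McNemar test for paired binary outcomes
#'
#' Two-sided test on the discordant-pair counts: exact binomial when
#' `b + c < 25`, otherwise chi-square with continuity correction. Used to
#' compare above-threshold indicator agreement between two confidence
#' signals on the same items.
#'
#' @param b,c discordant counts (signal A only / signal B only).
#' @return Two-sided p-value.
#' @examples
#' mcnemar_paired(10, 0)
#' @export
mcnemar_paired <- function(b, c) {
  if (b < 0 || c < 0) abort("Discordant counts must be nonnegative.")
  n <- b + c
  if (n == 0) return(1)
  if (n < 25) {
    min(1, 2 * pbinom(min(b, c), n, 0.5))
  } else {
    x2 <- (abs(b - c) - 1)^2 / n
    pchisq(x2, df = 1, lower.tail = FALSE)
  }
}
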