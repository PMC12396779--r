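# ROC analysis: AUROC via the Mann-Whitney statistic (midrank formulation,
# O(n log n)), DeLong variance/covariance for confidence intervals and
# paired AUROC comparison.
#
# Orientation convention: the positive class is the CORRECT answer and
# higher scores mean more confidence. Doubt-oriented signals (entropy,
# perplexity) must be negated before entry.

# DeLong structural components. For positives X (n1) and negatives Y (n0):
#   V10_i = mean_j psi(X_i, Y_j),  V01_j = mean_i psi(X_i, Y_j),
#   psi = 1 if X > Y, 1/2 if tied, 0 otherwise.
# Midrank identity: sum_j psi(X_i, .) = midrank_combined(X_i) - midrank_X(X_i).
delong_components <- function(scores, outcomes) {
  x <- scores[outcomes]
  y <- scores[!outcomes]
  n1 <- length(x)
  n0 <- length(y)
  rc <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rc[seq_len(n1)] - rx) / n0
  v01 <- 1 - (rc[n1 + seq_len(n0)] - ry) / n1
  auc <- (sum(rc[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

check_two_classes <- function(outcomes) {
  if (!any(outcomes) || all(outcomes)) {
    abort("AUROC undefined: both classes (correct and incorrect) required.")
  }
}

#' ROC curve and AUROC with DeLong confidence interval
#'
#' Computes the ROC curve and the area under it for a confidence score
#' against binary correctness. The AUROC is the Mann-Whitney statistic:
#' the probability that a random correct answer scores higher than a random
#' incorrect one, ties counting one half; the confidence interval uses the
#' DeLong variance with a normal approximation. Candidate thresholds are
#' the observed score values (descending), with `score >= threshold`
#' counting as above.
#'
#' @param scores numeric confidence scores (higher = more confident).
#' @param outcomes logical, `TRUE` for correct answers (the positive class).
#' @param ci_level confidence level for the AUROC interval.
#' @return Object of class `roc_analysis`: list with `curve` (tibble
#'   `threshold`, `tpr`, `fpr`), `auc`, `auc_ci`, `var_auc`, `n_pos`,
#'   `n_neg`, `ci_level`, and `components` (for paired tests).
#' @examples
#' roc_analysis(c(.9, .8, .1), c(TRUE, TRUE, FALSE))$auc
#' @export
roc_analysis <- function(scores, outcomes, ci_level = 0.95) {
  stopifnot(length(scores) == length(outcomes), is.logical(outcomes))
  if (any(is.na(scores)) || any(is.na(outcomes))) {
    abort("NA in scores or outcomes; exclude records before ROC analysis.")
  }
  check_two_classes(outcomes)
  comp <- delong_components(scores, outcomes)
  var_auc <- stats::var(comp$v10) / comp$n1 + stats::var(comp$v01) / comp$n0
  z <- qnorm(1 - (1 - ci_level) / 2)
  half <- z * sqrt(var_auc)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  o_sorted <- outcomes[ord]
  n <- length(scores)
  last_of_value <- which(c(s_sorted[-1] != s_sorted[-n], TRUE))
  curve <- tibble(
    threshold = s_sorted[last_of_value],
    tpr = cumsum(o_sorted)[last_of_value] / comp$n1,
    fpr = cumsum(!o_sorted)[last_of_value] / comp$n0
  )
  structure(
    list(
      curve = curve,
      auc = comp$auc,
      auc_ci = c(max(0, comp$auc - half), min(1, comp$auc + half)),
      var_auc = var_auc,
      n_pos = comp$n1,
      n_neg = comp$n0,
      ci_level = ci_level,
      components = comp
    ),
    class = "roc_analysis"
  )
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf(
    "<roc_analysis> AUROC %.4f (%d%% CI %.4f-%.4f), n_pos %d, n_neg %d\n",
    x$auc, round(100 * x$ci_level), x$auc_ci[1], x$auc_ci[2],
    x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' DeLong paired test for two correlated AUROCs
#'
#' Compares the AUROCs of two confidence scores computed on the same items
#' (same outcomes) using the DeLong structural-components covariance;
#' `z = (aucA - aucB) / se(diff)`, two-sided normal p-value.
#'
#' @param scores_a,scores_b numeric scores for the same items.
#' @param outcomes logical correctness, shared by both score sets.
#' @return One-row tibble: `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  stopifnot(length(scores_a) == length(outcomes),
            length(scores_b) == length(outcomes))
  check_two_classes(outcomes)
  ca <- delong_components(scores_a, outcomes)
  cb <- delong_components(scores_b, outcomes)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n0
  diff <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (abs(diff) < 1e-12) {
      z <- 0
      p <- 1
    } else {
      abort("DeLong variance of the AUC difference is zero but AUCs differ.")
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = diff, z = z, p_value = p)
}

#' Youden-optimal threshold
#'
#' Threshold maximizing Youden's J = TPR - FPR over the observed score
#' values (no midpoints); ties are broken toward the HIGHEST threshold, the
#' conservative choice that flags the fewest answers as confident.
#'
#' @param roc a [roc_analysis()] object.
#' @return The optimal threshold (numeric scalar).
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  j <- roc$curve$tpr - roc$curve$fpr
  best <- which(j >= max(j) - 1e-12)
  # curve thresholds are sorted descending, so the first maximizer is highest
  roc$curve$threshold[best[1]]
}

#' Threshold-conditional performance block
#'
#' Rates at a fixed confidence threshold, with Wilson confidence intervals:
#' TPR = share of correct answers scoring at or above the threshold, FPR =
#' share of incorrect answers at or above it, and the accuracy among
#' answers above versus below. `score >= threshold` counts as above
#' (set `strict = TRUE` for `>`). Empty strata yield `NA` estimates and
#' are flagged.
#'
#' @param scores,outcomes as in [roc_analysis()].
#' @param threshold confidence threshold.
#' @param ci_level confidence level for the Wilson intervals.
#' @param strict use strictly-greater instead of `>=`.
#' @return One-row tibble: `threshold`, `tpr`, `tpr_low`, `tpr_high`,
#'   `fpr`, `fpr_low`, `fpr_high`, `acc_above`, `acc_above_low`,
#'   `acc_above_high`, `acc_below`, `acc_below_low`, `acc_below_high`,
#'   `n_above`, `n_below`, `empty_stratum`.
#' @export
threshold_block <- function(scores, outcomes, threshold, ci_level = 0.95,
                            strict = FALSE) {
  stopifnot(length(scores) == length(outcomes))
  above <- if (strict) scores > threshold else scores >= threshold
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  wils <- function(x, n) {
    if (n == 0) {
      return(tibble(estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n = 0L))
    }
    wilson_ci(x, n, ci_level)
  }
  w_tpr <- wils(sum(above & outcomes), n1)
  w_fpr <- wils(sum(above & !outcomes), n0)
  w_acc_above <- wils(sum(above & outcomes), sum(above))
  w_acc_below <- wils(sum(!above & outcomes), sum(!above))
  out <- tibble(
    threshold = threshold,
    tpr = w_tpr$estimate, tpr_low = w_tpr$ci_low, tpr_high = w_tpr$ci_high,
    fpr = w_fpr$estimate, fpr_low = w_fpr$ci_low, fpr_high = w_fpr$ci_high,
    acc_above = w_acc_above$estimate, acc_above_low = w_acc_above$ci_low,
    acc_above_high = w_acc_above$ci_high,
    acc_below = w_acc_below$estimate, acc_below_low = w_acc_below$ci_low,
    acc_below_high = w_acc_below$ci_high,
    n_above = as.integer(sum(above)),
    n_below = as.integer(sum(!above)),
    empty_stratum = sum(above) == 0 || sum(!above) == 0
  )
  if (out$empty_stratum) {
    warn("One threshold stratum is empty; its accuracy is undefined (NA).")
  }
  out
}
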