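# broom-style tidiers for the package's result objects.

#' Tidy a ROC analysis
#'
#' @param x a [roc_analysis()] object.
#' @param ... unused.
#' @return The ROC curve as a tibble (`threshold`, `tpr`, `fpr`).
#' @export
tidy.roc_analysis <- function(x, ...) {
  x$curve
}

#' One-row summary of a ROC analysis
#'
#' @param x a [roc_analysis()] object.
#' @param ... unused.
#' @return Tibble with `auc`, `auc_low`, `auc_high`, `n_pos`, `n_neg`,
#'   `ci_level`.
#' @export
glance.roc_analysis <- function(x, ...) {
  tibble(
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
    n_pos = x$n_pos, n_neg = x$n_neg, ci_level = x$ci_level
  )
}

#' Tidy a calibration report
#'
#' @param x a [calibration_report()] object.
#' @param ... unused.
#' @return The bin table as a tibble (one row per equal-mass bin).
#' @export
tidy.calibration_report <- function(x, ...) {
  x$bins
}

#' One-row summary of a calibration report
#'
#' @param x a [calibration_report()] object.
#' @param ... unused.
#' @return Tibble with `metric`, `ace`, `ace_low`, `ace_high`, `brier`,
#'   `brier_low`, `brier_high`, `n_bins`, `n`, `flag_poor`.
#' @export
glance.calibration_report <- function(x, ...) {
  tibble(
    metric = x$metric,
    ace = x$ace, ace_low = x$ace_ci[[1]], ace_high = x$ace_ci[[2]],
    brier = x$brier, brier_low = x$brier_ci[[1]],
    brier_high = x$brier_ci[[2]],
    n_bins = x$n_bins, n = x$n, flag_poor = x$flag_poor
  )
}

#' Tidy a full evaluation
#'
#' @param x a [run_evaluation()] result.
#' @param ... unused.
#' @return The per-metric discrimination tibble.
#' @export
tidy.confidence_evaluation <- function(x, ...) {
  x$discrimination
}

#' One-row summary of a full evaluation
#'
#' @param x a [run_evaluation()] result.
#' @param ... unused.
#' @return Tibble with overall accuracy, the AUROC of each analyzed
#'   signal, and the number of graded and excluded records.
#' @export
glance.confidence_evaluation <- function(x, ...) {
  aucs <- setNames(x$discrimination$auroc,
                   paste0("auroc_", x$discrimination$metric))
  dplyr::bind_cols(
    tibble(
      accuracy = x$accuracy$estimate,
      accuracy_low = x$accuracy$ci_low,
      accuracy_high = x$accuracy$ci_high
    ),
    as_tibble(as.list(aucs)),
    tibble(
      n_graded = x$accuracy$n,
      n_excluded = sum(x$exclusions)
    )
  )
}
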