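# ggplot2 graphics: ROC curves, reliability diagrams, and violin plots of
# the score distributions by correctness.

#' @describeIn roc_analysis ROC curve plot with the chance diagonal.
#' @param object a `roc_analysis` object.
#' @param ... unused.
#' @export
autoplot.roc_analysis <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate",
      y = "True positive rate",
      title = sprintf("AUROC %.3f (%d%% CI %.3f-%.3f)", object$auc,
                      round(100 * object$ci_level),
                      object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn calibration_report Reliability diagram (accuracy vs mean
#'   confidence per equal-mass bin) against the identity line.
#' @param object a `calibration_report` object.
#' @param ... unused.
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$conf_mean, y = .data$acc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean confidence (bin)", y = "Accuracy (bin)", size = "n",
      title = sprintf("%s: ACE %.3f, Brier %.3f%s", object$metric,
                      object$ace, object$brier,
                      if (object$flag_poor) " (poor calibration)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Compare ROC curves of all analyzed signals
#'
#' @param evaluation a [run_evaluation()] result.
#' @return A ggplot with one ROC curve per confidence signal.
#' @export
plot_roc_curves <- function(evaluation) {
  stopifnot(inherits(evaluation, "confidence_evaluation"))
  curves <- dplyr::bind_rows(
    purrr::imap(evaluation$roc,
                ~ dplyr::mutate(tidy(.x), metric = .y, .before = 1))
  )
  labs <- sprintf("%s (%.2f)", evaluation$discrimination$metric,
                  evaluation$discrimination$auroc)
  names(labs) <- evaluation$discrimination$metric
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$metric)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::scale_colour_discrete(labels = labs) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Signal (AUROC)") +
    ggplot2::theme_minimal()
}

#' Violin plot of a confidence signal by correctness
#'
#' Emulates the classic presentation of confidence distributions for
#' correct versus incorrect answers.
#'
#' @param graded graded tibble (component `graded` of a
#'   [run_evaluation()] result).
#' @param metric which signal to plot (column name logic as in the
#'   discrimination analysis).
#' @return A ggplot.
#' @export
plot_score_violin <- function(graded, metric = "token_prob") {
  score <- oriented_score(graded, metric)
  df <- tibble(
    score = natural_threshold(metric, score),
    correct = factor(ifelse(graded$correct, "correct", "incorrect"),
                     levels = c("incorrect", "correct"))
  )
  df <- dplyr::filter(df, !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correct, y = .data$score,
                                   fill = .data$correct)) +
    ggplot2::geom_violin(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
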