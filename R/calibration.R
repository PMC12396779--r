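# Calibration: adaptive (equal-mass) binning, adaptive calibration error,
# Brier score, percentile-bootstrap confidence intervals and paired
# bootstrap p-values, and reliability-curve points.
#
# Only probability-scale signals are calibrated (normalized expressed
# confidence and raw token probability); entropy and perplexity are not
# probabilities and enter discrimination analyses only.

#' Equal-mass (adaptive) confidence bins
#'
#' Sorts confidences ascending (stable on input order) and splits them into
#' `n_bins` contiguous groups whose sizes differ by at most one, larger
#' bins first. Ties in confidence may span bin boundaries; no tie merging
#' is performed, which keeps bin masses exactly balanced on skewed
#' (e.g. all-95) confidence distributions.
#'
#' @param confidences numeric vector in `[0, 1]`.
#' @param outcomes logical correctness vector, same length.
#' @param n_bins number of bins (default 10).
#' @return Tibble with one row per bin: `bin`, `n`, `conf_mean`, `acc`,
#'   `conf_low`, `conf_high`.
#' @export
adaptive_bins <- function(confidences, outcomes, n_bins = 10) {
  n <- length(confidences)
  stopifnot(length(outcomes) == n)
  if (n_bins < 1) abort("n_bins must be >= 1.")
  if (n < n_bins) {
    abort(paste0("Need at least as many records (", n, ") as bins (",
                 n_bins, "); use a smaller n_bins."))
  }
  if (any(is.na(confidences)) || any(confidences < 0 | confidences > 1)) {
    abort("Confidences must be in [0, 1] with no NA.")
  }
  ord <- order(confidences)  # stable: ties keep input order
  conf <- confidences[ord]
  out <- outcomes[ord]
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- c(rep(base + 1L, extra), rep(base, n_bins - extra))
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, head(idx_end, -1) + 1L)
  tibble(
    bin = seq_len(n_bins),
    n = as.integer(sizes),
    conf_mean = purrr::map2_dbl(idx_start, idx_end,
                                ~ mean(conf[.x:.y])),
    acc = purrr::map2_dbl(idx_start, idx_end, ~ mean(out[.x:.y])),
    conf_low = conf[idx_start],
    conf_high = conf[idx_end]
  )
}

#' Adaptive calibration error (ACE)
#'
#' Mean absolute gap between accuracy and mean confidence across
#' equal-mass confidence bins:
#' `ACE = (1/B) * sum_b |acc(b) - conf_mean(b)|`. With `n_bins = 1` this is
#' exactly `|overall accuracy - overall mean confidence|`. An ACE above
#' 0.25 is conventionally flagged as poor calibration.
#'
#' @inheritParams adaptive_bins
#' @return ACE in `[0, 1]`.
#' @export
ace <- function(confidences, outcomes, n_bins = 10) {
  bins <- adaptive_bins(confidences, outcomes, n_bins)
  mean(abs(bins$acc - bins$conf_mean))
}

#' Brier score
#'
#' Mean squared difference between the probabilistic confidence and the
#' binary correctness outcome; lower is better, and a constant forecast at
#' the base rate attains `p * (1 - p)` in expectation.
#'
#' @inheritParams adaptive_bins
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(confidences, outcomes) {
  n <- length(confidences)
  if (n == 0) abort("Empty input; Brier score undefined.")
  stopifnot(length(outcomes) == n)
  mean((confidences - as.numeric(outcomes))^2)
}

#' Percentile bootstrap confidence interval for a calibration statistic
#'
#' Resamples records with replacement `reps` times and returns the
#' percentile interval of the statistic. Reproducible given `seed`.
#' Degenerate resamples (single outcome class) are redrawn when
#' `require_both_classes` is set, with a retry cap.
#'
#' @param statistic function of `(confidences, outcomes)` returning a
#'   scalar.
#' @param confidences,outcomes the data.
#' @param reps bootstrap replicates (>= 200).
#' @param seed integer seed (mandatory).
#' @param ci_level confidence level.
#' @param require_both_classes redraw resamples containing one class only.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(statistic, confidences, outcomes, reps = 2000,
                         seed, ci_level = 0.95,
                         require_both_classes = FALSE) {
  if (reps < 200) abort("Use at least 200 bootstrap replicates.")
  if (missing(seed)) abort("A seed is mandatory for bootstrap resampling.")
  n <- length(confidences)
  stopifnot(length(outcomes) == n, n >= 1)
  stats_boot <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (!require_both_classes ||
            (any(outcomes[idx]) && !all(outcomes[idx]))) {
          return(statistic(confidences[idx], outcomes[idx]))
        }
      }
      abort("Could not draw a non-degenerate bootstrap resample.")
    }, numeric(1))
  })
  alpha <- 1 - ci_level
  out <- unname(quantile(stats_boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  c(low = out[1], high = out[2])
}

#' Paired bootstrap p-value for comparing two calibration statistics
#'
#' Jointly resamples items and compares `statistic` between two confidence
#' vectors sharing the outcomes. The two-sided p-value is
#' `2 * min(P(diff* <= 0), P(diff* >= 0))` with add-one smoothing
#' `(r + 1) / (reps + 1)`, so the smallest attainable p is
#' `2 / (reps + 1)`.
#'
#' @param statistic function of `(confidences, outcomes)`.
#' @param confidences_a,confidences_b paired confidence vectors.
#' @param outcomes shared correctness vector.
#' @inheritParams bootstrap_ci
#' @return Two-sided p-value.
#' @export
bootstrap_paired_pvalue <- function(statistic, confidences_a, confidences_b,
                                    outcomes, reps = 2000, seed,
                                    require_both_classes = FALSE) {
  if (reps < 200) abort("Use at least 200 bootstrap replicates.")
  if (missing(seed)) abort("A seed is mandatory for bootstrap resampling.")
  n <- length(outcomes)
  stopifnot(length(confidences_a) == n, length(confidences_b) == n)
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (!require_both_classes ||
            (any(outcomes[idx]) && !all(outcomes[idx]))) {
          return(statistic(confidences_a[idx], outcomes[idx]) -
                   statistic(confidences_b[idx], outcomes[idx]))
        }
      }
      abort("Could not draw a non-degenerate bootstrap resample.")
    }, numeric(1))
  })
  p_low <- (sum(diffs <= 0) + 1) / (reps + 1)
  p_high <- (sum(diffs >= 0) + 1) / (reps + 1)
  min(1, 2 * min(p_low, p_high))
}

#' Calibration-curve (reliability-diagram) points
#'
#' @param bins bin tibble from [adaptive_bins()].
#' @return Tibble of points `(conf_mean, acc, n)` sorted by `conf_mean`,
#'   ready to plot against the identity line.
#' @export
calibration_curve <- function(bins) {
  stopifnot(all(c("conf_mean", "acc", "n") %in% names(bins)))
  dplyr::arrange(dplyr::select(bins, "conf_mean", "acc", "n"),
                 .data$conf_mean)
}

#' Full calibration report for one confidence signal
#'
#' Computes equal-mass bins, ACE and Brier score with percentile-bootstrap
#' confidence intervals, and flags poor calibration (ACE > 0.25).
#'
#' @inheritParams adaptive_bins
#' @param reps bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param ci_level confidence level.
#' @param metric label for the signal (carried into reports).
#' @return Object of class `calibration_report`: list with `metric`, `ace`,
#'   `ace_ci`, `brier`, `brier_ci`, `bins`, `n_bins`, `n`, `flag_poor`.
#' @export
calibration_report <- function(confidences, outcomes, n_bins = 10,
                               reps = 2000, seed, ci_level = 0.95,
                               metric = "confidence") {
  bins <- adaptive_bins(confidences, outcomes, n_bins)
  ace_hat <- mean(abs(bins$acc - bins$conf_mean))
  brier_hat <- brier_score(confidences, outcomes)
  ace_stat <- function(conf, out) ace(conf, out, n_bins)
  ace_ci <- bootstrap_ci(ace_stat, confidences, outcomes, reps, seed,
                         ci_level)
  brier_ci <- bootstrap_ci(brier_score, confidences, outcomes, reps,
                           seed, ci_level)
  structure(
    list(
      metric = metric,
      ace = ace_hat, ace_ci = ace_ci,
      brier = brier_hat, brier_ci = brier_ci,
      bins = bins, n_bins = n_bins, n = length(confidences),
      ci_level = ci_level, reps = reps,
      flag_poor = ace_hat > 0.25
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_report> %s: ACE %.4f (CI %.4f-%.4f)%s, ",
           "Brier %.4f (CI %.4f-%.4f), %d bins, n %d\n"),
    x$metric, x$ace, x$ace_ci[1], x$ace_ci[2],
    if (x$flag_poor) " [poorly calibrated]" else "",
    x$brier, x$brier_ci[1], x$brier_ci[2], x$n_bins, x$n
  ))
  invisible(x)
}
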