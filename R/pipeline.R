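# End-to-end evaluation: parse -> score -> grade -> discrimination ->
# calibration -> report tables. All randomness (bootstrap only) is driven
# by one user-supplied seed, so identical inputs + config + seed give
# byte-identical report CSVs.

METRICS <- c("expressed", "token_prob", "entropy", "perplexity")
# probability-scale signals eligible for calibration
CALIBRATABLE <- c("expressed", "token_prob")

# Oriented score column for ROC entry: higher = more confident. Entropy
# and perplexity are doubt scores and are negated.
oriented_score <- function(scored, metric) {
  switch(metric,
    expressed = scored$expressed_conf_norm,
    token_prob = scored$token_prob,
    entropy = -scored$entropy_bits,
    perplexity = -scored$perplexity,
    abort(paste0("Unknown metric '", metric, "'."))
  )
}

# report thresholds on the metric's natural scale
natural_threshold <- function(metric, oriented) {
  if (metric %in% c("entropy", "perplexity")) -oriented else oriented
}

#' Run the full confidence-evaluation pipeline
#'
#' Parses a response log, computes all requested uncertainty scores,
#' grades against gold letters, and produces the discrimination analysis
#' (AUROC with DeLong CI per signal, DeLong paired test of each signal
#' against expressed confidence, Youden-optimal threshold and
#' threshold-conditional rates with McNemar comparisons) and the
#' calibration analysis (equal-mass-bin ACE and Brier with bootstrap CIs
#' and a paired bootstrap p-value for expressed vs token probability).
#' Gold answers are never consulted during score computation, only at the
#' grading step.
#'
#' @param items item tibble ([read_mcq_dataset()] / [simulate_items()]).
#' @param log response-log tibble ([read_response_log()] /
#'   [simulate_responses()]).
#' @param metrics confidence signals to analyze (subset of `"expressed"`,
#'   `"token_prob"`, `"entropy"`, `"perplexity"`).
#' @param n_bins equal-mass calibration bins.
#' @param bootstrap_reps bootstrap replicates for calibration CIs and
#'   paired p-values.
#' @param seed integer seed driving all bootstrap resampling (mandatory
#'   when `bootstrap_reps > 0`).
#' @param ci_level confidence level used throughout.
#' @param confidence_scale_max scale of the verbalized confidence (100
#'   or 1).
#' @param output_dir if non-`NULL`, report CSVs and a run manifest are
#'   written there.
#' @return Object of class `confidence_evaluation`: list with `accuracy`,
#'   `discrimination` (per-metric tibble), `delong` (pairwise tests vs
#'   expressed), `roc` (named list of [roc_analysis()] objects),
#'   `calibration` (named list of [calibration_report()] objects),
#'   `calibration_comparison`, `exclusions`, `graded`, `config`.
#' @export
run_evaluation <- function(items, log,
                           metrics = METRICS,
                           n_bins = 10,
                           bootstrap_reps = 2000,
                           seed = NULL,
                           ci_level = 0.95,
                           confidence_scale_max = 100,
                           output_dir = NULL) {
  metrics <- match.arg(metrics, METRICS, several.ok = TRUE)
  if (length(metrics) == 0) abort("`metrics` must be non-empty.")
  if (bootstrap_reps > 0 && is.null(seed)) {
    abort("A seed is mandatory when bootstrap_reps > 0.")
  }
  if (nrow(log) == 0) abort("Response log is empty; nothing to evaluate.")

  n_opts <- max(purrr::map_int(items$options, length))
  option_letters <- OPTION_LETTERS[seq_len(n_opts)]
  parsed <- parse_responses(log, confidence_scale_max)
  scored <- score_responses(log, parsed, option_letters,
                            confidence_scale_max)
  graded <- grade_answers(items, scored)
  if (nrow(graded) == 0) abort("No gradable records after exclusions.")
  if (all(graded$correct) || !any(graded$correct)) {
    abort(paste0("Only one correctness class present (accuracy ",
                 mean(graded$correct),
                 "); discrimination analyses are undefined."))
  }

  accuracy <- accuracy_ci(graded, ci_level)

  metric_data <- purrr::map(metrics, function(m) {
    sc <- oriented_score(graded, m)
    keep <- !is.na(sc)
    if (!any(keep)) {
      abort(paste0("Metric '", m, "' absent from the scored log."))
    }
    list(metric = m, scores = sc[keep], outcomes = graded$correct[keep],
         keep = keep)
  })
  names(metric_data) <- metrics

  rocs <- purrr::map(metric_data, function(d) {
    roc_analysis(d$scores, d$outcomes, ci_level)
  })

  disc_rows <- purrr::map(metric_data, function(d) {
    roc <- rocs[[d$metric]]
    thr <- youden_threshold(roc)
    blk <- threshold_block(d$scores, d$outcomes, thr, ci_level)
    dplyr::bind_cols(
      tibble(
        metric = d$metric,
        n = length(d$scores),
        auroc = roc$auc,
        auroc_low = roc$auc_ci[1],
        auroc_high = roc$auc_ci[2],
        optimal_threshold = natural_threshold(d$metric, thr)
      ),
      dplyr::select(blk, -"threshold")
    )
  })
  discrimination <- dplyr::bind_rows(disc_rows)

  # paired comparisons against expressed confidence (DeLong on the AUROC,
  # McNemar on the above-threshold indicators), on records where both
  # signals are available
  delong <- NULL
  if ("expressed" %in% metrics && length(metrics) > 1) {
    delong_rows <- purrr::map(setdiff(metrics, "expressed"), function(m) {
      both <- metric_data[["expressed"]]$keep & metric_data[[m]]$keep
      sa <- oriented_score(graded, m)[both]
      sb <- oriented_score(graded, "expressed")[both]
      outc <- graded$correct[both]
      dl <- delong_test(sa, sb, outc)
      roc_a <- roc_analysis(sa, outc, ci_level)
      roc_b <- roc_analysis(sb, outc, ci_level)
      ta <- youden_threshold(roc_a)
      tb <- youden_threshold(roc_b)
      above_a <- sa >= ta
      above_b <- sb >= tb
      mcn <- function(mask) {
        mcnemar_paired(sum(mask & above_a & !above_b),
                       sum(mask & !above_a & above_b))
      }
      rule_a <- above_a == outc
      rule_b <- above_b == outc
      tibble(
        metric = m,
        auroc = dl$auc_a,
        auroc_expressed = dl$auc_b,
        delong_z = dl$z,
        delong_p = dl$p_value,
        tpr_mcnemar_p = mcn(outc),
        fpr_mcnemar_p = mcn(!outc),
        rule_accuracy_mcnemar_p = mcnemar_paired(
          sum(rule_a & !rule_b), sum(!rule_a & rule_b)
        )
      )
    })
    delong <- dplyr::bind_rows(delong_rows)
  }

  calib_metrics <- intersect(metrics, CALIBRATABLE)
  calibration <- list()
  calibration_comparison <- NULL
  if (length(calib_metrics) > 0 && bootstrap_reps > 0) {
    calibration <- purrr::imap(
      setNames(calib_metrics, calib_metrics),
      function(m, nm) {
        d <- metric_data[[m]]
        calibration_report(d$scores, d$outcomes, n_bins, bootstrap_reps,
                           seed = seed + match(m, METRICS), ci_level,
                           metric = m)
      }
    )
    if (all(c("expressed", "token_prob") %in% calib_metrics)) {
      both <- metric_data[["expressed"]]$keep &
        metric_data[["token_prob"]]$keep
      ca <- graded$expressed_conf_norm[both]
      cb <- graded$token_prob[both]
      outc <- graded$correct[both]
      ace_stat <- function(conf, out) ace(conf, out, n_bins)
      calibration_comparison <- tibble(
        statistic = c("ace", "brier"),
        expressed = c(ace(ca, outc, n_bins), brier_score(ca, outc)),
        token_prob = c(ace(cb, outc, n_bins), brier_score(cb, outc)),
        p_value = c(
          bootstrap_paired_pvalue(ace_stat, ca, cb, outc,
                                  bootstrap_reps, seed = seed + 11L),
          bootstrap_paired_pvalue(brier_score, ca, cb, outc,
                                  bootstrap_reps, seed = seed + 12L)
        )
      )
    }
  }

  config <- list(
    metrics = metrics, n_bins = n_bins, bootstrap_reps = bootstrap_reps,
    seed = seed, ci_level = ci_level,
    confidence_scale_max = confidence_scale_max,
    n_items = nrow(items), n_records = nrow(log),
    package_version = as.character(utils::packageVersion("tokenconf")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  result <- structure(
    list(
      accuracy = accuracy,
      discrimination = discrimination,
      delong = delong,
      roc = rocs,
      calibration = calibration,
      calibration_comparison = calibration_comparison,
      exclusions = attr(graded, "exclusions"),
      graded = graded,
      config = config
    ),
    class = "confidence_evaluation"
  )

  if (!is.null(output_dir)) {
    write_evaluation_reports(result, output_dir)
  }
  result
}

write_evaluation_reports <- function(result, output_dir) {
  reports <- list(
    accuracy = result$accuracy,
    discrimination = result$discrimination,
    roc_curves = dplyr::bind_rows(
      purrr::imap(result$roc, ~ dplyr::mutate(tidy(.x), metric = .y,
                                              .before = 1))
    ),
    exclusions = tibble(
      reason = names(result$exclusions),
      n = as.integer(result$exclusions)
    )
  )
  if (!is.null(result$delong)) reports$delong <- result$delong
  if (length(result$calibration) > 0) {
    reports$calibration <- dplyr::bind_rows(
      purrr::map(result$calibration, glance)
    )
    reports$calibration_curves <- dplyr::bind_rows(
      purrr::imap(result$calibration,
                  ~ dplyr::mutate(tidy(.x), metric = .y, .before = 1))
    )
  }
  if (!is.null(result$calibration_comparison)) {
    reports$calibration_comparison <- result$calibration_comparison
  }
  paths <- write_report_tables(reports, output_dir)
  manifest <- result$config
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.confidence_evaluation <- function(x, ...) {
  cat("<confidence_evaluation>\n")
  cat(sprintf("  accuracy: %.3f (CI %.3f-%.3f), n = %d\n",
              x$accuracy$estimate, x$accuracy$ci_low, x$accuracy$ci_high,
              x$accuracy$n))
  for (i in seq_len(nrow(x$discrimination))) {
    d <- x$discrimination[i, ]
    cat(sprintf("  %-11s AUROC %.3f (%.3f-%.3f)\n", d$metric, d$auroc,
                d$auroc_low, d$auroc_high))
  }
  if (length(x$calibration) > 0) {
    for (cal in x$calibration) {
      cat(sprintf("  %-11s ACE %.3f, Brier %.3f%s\n", cal$metric, cal$ace,
                  cal$brier, if (cal$flag_poor) " [poor]" else ""))
    }
  }
  excl <- x$exclusions[x$exclusions > 0]
  if (length(excl) > 0) {
    cat("  exclusions:", paste(names(excl), excl, sep = "=",
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare prompt variants on the same item set
#'
#' Computes the per-variant AUROC of a confidence signal and a paired
#' DeLong test of each variant against the vanilla variant. All variants
#' must cover exactly the same items.
#'
#' @param items item tibble.
#' @param logs either one response-log tibble containing several
#'   `prompt_variant` values, or a list of per-variant log tibbles.
#' @param metric confidence signal to compare (default token probability).
#' @param reference the reference variant (default `"vanilla"`).
#' @param ci_level confidence level.
#' @param confidence_scale_max see [parse_response()].
#' @return Tibble with one row per variant: `prompt_variant`, `n`, `auroc`,
#'   `auroc_low`, `auroc_high`, `p_vs_reference` (`NA` for the reference).
#' @export
compare_prompt_variants <- function(items, logs, metric = "token_prob",
                                    reference = "vanilla",
                                    ci_level = 0.95,
                                    confidence_scale_max = 100) {
  log <- if (is.data.frame(logs)) logs else dplyr::bind_rows(logs)
  variants <- unique(log$prompt_variant)
  if (length(variants) < 2) {
    abort("Need at least two prompt variants to compare.")
  }
  if (!reference %in% variants) {
    abort(paste0("Reference variant '", reference, "' not present."))
  }
  n_opts <- max(purrr::map_int(items$options, length))
  option_letters <- OPTION_LETTERS[seq_len(n_opts)]
  per_variant <- purrr::map(setNames(variants, variants), function(v) {
    sub <- dplyr::filter(log, .data$prompt_variant == v)
    scored <- score_responses(sub, NULL, option_letters,
                              confidence_scale_max)
    graded <- grade_answers(items, scored)
    sc <- oriented_score(graded, metric)
    keep <- !is.na(sc)
    tibble(item_id = graded$item_id[keep], score = sc[keep],
           correct = graded$correct[keep])
  })
  ref_items <- sort(per_variant[[reference]]$item_id)
  for (v in variants) {
    if (!identical(sort(per_variant[[v]]$item_id), ref_items)) {
      abort(paste0("Variant '", v, "' covers a different item set than '",
                   reference, "'; paired comparison impossible."))
    }
  }
  ref <- dplyr::arrange(per_variant[[reference]], .data$item_id)
  rows <- purrr::map(variants, function(v) {
    d <- dplyr::arrange(per_variant[[v]], .data$item_id)
    roc <- roc_analysis(d$score, d$correct, ci_level)
    p <- NA_real_
    if (v != reference) {
      # correctness differs between variants, so the paired DeLong form
      # requires a common outcome; we pair on the variant's own outcomes
      # only when they coincide, else fall back to the unpaired z-test.
      if (identical(d$correct, ref$correct)) {
        p <- delong_test(d$score, ref$score, d$correct)$p_value
      } else {
        roc_ref <- roc_analysis(ref$score, ref$correct, ci_level)
        z <- (roc$auc - roc_ref$auc) /
          sqrt(roc$var_auc + roc_ref$var_auc)
        p <- 2 * pnorm(-abs(z))
      }
    }
    tibble(
      prompt_variant = v, n = nrow(d),
      auroc = roc$auc, auroc_low = roc$auc_ci[1],
      auroc_high = roc$auc_ci[2],
      p_vs_reference = p
    )
  })
  dplyr::bind_rows(rows)
}
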