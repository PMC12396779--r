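Package: tokenconf
Title: Discrimination and Calibration of Language-Model Confidence Signals
    on Multiple-Choice Questions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for comparing confidence signals of large
    language models answering multiple-choice (medical licensing style)
    questions. Computes four per-answer uncertainty scores from raw answer
    logs with token log-probabilities (verbalized "expressed" confidence,
    raw response-token probability, Shannon entropy of the option-token
    distribution, and answer perplexity), quantifies how well each signal
    discriminates correct from incorrect answers (AUROC with DeLong
    confidence intervals and paired tests, Youden-optimal thresholds,
    threshold-conditional accuracy with McNemar and Fisher exact tests),
    and quantifies calibration (adaptive calibration error over equal-mass
    bins, Brier score, bootstrap confidence intervals and paired p-values).
    Includes a seeded synthetic answer-log generator with known ground-truth
    accuracy, discrimination (closed-form AUC) and miscalibration, so every
    pipeline stage is testable without model APIs or dataset downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
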