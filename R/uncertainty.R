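# Per-answer confidence signals: raw response-token probability, Shannon
# entropy of the option-token distribution, answer perplexity, and
# normalized expressed confidence.
#
# Conventions:
#   * token probability is the RAW probability of the chosen letter token,
#     never renormalized over the option letters;
#   * top-k mass not assigned to any option letter is carried as a single
#     residual outcome, so entropy is computed over a proper distribution;
#   * entropy is in bits; entropy and perplexity are doubt scores and are
#     negated before they enter any ROC analysis.

#' Build the option-token distribution at the answer position
#'
#' Reads the top-k token log-probabilities at the answer-token position and
#' assigns each option letter the probability of its best-matching top-k
#' entry (same token-stripping rule as [locate_answer_token()]); letters
#' absent from the top-k get 0. Mass not assigned to any option letter is
#' kept as `residual_mass`, so the distribution stays proper.
#'
#' @param token_steps a record's token-step tibble.
#' @param answer_index index returned by [locate_answer_token()].
#' @param option_letters character vector of the item's option letters.
#' @return An object of class `option_distribution`: list with `probs`
#'   (named numeric over the option letters), `residual_mass` and
#'   `source_k`.
#' @export
build_option_distribution <- function(token_steps, answer_index,
                                      option_letters = LETTERS[1:5]) {
  stopifnot(answer_index >= 1, answer_index <= nrow(token_steps))
  top_k <- token_steps$top_k[[answer_index]]
  if (nrow(top_k) == 0) abort("top_k at the answer position is empty.")
  stripped <- toupper(strip_token(top_k$token))
  probs <- vapply(option_letters, function(l) {
    hit <- which(stripped == l)
    if (length(hit) == 0) 0 else exp(top_k$logp[hit[1]])
  }, numeric(1))
  chosen <- toupper(strip_token(token_steps$token[answer_index]))
  if (!chosen %in% option_letters || probs[[chosen]] == 0) {
    abort(paste0("Chosen letter '", chosen,
                 "' is absent from top_k at the answer position."))
  }
  total <- sum(probs)
  if (total > 1 + 1e-6) {
    abort("Option-token probabilities sum to more than 1.")
  }
  structure(
    list(
      probs = probs,
      residual_mass = max(0, 1 - total),
      source_k = nrow(top_k)
    ),
    class = "option_distribution"
  )
}

#' @export
print.option_distribution <- function(x, ...) {
  cat("<option_distribution> k =", x$source_k, "\n")
  print(round(c(x$probs, residual = x$residual_mass), 4))
  invisible(x)
}

#' Raw response-token probability
#'
#' Probability of the chosen option letter's token, taken raw from the
#' option-token distribution: it is deliberately NOT renormalized over the
#' option letters, so residual top-k mass lowers it.
#'
#' @param dist an [build_option_distribution()] result.
#' @param letter chosen option letter.
#' @return Probability in `[0, 1]`.
#' @export
response_token_probability <- function(dist, letter) {
  stopifnot(inherits(dist, "option_distribution"))
  letter <- toupper(letter)
  if (!letter %in% names(dist$probs)) {
    abort(paste0("Letter '", letter, "' is not in the distribution."))
  }
  unname(dist$probs[[letter]])
}

#' Shannon entropy of the option-token distribution, in bits
#'
#' Dispersion of the probabilities over the option letters, with the
#' residual top-k mass counted as one extra pseudo-outcome; terms with
#' probability 0 contribute 0. Bounded by `log2(m)` where `m` is the number
#' of nonzero outcomes.
#'
#' @inheritParams response_token_probability
#' @return Entropy in bits, `>= 0`.
#' @export
shannon_entropy_bits <- function(dist) {
  stopifnot(inherits(dist, "option_distribution"))
  p <- c(dist$probs, dist$residual_mass)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Answer perplexity
#'
#' Product over emitted tokens of the reciprocal of each token's
#' probability, computed in log space as `exp(-sum(log p_t))`. By default no
#' length normalization is applied; `normalize = TRUE` gives the
#' per-token variant `exp(-mean(log p_t))`.
#'
#' @param token_steps a record's token-step tibble.
#' @param normalize length-normalize (default `FALSE`).
#' @return Perplexity `>= 1`; equals 1 iff every emitted token has
#'   probability 1.
#' @export
answer_perplexity <- function(token_steps, normalize = FALSE) {
  logp <- purrr::map2_dbl(token_steps$top_k, token_steps$token,
    function(tk, tok) {
      hit <- which(tk$token == tok)
      tk$logp[hit[1]]
    })
  if (any(!is.finite(logp)) || any(exp(logp) == 0)) {
    abort("An emitted token has probability 0; cannot compute perplexity.")
  }
  if (normalize) exp(-mean(logp)) else exp(-sum(logp))
}

#' Normalize expressed confidence to [0, 1]
#'
#' Divides the raw expressed confidence by its declared scale maximum (100
#' for vanilla/expert/few-shot prompts, 1 for the confidence-scaling
#' prompt).
#'
#' @param expressed_confidence raw confidence value(s).
#' @param confidence_scale_max declared scale maximum, 100 or 1.
#' @return Value(s) in `[0, 1]`; `NA` input raises an error directing the
#'   caller to exclusion handling.
#' @export
normalize_expressed_confidence <- function(expressed_confidence,
                                           confidence_scale_max = 100) {
  if (any(is.na(expressed_confidence))) {
    abort(paste0(
      "Missing expressed confidence; exclude the record from ",
      "expressed-confidence analyses instead of normalizing it."
    ))
  }
  stopifnot(all(confidence_scale_max %in% c(100, 1)))
  out <- expressed_confidence / confidence_scale_max
  if (any(out < 0 | out > 1)) {
    abort("Expressed confidence outside [0, scale maximum].")
  }
  out
}

#' Score every record of a response log
#'
#' Parses each record (unless pre-parsed answers are supplied), locates the
#' answer token, and computes all four uncertainty scores. Records that
#' failed to parse, or whose answer letter was never emitted as a token,
#' are kept with `NA` scores and counted in the exclusion tally attached as
#' attribute `"exclusions"`.
#'
#' @param log response-log tibble from [read_response_log()] or
#'   [simulate_responses()].
#' @param parsed optional tibble from [parse_responses()]; parsed from
#'   `log` if omitted.
#' @param option_letters option letters in play (default A-E).
#' @param confidence_scale_max see [parse_response()].
#' @return Tibble with one row per record: `item_id`, `model_tag`,
#'   `prompt_variant`, `letter`, `parse_status`, `token_prob`,
#'   `entropy_bits`, `perplexity`, `expressed_conf_norm`, `token_found`.
#'   Attribute `"exclusions"` is a named integer vector
#'   (`parse_failed`, `token_not_found`, `no_confidence`).
#' @export
score_responses <- function(log, parsed = NULL,
                            option_letters = LETTERS[1:5],
                            confidence_scale_max = 100) {
  if (nrow(log) == 0) abort("Response log is empty; nothing to score.")
  if (is.null(parsed)) parsed <- parse_responses(log, confidence_scale_max)
  stopifnot(nrow(parsed) == nrow(log))
  rows <- purrr::map(seq_len(nrow(log)), function(i) {
    steps <- log$token_steps[[i]]
    letter <- parsed$letter[i]
    status <- parsed$parse_status[i]
    token_prob <- NA_real_
    entropy <- NA_real_
    ppl <- NA_real_
    token_found <- FALSE
    # a letter outside the option set is kept for grading (it counts as
    # incorrect) but has no option-token distribution to score
    if (status != "failed" && !is.na(letter) &&
        letter %in% option_letters) {
      idx <- tryCatch(locate_answer_token(steps, letter),
                      error = function(e) NA_integer_)
      if (!is.na(idx)) {
        token_found <- TRUE
        dist <- build_option_distribution(steps, idx, option_letters)
        token_prob <- response_token_probability(dist, letter)
        entropy <- shannon_entropy_bits(dist)
        ppl <- answer_perplexity(steps)
      }
    }
    conf <- parsed$expressed_confidence[i]
    conf_norm <- if (is.na(conf)) NA_real_ else {
      normalize_expressed_confidence(conf, parsed$confidence_scale_max[i])
    }
    tibble(
      item_id = log$item_id[i],
      model_tag = log$model_tag[i],
      prompt_variant = log$prompt_variant[i],
      letter = letter,
      parse_status = status,
      token_prob = token_prob,
      entropy_bits = entropy,
      perplexity = ppl,
      expressed_conf_norm = conf_norm,
      token_found = token_found
    )
  })
  out <- dplyr::bind_rows(rows)
  exclusions <- c(
    parse_failed = sum(out$parse_status == "failed"),
    token_not_found = sum(out$parse_status != "failed" & !out$token_found),
    no_confidence = sum(out$parse_status != "failed" &
                          is.na(out$expressed_conf_norm))
  )
  attr(out, "exclusions") <- exclusions
  out
}
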