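# Shared fixture builders and independent oracles.

# Build a token-step tibble for a templated response by hand. `probs` is a
# named probability vector over option letters defining the top-k at the
# answer position; all other tokens are emitted with probability 1 at
# top-k depth 1 (depth is constant within the record only when k matches,
# so this builder uses k = length(probs) everywhere).
toy_token_steps <- function(letter, conf, probs) {
  k <- length(probs)
  ord <- order(probs, decreasing = TRUE)
  ans_top_k <- tibble::tibble(
    token = paste0(" ", names(probs)[ord]),
    logp = log(unname(probs[ord]))
  )
  certain <- function(tok) {
    tibble::tibble(
      token = c(tok, paste0("<p", seq_len(k - 1), ">")),
      logp = c(0, -30 - seq_len(k - 1))
    )[seq_len(k), , drop = FALSE]
  }
  tokens <- c("The", " correct", " answer", " is", ":",
              paste0(" ", letter), ".",
              " My", " confidence", " level", " is", ":",
              paste0(" ", conf), ".")
  top_k <- lapply(tokens, certain)
  top_k[[6]] <- ans_top_k
  tibble::tibble(token = tokens, top_k = top_k)
}

# One-record response-log tibble.
toy_log_record <- function(item_id, letter, conf, probs,
                           model_tag = "toy", prompt_variant = "vanilla",
                           temperature = 0) {
  tibble::tibble(
    item_id = item_id,
    model_tag = model_tag,
    prompt_variant = prompt_variant,
    temperature = temperature,
    raw_text = sprintf(
      "The correct answer is: %s. My confidence level is: %s.", letter, conf
    ),
    token_steps = list(toy_token_steps(letter, conf, probs))
  )
}

# Minimal item tibble with identical placeholder options.
toy_items <- function(ids, gold, n_options = 4) {
  letters_ <- LETTERS[seq_len(n_options)]
  opts <- stats::setNames(paste("Option", letters_), letters_)
  tibble::tibble(
    item_id = ids,
    stem = paste("Stem", ids),
    options = rep(list(opts), length(ids)),
    gold = gold,
    dataset_tag = "toy",
    language_tag = "en"
  )
}

# O(n^2) brute-force AUROC oracle: all correct x incorrect pairs, ties
# counting one half.
brute_auc <- function(scores, outcomes) {
  x <- scores[outcomes]
  y <- scores[!outcomes]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
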