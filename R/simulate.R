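# Synthetic multiple-choice items and model answer logs with known
# ground-truth accuracy, discrimination and miscalibration.
#
# The generator draws correctness first (Bernoulli at the target accuracy)
# and conditions the latent confidence on it. In binormal mode the latent
# score is Normal(mu, 1) for correct answers and Normal(0, 1) for
# incorrect ones, mapped to (0, 1) by the logistic function, which gives
# the token-probability score a closed-form true AUC of Phi(mu / sqrt(2))
# (the logistic map is monotone, so ranks are unchanged). Dirichlet mode
# produces ragged option-probability vectors with no closed form.
#
# Every generated response follows the elicitation template exactly, so
# the parsing layer sees 100% template matches on simulated logs.

SIM_PAD_TOKENS <- paste0("<pad", 1:8, ">")

#' Simulator configuration
#'
#' Bundles and validates the parameters of the synthetic answer-log
#' generator.
#'
#' @param n_items number of items.
#' @param n_options options per item (2-5).
#' @param target_accuracy probability an answer is correct.
#' @param discrimination_mode `"binormal"` (closed-form AUC) or
#'   `"dirichlet"` (ragged option distributions).
#' @param binormal_mu separation of the latent confidence for correct vs
#'   incorrect answers (unit variance); true AUC is `pnorm(mu / sqrt(2))`.
#' @param dirichlet_skill concentration placed on the chosen letter for
#'   correct answers in Dirichlet mode (incorrect answers draw from a flat
#'   Dirichlet).
#' @param overconfidence_offset uniform shift added to the latent
#'   confidence before quantized expressed confidence is emitted
#'   (`[-1, 1]`; clipped at the scale bounds).
#' @param expressed_profile `"constant_high"` (the verbalized score is
#'   always `expressed_base`, emulating the near-uninformative clustered
#'   confidence LLMs verbalize) or `"quantized_informative"` (rounded to
#'   multiples of 5 on the 0-100 scale).
#' @param expressed_base the constant verbalized confidence (0-100 scale).
#' @param temperature_label temperature recorded in the log (label only).
#' @param top_k top-k depth recorded per token step (>= n_options).
#' @param model_tag,prompt_variant provenance labels for the log.
#' @param seed integer seed; all generator draws are functions of it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_items,
                       n_options = 5,
                       target_accuracy = 0.7,
                       discrimination_mode = c("binormal", "dirichlet"),
                       binormal_mu = 1.4652,
                       dirichlet_skill = 5,
                       overconfidence_offset = 0,
                       expressed_profile = c("constant_high",
                                             "quantized_informative"),
                       expressed_base = 95,
                       temperature_label = 0,
                       top_k = 5,
                       model_tag = "sim-model",
                       prompt_variant = "vanilla",
                       seed) {
  discrimination_mode <- match.arg(discrimination_mode)
  expressed_profile <- match.arg(expressed_profile)
  if (missing(seed)) abort("sim_config() requires an explicit seed.")
  stopifnot(
    n_items >= 0, n_options >= 2, n_options <= 5,
    target_accuracy > 0, target_accuracy <= 1,
    binormal_mu >= 0, dirichlet_skill > 0,
    overconfidence_offset >= -1, overconfidence_offset <= 1,
    expressed_base >= 0, expressed_base <= 100,
    temperature_label >= 0, top_k >= n_options, top_k <= 9
  )
  structure(
    list(
      n_items = as.integer(n_items), n_options = as.integer(n_options),
      target_accuracy = target_accuracy,
      discrimination_mode = discrimination_mode,
      binormal_mu = binormal_mu, dirichlet_skill = dirichlet_skill,
      overconfidence_offset = overconfidence_offset,
      expressed_profile = expressed_profile,
      expressed_base = expressed_base,
      temperature_label = temperature_label,
      top_k = as.integer(top_k),
      model_tag = model_tag, prompt_variant = prompt_variant,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a multiple-choice item set
#'
#' @param config a [sim_config()].
#' @return Item tibble in the [read_mcq_dataset()] layout, with placeholder
#'   stems/options and a uniformly drawn gold letter; deterministic given
#'   the config seed.
#' @export
simulate_items <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_items
  if (n == 0) {
    return(tibble(
      item_id = character(), stem = character(), options = list(),
      gold = character(), dataset_tag = character(), language_tag = character()
    ))
  }
  letters_ <- OPTION_LETTERS[seq_len(config$n_options)]
  gold <- withr::with_seed(config$seed,
                           sample(letters_, n, replace = TRUE))
  opts <- setNames(paste("Option", letters_), letters_)
  tibble(
    item_id = sprintf("sim-%06d", seq_len(n)),
    stem = sprintf("Synthetic question %d", seq_len(n)),
    options = rep(list(opts), n),
    gold = gold,
    dataset_tag = "synthetic",
    language_tag = "en"
  )
}

# fast tibble constructors (hot path: thousands of small nested tibbles)
new_tbl <- function(lst, n) {
  tibble::new_tibble(lst, nrow = n)
}

# Build the token-step tibble for one templated response.
# All tokens are emitted with probability 1 except the answer-letter token,
# whose top-k encodes the option-token distribution.
sim_token_steps <- function(letter, expressed, option_probs, k) {
  letter_tokens <- paste0(" ", names(option_probs))
  m <- length(option_probs)
  logp <- log(option_probs)
  ord <- order(logp, decreasing = TRUE)
  ans_tokens <- letter_tokens[ord]
  ans_logp <- logp[ord]
  if (m < k) {
    pad_logp <- min(ans_logp) - 10 - seq_len(k - m)
    ans_tokens <- c(ans_tokens, SIM_PAD_TOKENS[seq_len(k - m)])
    ans_logp <- c(ans_logp, pad_logp)
  }
  ans_top_k <- new_tbl(list(token = ans_tokens, logp = unname(ans_logp)), k)
  certain_top_k <- function(tok) {
    new_tbl(list(
      token = c(tok, SIM_PAD_TOKENS[seq_len(k - 1)]),
      logp = c(0, -30 - seq_len(k - 1))
    ), k)
  }
  tokens <- c("The", " correct", " answer", " is", ":",
              paste0(" ", letter), ".",
              " My", " confidence", " level", " is", ":",
              paste0(" ", format(expressed, trim = TRUE)), ".")
  answer_pos <- 6L
  top_k <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    top_k[[i]] <- if (i == answer_pos) ans_top_k else certain_top_k(tokens[i])
  }
  new_tbl(list(token = tokens, top_k = top_k), length(tokens))
}

#' Simulate a model answer log for an item set
#'
#' For each item, correctness is drawn at the target accuracy; the chosen
#' letter is the gold letter when correct and uniform among the others
#' when not. A latent confidence conditioned on correctness drives the
#' option-token distribution at the answer position (see [sim_config()]),
#' and the verbalized confidence follows the configured profile. Responses
#' follow the elicitation template exactly.
#'
#' @param items item tibble from [simulate_items()].
#' @param config the same [sim_config()].
#' @return Response-log tibble in the [read_response_log()] layout,
#'   deterministic given the config seed. Attribute `"truth"` holds a
#'   tibble with the latent per-item ground truth (`correct`, `latent_s`).
#' @export
simulate_responses <- function(items, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(items)
  if (n == 0) {
    return(tibble(
      item_id = character(), model_tag = character(),
      prompt_variant = character(), temperature = numeric(),
      raw_text = character(), token_steps = list()
    ))
  }
  m <- config$n_options
  letters_ <- OPTION_LETTERS[seq_len(m)]
  draws <- withr::with_seed(config$seed + 1L, {
    correct <- runif(n) < config$target_accuracy
    latent <- rnorm(n, mean = ifelse(correct, config$binormal_mu, 0), sd = 1)
    pick <- runif(n)  # picks the wrong letter when incorrect
    gam <- NULL
    if (config$discrimination_mode == "dirichlet") {
      # flat Dirichlet for incorrect answers; concentration on the chosen
      # letter for correct ones
      gam <- matrix(rgamma(n * m, shape = 1), nrow = n)
    }
    list(correct = correct, latent = latent, pick = pick, gam = gam)
  })
  s <- pmin(pmax(plogis(draws$latent), 1e-9), 1 - 1e-9)
  chosen <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gold <- items$gold[i]
    if (draws$correct[i]) {
      letter <- gold
    } else {
      others <- setdiff(letters_, gold)
      letter <- others[ceiling(draws$pick[i] * length(others))]
    }
    chosen[i] <- letter
    if (config$discrimination_mode == "binormal") {
      probs <- setNames(rep((1 - s[i]) / (m - 1), m), letters_)
      probs[letter] <- s[i]
    } else {
      g <- draws$gam[i, ]
      if (draws$correct[i]) {
        g[match(letter, letters_)] <-
          g[match(letter, letters_)] * config$dirichlet_skill
      }
      probs <- setNames(pmax(g / sum(g), 1e-12), letters_)
      probs <- probs / sum(probs)
      s[i] <- probs[[letter]]
    }
    expressed <- if (config$expressed_profile == "constant_high") {
      config$expressed_base
    } else {
      min(100, max(0, 5 * round(
        100 * (s[i] + config$overconfidence_offset) / 5
      )))
    }
    rows[[i]] <- list(
      raw_text = sprintf(
        "The correct answer is: %s. My confidence level is: %s.",
        letter, format(expressed, trim = TRUE)
      ),
      token_steps = sim_token_steps(letter, expressed, probs, config$top_k)
    )
  }
  out <- tibble(
    item_id = items$item_id,
    model_tag = config$model_tag,
    prompt_variant = config$prompt_variant,
    temperature = config$temperature_label,
    raw_text = purrr::map_chr(rows, "raw_text"),
    token_steps = purrr::map(rows, "token_steps")
  )
  attr(out, "truth") <- tibble(
    item_id = items$item_id,
    correct = draws$correct,
    chosen = chosen,
    latent_s = s
  )
  out
}

#' Closed-form true AUC of the binormal simulator
#'
#' The latent confidence is Normal(mu, 1) for correct answers and
#' Normal(0, 1) for incorrect ones, so the AUC of any strictly increasing
#' transform of it (here the logistic map to token probability) is
#' `pnorm(mu / sqrt(2))`.
#'
#' @param config a [sim_config()] in binormal mode.
#' @return True AUC in `[0.5, 1]`.
#' @examples
#' true_auc(sim_config(1, binormal_mu = 1.4652, seed = 1))  # 0.85
#' @export
true_auc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$discrimination_mode != "binormal") {
    abort("No closed form: true_auc() is defined for binormal mode only.")
  }
  pnorm(config$binormal_mu / sqrt(2))
}
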