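test_that("the option-token distribution exponentiates the top-k and tracks residual mass", {
  steps <- toy_token_steps("B", 95, c(B = .7, A = .2, C = .1))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(unname(d$probs[c("A", "B", "C", "D")]), c(.2, .7, .1, 0))
  expect_equal(d$residual_mass, 0)
  expect_equal(d$source_k, 3)

  # degenerate: single token with log-probability 0
  steps <- toy_token_steps("B", 100, c(B = 1))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(unname(d$probs[["B"]]), 1)
  expect_equal(d$residual_mass, 0)

  # non-letter tokens leave residual mass: top_k [B: .5, "Answer": .3]
  steps <- toy_token_steps("B", 95, c(B = .5, Answer = .3))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(unname(d$probs[["B"]]), .5)
  expect_equal(unname(d$probs[["A"]]), 0)
  expect_equal(d$residual_mass, .5)
})

test_that("token probability is raw: residual mass is never renormalized away", {
  steps <- toy_token_steps("B", 95, c(B = .7, A = .2, C = .1))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(response_token_probability(d, "B"), .7)

  steps <- toy_token_steps("B", 95, c(B = .5, Answer = .5))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(response_token_probability(d, "B"), .5)  # not 1.0

  steps <- toy_token_steps("B", 100, c(B = 1))
  d <- build_option_distribution(steps, 6, LETTERS[1:4])
  expect_equal(response_token_probability(d, "B"), 1)
})

test_that("entropy matches closed forms (bits)", {
  mk <- function(probs) {
    build_option_distribution(toy_token_steps(names(probs)[1], 95, probs),
                              6, LETTERS[1:4])
  }
  expect_equal(shannon_entropy_bits(mk(c(A = .25, B = .25, C = .25, D = .25))), 2)
  expect_equal(shannon_entropy_bits(mk(c(B = 1))), 0)
  expect_equal(shannon_entropy_bits(mk(c(A = .5, B = .5))), 1)
  # hand evaluation of -sum p log2 p for {.7, .2, .1}
  expect_equal(shannon_entropy_bits(mk(c(B = .7, A = .2, C = .1))),
               1.15677965, tolerance = 1e-6)
})

test_that("entropy is bounded by log2 of the number of nonzero outcomes", {
  set.seed(421)
  for (r in 1:200) {
    m <- sample(2:5, 1)
    p <- rgamma(m, 1)
    p <- p / sum(p) * runif(1, 0.5, 1)  # leave some residual mass
    names(p) <- LETTERS[seq_len(m)]
    steps <- toy_token_steps("A", 95, p)
    d <- build_option_distribution(steps, 6, LETTERS[seq_len(m)])
    h <- shannon_entropy_bits(d)
    nonzero <- sum(c(d$probs, d$residual_mass) > 0)
    expect_gte(h, 0)
    expect_lte(h, log2(nonzero) + 1e-12)
  }
})

test_that("perplexity matches hand-computed products and is >= 1", {
  # all emitted tokens probability 1
  steps <- toy_token_steps("B", 100, c(B = 1))
  expect_equal(answer_perplexity(steps), 1)

  # two tokens at probability 0.5 each -> 4
  steps <- tibble::tibble(
    token = c("x", "y"),
    top_k = list(
      tibble::tibble(token = c("x", "z"), logp = log(c(.5, .5))),
      tibble::tibble(token = c("y", "z"), logp = log(c(.5, .5)))
    )
  )
  expect_equal(answer_perplexity(steps), 4)

  # hand product: p = (.9, .8, .5) -> 1/0.36
  steps <- tibble::tibble(
    token = c("a", "b", "c"),
    top_k = list(
      tibble::tibble(token = "a", logp = log(.9)),
      tibble::tibble(token = "b", logp = log(.8)),
      tibble::tibble(token = "c", logp = log(.5))
    )
  )
  expect_equal(answer_perplexity(steps), 1 / 0.36, tolerance = 1e-9)
  expect_equal(answer_perplexity(steps, normalize = TRUE),
               (1 / 0.36)^(1 / 3), tolerance = 1e-9)
})

test_that("log-space perplexity equals the direct product on random sequences", {
  set.seed(99)
  for (r in 1:50) {
    len <- sample(1:50, 1)
    p <- runif(len, 0.05, 1)
    steps <- tibble::tibble(
      token = paste0("t", seq_len(len)),
      top_k = lapply(seq_len(len), function(i) {
        tibble::tibble(token = paste0("t", i), logp = log(p[i]))
      })
    )
    direct <- prod(1 / p)
    expect_equal(answer_perplexity(steps), direct,
                 tolerance = 1e-9 * direct)
    expect_gte(answer_perplexity(steps), 1)
  }
})

test_that("token probability ignores the probabilities of non-chosen options", {
  for (pb in c(.3, .6)) {
    d1 <- build_option_distribution(
      toy_token_steps("B", 95, c(B = pb, A = (1 - pb) * .9,
                                 C = (1 - pb) * .1)), 6, LETTERS[1:4])
    d2 <- build_option_distribution(
      toy_token_steps("B", 95, c(B = pb, A = (1 - pb) * .2,
                                 C = (1 - pb) * .8)), 6, LETTERS[1:4])
    expect_identical(response_token_probability(d1, "B"),
                     response_token_probability(d2, "B"))
  }
})

test_that("expressed confidence normalizes by its declared scale", {
  expect_equal(normalize_expressed_confidence(95, 100), 0.95)
  expect_equal(normalize_expressed_confidence(100, 100), 1)
  expect_equal(normalize_expressed_confidence(0.8, 1), 0.8)
  expect_error(normalize_expressed_confidence(NA_real_, 100), "exclu")
  expect_error(normalize_expressed_confidence(120, 100), "outside")
})

test_that("score_responses assembles all four signals and tallies exclusions", {
  log <- dplyr::bind_rows(
    toy_log_record("q1", "B", 95, c(B = .7, A = .2, C = .1)),
    toy_log_record("q2", "A", 80, c(A = .6, B = .4))
  )
  log <- dplyr::bind_rows(log, tibble::tibble(
    item_id = "q3", model_tag = "toy", prompt_variant = "vanilla",
    temperature = 0, raw_text = "I cannot answer this question.",
    token_steps = list(toy_token_steps("B", 95, c(B = 1)))
  ))
  scored <- score_responses(log, option_letters = LETTERS[1:4])
  expect_equal(nrow(scored), 3)
  expect_equal(scored$token_prob[1:2], c(.7, .6))
  expect_equal(scored$expressed_conf_norm[1:2], c(.95, .80))
  expect_true(is.na(scored$token_prob[3]))
  excl <- attr(scored, "exclusions")
  expect_equal(unname(excl["parse_failed"]), 1L)
})
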