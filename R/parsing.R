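# Extracting the chosen option letter and the expressed confidence from
# templated model output, and locating the answer token in the token stream.
#
# The elicitation template is:
#   "The correct answer is: [letter]. My confidence level is: [number]."
# The template branch matches it case-insensitively with flexible
# whitespace. A deterministic rule-based fallback handles off-template
# responses; parse failure is a status, never an error, so exclusions can
# be tallied explicitly downstream.

TEMPLATE_LETTER_RE <-
  "(?i)the\\s+correct\\s+answer\\s+is\\s*:\\s*\\(?([A-Ea-e])\\)?\\b"
TEMPLATE_CONF_RE <-
  "(?i)my\\s+confidence\\s+level\\s+is\\s*:\\s*([0-9]*\\.?[0-9]+)"

first_match <- function(text, pattern) {
  m <- stringr::str_match(text, pattern)
  if (is.na(m[1, 1])) NA_character_ else m[1, 2]
}

#' Parse one model response
#'
#' Extracts the chosen option letter and the expressed confidence from raw
#' response text. The template branch matches the elicitation template
#' ("The correct answer is: X. My confidence level is: N.")
#' case-insensitively with flexible whitespace; a rule-based fallback scans
#' for the first standalone uppercase option letter and the first number
#' within the confidence scale. Lowercase standalone letters are not
#' accepted by the fallback ("a" is an English article). Parse failure is
#' recorded as `parse_status = "failed"`, never raised as an error.
#'
#' @param raw_text the raw response text (length-1 character).
#' @param confidence_scale_max scale the confidence was elicited on: 100
#'   (default; vanilla/expert/few-shot prompts) or 1 (confidence-scaling
#'   prompt).
#' @param item_id optional item identifier carried through to the output.
#' @return One-row tibble with columns `item_id`, `letter`,
#'   `expressed_confidence` (raw, on the declared scale),
#'   `confidence_scale_max` and `parse_status`
#'   (`"template"`, `"fallback"` or `"failed"`).
#' @examples
#' parse_response("The correct answer is: B. My confidence level is: 95.")
#' parse_response("I believe the answer is D, confidence about 80")
#' @export
parse_response <- function(raw_text, confidence_scale_max = 100,
                           item_id = NA_character_) {
  stopifnot(length(raw_text) == 1, !is.null(raw_text))
  stopifnot(confidence_scale_max %in% c(100, 1))
  letter <- first_match(raw_text, TEMPLATE_LETTER_RE)
  conf_s <- first_match(raw_text, TEMPLATE_CONF_RE)
  conf <- if (is.na(conf_s)) NA_real_ else as.numeric(conf_s)
  status <- "template"
  in_scale <- !is.na(conf) && conf >= 0 && conf <= confidence_scale_max
  if (is.na(letter) || !in_scale) {
    # fallback: first standalone uppercase option letter, first in-scale
    # number; a letter already found by the template phrase is kept
    status <- "fallback"
    if (is.na(letter)) letter <- first_match(raw_text, "\\b([A-E])\\b")
    nums <- stringr::str_match_all(raw_text,
                                   "\\b([0-9]*\\.?[0-9]+)\\b")[[1]]
    conf <- NA_real_
    if (nrow(nums) > 0) {
      vals <- as.numeric(nums[, 2])
      ok <- vals >= 0 & vals <= confidence_scale_max
      if (any(ok)) conf <- vals[which(ok)[1]]
    }
    if (is.na(letter)) {
      status <- "failed"
      conf <- NA_real_
    }
  }
  tibble(
    item_id = item_id,
    letter = if (is.na(letter)) NA_character_ else toupper(letter),
    expressed_confidence = conf,
    confidence_scale_max = confidence_scale_max,
    parse_status = status
  )
}

#' Parse every record of a response log
#'
#' Applies [parse_response()] row-wise to a response-log tibble.
#'
#' @param log response-log tibble from [read_response_log()] or
#'   [simulate_responses()].
#' @param confidence_scale_max see [parse_response()].
#' @return Tibble of parsed answers, one row per log record, same order.
#' @export
parse_responses <- function(log, confidence_scale_max = 100) {
  purrr::map2(log$raw_text, log$item_id,
              ~ parse_response(.x, confidence_scale_max, item_id = .y)) |>
    dplyr::bind_rows()
}

#' Locate the answer token in a response record
#'
#' Returns the index of the first emitted token whose stripped text equals
#' the chosen option letter. Stripping removes leading whitespace/brackets
#' and trailing whitespace/punctuation so tokenizer variants " B", "B.",
#' "(B", "B)" all match. The top-k list at the returned index defines the
#' option-token distribution.
#'
#' @param token_steps a record's token-step tibble (columns `token`,
#'   `top_k`), i.e. one element of the `token_steps` list column.
#' @param letter chosen option letter.
#' @return Integer index into `token_steps`.
#' @export
locate_answer_token <- function(token_steps, letter) {
  stopifnot(!is.na(letter), nzchar(letter))
  letter <- toupper(letter)
  stripped <- toupper(strip_token(token_steps$token))
  idx <- which(stripped == letter)
  if (length(idx) == 0) {
    abort(paste0("answer token not found: no emitted token matches letter '",
                 letter, "'"))
  }
  idx[1]
}
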