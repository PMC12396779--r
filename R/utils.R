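# Internal helpers shared across modules.

OPTION_LETTERS <- LETTERS[1:5]

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return A one-row tibble with `estimate`, `ci_low`, `ci_high`, `n`.
#' @examples
#' wilson_ci(89, 100)
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1)
  if (n < 1) abort("Wilson interval needs n >= 1.")
  if (x < 0 || x > n) abort("x must be in [0, n].")
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(
    estimate = p,
    ci_low = max(0, centre - half),
    ci_high = min(1, centre + half),
    n = as.integer(n)
  )
}

# Strip tokenizer decoration from a token so " B", "B.", "(B", "B)" all
# compare equal to the bare option letter. Leading space/quote/bracket and
# trailing space/punctuation are removed; the core is left untouched.
strip_token <- function(token) {
  out <- gsub("^[\\s(\\[\"']+", "", token, perl = TRUE)
  gsub("[\\s.):,;\"'\\]]+$", "", out, perl = TRUE)
}

# Read a JSONL file into a list of parsed records, reporting 1-based line
# numbers on malformed lines. Blank lines are skipped.
read_jsonl <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  purrr::map(keep, function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        abort(paste0("Malformed JSON on line ", i, ": ", conditionMessage(e)))
      }
    )
    rec$.line <- i
    rec
  })
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
      con,
      useBytes = TRUE
    )
  }
  invisible(path)
}

# Field presence check with line-numbered error for JSONL readers.
require_fields <- function(rec, fields, line, what) {
  missing <- setdiff(fields, names(rec))
  if (length(missing) > 0) {
    abort(paste0(
      "Malformed ", what, " record on line ", line,
      ": missing field(s) ", paste(missing, collapse = ", ")
    ))
  }
  invisible(rec)
}
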