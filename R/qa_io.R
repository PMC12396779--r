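# Reading and writing multiple-choice QA datasets and model answer logs.
#
# Canonical on-disk formats (all plain text, UTF-8):
#   * dataset JSONL: one item per line,
#     {"item_id","stem","options":{"A":...,...},"gold","dataset_tag","language_tag"}
#   * dataset CSV: columns item_id, stem, option_a..option_e, gold,
#     dataset_tag, language_tag (empty option cells mean the option is absent)
#   * response-log JSONL: one record per line,
#     {"item_id","model_tag","prompt_variant","temperature","raw_text",
#      "token_steps":[{"token","top_k":[["tok",logp],...]},...]}
# Log-probabilities are natural-log throughout and are only exponentiated
# inside the metric code, never at I/O time.

PROMPT_VARIANTS <- c("vanilla", "expert", "confidence_scaling", "few_shot")

validate_mcq_item <- function(item_id, options, gold, where) {
  letters_ <- names(options)
  n <- length(options)
  if (n < 2 || n > 5) {
    abort(paste0(where, ": item '", item_id, "' has ", n,
                 " options; between 2 and 5 are required."))
  }
  if (!identical(letters_, OPTION_LETTERS[seq_len(n)])) {
    abort(paste0(where, ": item '", item_id,
                 "' option letters must be consecutive from A, got: ",
                 paste(letters_, collapse = ", ")))
  }
  if (!gold %in% letters_) {
    abort(paste0(where, ": item '", item_id, "' gold letter '", gold,
                 "' is not among its options (", paste(letters_, collapse = ""),
                 ")."))
  }
  invisible(TRUE)
}

#' Read a multiple-choice QA dataset
#'
#' Reads question items (stem, lettered options, gold answer) from JSONL or
#' CSV into a tibble with one row per item. Option letters are normalized to
#' uppercase; every item is validated (2-5 options lettered consecutively
#' from A, gold among the options, unique `item_id`).
#'
#' @param path path to the dataset file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (columns
#'   `item_id, stem, option_a..option_e, gold, dataset_tag, language_tag`).
#' @return A tibble with columns `item_id`, `stem`, `options` (list column of
#'   named character vectors), `gold`, `dataset_tag`, `language_tag`, in file
#'   order.
#' @seealso [write_mcq_dataset()], [read_response_log()]
#' @export
read_mcq_dataset <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  rows <- if (format == "jsonl") read_mcq_jsonl(path) else read_mcq_csv(path)
  dup <- rows$item_id[duplicated(rows$item_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate item_id in dataset: ",
                 paste(unique(dup), collapse = ", ")))
  }
  rows
}

read_mcq_jsonl <- function(path) {
  recs <- read_jsonl(path)
  rows <- purrr::map(recs, function(rec) {
    require_fields(rec, c("item_id", "stem", "options", "gold"),
                   rec$.line, "dataset")
    where <- paste0("Line ", rec$.line)
    opts <- unlist(rec$options)
    names(opts) <- toupper(names(opts))
    opts <- opts[order(names(opts))]
    gold <- toupper(trimws(rec$gold))
    validate_mcq_item(rec$item_id, opts, gold, where)
    tibble(
      item_id = as.character(rec$item_id),
      stem = as.character(rec$stem),
      options = list(opts),
      gold = gold,
      dataset_tag = as.character(rec$dataset_tag %||% ""),
      language_tag = as.character(rec$language_tag %||% "")
    )
  })
  if (length(rows) == 0) {
    return(tibble(
      item_id = character(), stem = character(), options = list(),
      gold = character(), dataset_tag = character(), language_tag = character()
    ))
  }
  dplyr::bind_rows(rows)
}

read_mcq_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("item_id", "stem", "gold")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("Dataset CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  opt_cols <- paste0("option_", letters[1:5])
  opt_cols <- opt_cols[opt_cols %in% names(df)]
  if (length(opt_cols) == 0) {
    abort("Dataset CSV has no option_a..option_e columns.")
  }
  rows <- purrr::map(seq_len(nrow(df)), function(i) {
    where <- paste0("Row ", i)
    vals <- unlist(df[i, opt_cols])
    present <- !is.na(vals) & nzchar(vals)
    opts <- setNames(as.character(vals[present]),
                     toupper(sub("^option_", "", opt_cols[present])))
    gold <- toupper(trimws(df$gold[i]))
    validate_mcq_item(df$item_id[i], opts, gold, where)
    tibble(
      item_id = df$item_id[i],
      stem = df$stem[i],
      options = list(opts),
      gold = gold,
      dataset_tag = df$dataset_tag[i] %||% "",
      language_tag = df$language_tag[i] %||% ""
    )
  })
  if (length(rows) == 0) {
    return(read_mcq_jsonl_empty())
  }
  out <- dplyr::bind_rows(rows)
  out$dataset_tag[is.na(out$dataset_tag)] <- ""
  out$language_tag[is.na(out$language_tag)] <- ""
  out
}

read_mcq_jsonl_empty <- function() {
  tibble(
    item_id = character(), stem = character(), options = list(),
    gold = character(), dataset_tag = character(), language_tag = character()
  )
}

#' Write a multiple-choice QA dataset to JSONL
#'
#' Inverse of [read_mcq_dataset()] for the JSONL format; round-trips
#' field-for-field.
#'
#' @param items tibble of items as returned by [read_mcq_dataset()] or
#'   [simulate_items()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mcq_dataset <- function(items, path) {
  recs <- purrr::pmap(items, function(item_id, stem, options, gold,
                                      dataset_tag, language_tag, ...) {
    list(
      item_id = item_id, stem = stem, options = as.list(options),
      gold = gold, dataset_tag = dataset_tag, language_tag = language_tag
    )
  })
  write_jsonl(recs, path)
}

validate_token_steps <- function(steps, where) {
  if (length(steps) == 0) {
    abort(paste0(where, ": token_steps must be non-empty."))
  }
  k <- NULL
  for (s in seq_along(steps)) {
    st <- steps[[s]]
    tk <- st$top_k
    if (is.null(tk) || nrow(tk) < 1) {
      abort(paste0(where, ": token step ", s, " has an empty top_k."))
    }
    if (any(tk$logp > 0)) {
      abort(paste0(where, ": token step ", s,
                   " has a positive log-probability."))
    }
    if (is.unsorted(-tk$logp)) {
      abort(paste0(where, ": token step ", s,
                   " top_k is not sorted by descending log-probability."))
    }
    if (!st$token %in% tk$token) {
      abort(paste0(where, ": token step ", s, " emitted token '", st$token,
                   "' does not appear in its own top_k."))
    }
    if (is.null(k)) k <- nrow(tk)
    if (nrow(tk) != k) {
      abort(paste0(where, ": top_k depth is not constant within the record."))
    }
  }
  invisible(TRUE)
}

#' Read a model answer log
#'
#' Reads a JSONL response log (raw response text plus per-position top-k
#' token log-probabilities) into a tibble with one row per record. Each
#' record is validated: log-probabilities are non-positive and sorted
#' descending within each top-k list, the emitted token appears in its own
#' top-k, the top-k depth is constant within a record, and temperature is
#' non-negative. Duplicate `item_id`s are retained in file order with a
#' warning; downstream grading uses the first occurrence.
#'
#' @param path path to the response-log JSONL file.
#' @return A tibble with columns `item_id`, `model_tag`, `prompt_variant`,
#'   `temperature`, `raw_text` and `token_steps` (list column; each element a
#'   tibble with columns `token` and `top_k`, the latter a list column of
#'   tibbles with columns `token`, `logp` in natural log).
#' @export
read_response_log <- function(path) {
  recs <- read_jsonl(path)
  rows <- purrr::map(recs, function(rec) {
    require_fields(rec, c("item_id", "raw_text", "token_steps"),
                   rec$.line, "response-log")
    where <- paste0("Line ", rec$.line, " (item '", rec$item_id, "')")
    temperature <- as.numeric(rec$temperature %||% 0)
    if (is.na(temperature) || temperature < 0) {
      abort(paste0(where, ": temperature must be a real >= 0."))
    }
    variant <- as.character(rec$prompt_variant %||% "vanilla")
    if (!variant %in% PROMPT_VARIANTS) {
      abort(paste0(where, ": unknown prompt_variant '", variant, "'."))
    }
    steps <- purrr::map(rec$token_steps, function(st) {
      tk <- purrr::map(st$top_k, function(e) {
        tibble(token = as.character(e[[1]]), logp = as.numeric(e[[2]]))
      })
      tk <- dplyr::bind_rows(tk)
      list(token = as.character(st$token), top_k = tk)
    })
    validate_token_steps(steps, where)
    steps_tbl <- tibble(
      token = purrr::map_chr(steps, "token"),
      top_k = purrr::map(steps, "top_k")
    )
    tibble(
      item_id = as.character(rec$item_id),
      model_tag = as.character(rec$model_tag %||% ""),
      prompt_variant = variant,
      temperature = temperature,
      raw_text = as.character(rec$raw_text),
      token_steps = list(steps_tbl)
    )
  })
  if (length(rows) == 0) {
    return(tibble(
      item_id = character(), model_tag = character(),
      prompt_variant = character(), temperature = numeric(),
      raw_text = character(), token_steps = list()
    ))
  }
  out <- dplyr::bind_rows(rows)
  dup <- unique(out$item_id[duplicated(out$item_id)])
  if (length(dup) > 0) {
    warn(paste0("Response log contains ", length(dup),
                " duplicated item_id(s) (kept in file order; grading uses ",
                "the first): ", paste(head(dup, 5), collapse = ", ")))
  }
  out
}

#' Write a model answer log to JSONL
#'
#' Inverse of [read_response_log()]; log-probabilities are written verbatim
#' (natural log), so reading back never mutates probabilities.
#'
#' @param log tibble of response records as returned by
#'   [read_response_log()] or [simulate_responses()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_response_log <- function(log, path) {
  recs <- purrr::pmap(log, function(item_id, model_tag, prompt_variant,
                                    temperature, raw_text, token_steps, ...) {
    steps <- purrr::pmap(token_steps, function(token, top_k) {
      list(
        token = token,
        top_k = purrr::pmap(top_k, function(token, logp) list(token, logp))
      )
    })
    list(
      item_id = item_id, model_tag = model_tag,
      prompt_variant = prompt_variant, temperature = temperature,
      raw_text = raw_text, token_steps = steps
    )
  })
  write_jsonl(recs, path)
}

#' Write report tables to CSV
#'
#' Writes each report in a named list to `<out_dir>/<name>.csv` with a
#' deterministic column order and numeric columns rounded to 6 significant
#' digits. Report objects with a `tidy()` method (e.g. [roc_analysis()],
#' [calibration_report()]) are tidied first; data frames are written as-is.
#'
#' @param reports named list of data frames and/or report objects.
#' @param out_dir output directory; created if absent.
#' @return Character vector of the files written, invisibly.
#' @export
write_report_tables <- function(reports, out_dir) {
  stopifnot(is.list(reports))
  if (length(reports) == 0) return(invisible(character()))
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    abort("`reports` must be a fully named list.")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
  }
  paths <- purrr::imap_chr(reports, function(rep, name) {
    df <- if (is.data.frame(rep)) rep else generics::tidy(rep)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 6)))
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    path
  })
  invisible(unname(paths))
}
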