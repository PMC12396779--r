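test_that("JSONL datasets read back field-for-field, in file order", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"item_id":"q1","stem":"Which?","options":{"A":"a1","B":"b1","C":"c1","D":"d1"},"gold":"C","dataset_tag":"usmle-step1","language_tag":"en"}',
    '{"item_id":"q2","stem":"What?","options":{"a":"a2","b":"b2"},"gold":"b","dataset_tag":"usmle-step1","language_tag":"en"}'
  ), path)
  items <- read_mcq_dataset(path, "jsonl")
  expect_equal(nrow(items), 2)
  expect_equal(items$item_id, c("q1", "q2"))
  expect_equal(items$gold, c("C", "B"))          # lowercase normalized
  expect_named(items$options[[2]], c("A", "B"))  # letters uppercased
  expect_equal(items$options[[1]][["C"]], "c1")
})

test_that("an empty dataset file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  items <- read_mcq_dataset(path, "jsonl")
  expect_equal(nrow(items), 0)
  expect_true(all(c("item_id", "options", "gold") %in% names(items)))
})

test_that("invariant violations are reported with the offending item", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(
    '{"item_id":"bad1","stem":"s","options":{"A":"1","B":"2","C":"3","D":"4","E":"5"},"gold":"F"}',
    path
  )
  expect_error(read_mcq_dataset(path), "bad1")

  writeLines(
    '{"item_id":"gap","stem":"s","options":{"A":"1","C":"3"},"gold":"A"}',
    path
  )
  expect_error(read_mcq_dataset(path), "consecutive")

  writeLines(c(
    '{"item_id":"dup","stem":"s","options":{"A":"1","B":"2"},"gold":"A"}',
    '{"item_id":"dup","stem":"s","options":{"A":"1","B":"2"},"gold":"B"}'
  ), path)
  expect_error(read_mcq_dataset(path), "Duplicate item_id")

  writeLines('{"item_id":"mf","stem":"s","gold":"A"}', path)
  expect_error(read_mcq_dataset(path), "line 1.*options")
})

test_that("malformed JSON names the line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"item_id":"ok","stem":"s","options":{"A":"1","B":"2"},"gold":"A"}',
    "{not json"
  ), path)
  expect_error(read_mcq_dataset(path), "line 2")
})

test_that("CSV datasets read with absent option columns handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "item_id,stem,option_a,option_b,option_c,option_d,option_e,gold,dataset_tag,language_tag",
    "q1,Which?,a1,b1,c1,d1,,c,frmedmcqa,fr",
    "q2,What?,a2,b2,,,,A,frmedmcqa,fr"
  ), path)
  items <- read_mcq_dataset(path, "csv")
  expect_equal(length(items$options[[1]]), 4)
  expect_equal(length(items$options[[2]]), 2)
  expect_equal(items$gold, c("C", "A"))
})

test_that("dataset round-trip is the identity on simulator output", {
  cfg <- sim_config(n_items = 25, n_options = 4, seed = 11)
  items <- simulate_items(cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_mcq_dataset(items, path)
  back <- read_mcq_dataset(path)
  expect_equal(back$item_id, items$item_id)
  expect_equal(back$gold, items$gold)
  expect_equal(back$options, items$options)
  expect_equal(back$stem, items$stem)
  expect_equal(back$dataset_tag, items$dataset_tag)
})

test_that("response logs round-trip without mutating probabilities", {
  cfg <- sim_config(n_items = 12, n_options = 5, seed = 3)
  log <- simulate_responses(simulate_items(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_response_log(log, path)
  back <- read_response_log(path)
  expect_equal(back$item_id, log$item_id)
  expect_equal(back$raw_text, log$raw_text)
  for (i in seq_len(nrow(back))) {
    orig <- log$token_steps[[i]]
    rt <- back$token_steps[[i]]
    expect_equal(rt$token, orig$token)
    for (s in seq_len(nrow(rt))) {
      expect_equal(rt$top_k[[s]]$logp, orig$top_k[[s]]$logp)
      expect_lte(sum(exp(rt$top_k[[s]]$logp)), 1 + 1e-9)
    }
  }
})

test_that("response-log invariant violations error; duplicates warn", {
  base <- toy_log_record("q1", "B", 95, c(A = .2, B = .7, C = .1))
  path <- withr::local_tempfile(fileext = ".jsonl")

  write_response_log(base, path)
  rec <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)

  bad <- rec
  bad$token_steps[[6]]$top_k[[1]][[2]] <- 0.2  # positive logp
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), path)
  expect_error(read_response_log(path), "positive log-probability")

  bad <- rec
  bad$token_steps[[6]]$top_k <- rev(bad$token_steps[[6]]$top_k)  # unsorted
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), path)
  expect_error(read_response_log(path), "sorted")

  bad <- rec
  bad$temperature <- -1
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), path)
  expect_error(read_response_log(path), "temperature")

  write_response_log(dplyr::bind_rows(base, base), path)
  expect_warning(two <- read_response_log(path), "duplicated item_id")
  expect_equal(nrow(two), 2)  # both retained, file order
})

test_that("a top_k log-probability of 0 reads back as probability 1", {
  log <- toy_log_record("q1", "B", 100, c(B = 1))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_response_log(log, path)
  back <- read_response_log(path)
  tk <- back$token_steps[[1]]$top_k[[6]]
  expect_identical(exp(tk$logp[tk$token == " B"]), 1)
})

test_that("report tables write one CSV per report with 6-significant-digit round trip", {
  dir <- withr::local_tempdir()
  disc <- tibble::tibble(
    metric = c("expressed", "token_prob"),
    estimate = c(0.51234567, 0.87654321),
    ci_low = c(0.4912345, 0.8523456),
    ci_high = c(0.5334567, 0.8998765),
    p_value = c(2.3456789e-8, 1)
  )
  paths <- write_report_tables(list(discrimination = disc), dir)
  expect_equal(basename(paths), "discrimination.csv")
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_named(back, names(disc))
  expect_equal(back$estimate, signif(disc$estimate, 6))
  expect_equal(back$p_value, signif(disc$p_value, 6))

  expect_identical(write_report_tables(list(), dir), character())
  expect_error(write_report_tables(list(disc), dir), "named")
})
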