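test_that("screen-event JSON-lines round-trip is the identity", {
  ev <- fx_events(list(
    list(ts = "09:00:00", blocks = list(list("Hello there", 0.91),
                                        list("second block", 0.55))),
    list(ts = "09:00:05", blocks = list(list("pain again", 0.8)), social = 0.25),
    list(ts = "21:15:00", day = 2, blocks = list())
  ))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_screen_events(ev, path)
  back <- read_screen_events(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$text, ev$text)
  expect_equal(back$conf, ev$conf)
  expect_equal(back$social_prob, ev$social_prob)
  expect_equal(as.numeric(back$ts), as.numeric(ev$ts))
  expect_equal(back$utc_offset, ev$utc_offset)
  # events come back in timestamp order
  expect_true(!is.unsorted(as.numeric(unique(back$ts))))
})

test_that("empty files and malformed records are handled as specified", {
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_equal(nrow(read_screen_events(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"person_id":"P","ts":"2023-03-06T09:00:00-05:00","blocks":[]}',
               "{not json"), bad)
  expect_error(read_screen_events(bad), "line 2")

  oob <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"person_id":"P","ts":"2023-03-06T09:00:00-05:00",',
                    '"blocks":[{"text":"x","conf":1.3}]}'), oob)
  expect_error(read_screen_events(oob), "confidence")
})

test_that("EMA round-trip preserves prompt and response counts", {
  cfg <- fx_small_config()
  ema <- generate_ema(cfg, seed = 11)
  pp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_ema(ema, pp, rp)
  back <- read_ema(pp, rp)
  expect_equal(nrow(back$prompts), nrow(ema$prompts))
  expect_equal(nrow(back$responses), nrow(ema$responses))
  expect_equal(back$responses$pain, ema$responses$pain)
  # full protocol arithmetic: 28 days x 6 prompts
  expect_equal(nrow(back$prompts), 168L)
})

test_that("late responses are excluded with a warning and orphans error", {
  cfg <- fx_small_config()
  ema <- generate_ema(cfg, seed = 3)
  ema$responses$completed_at[1] <- ema$prompts$issued_at[
    match(paste(ema$responses$study_day[1], ema$responses$window_index[1]),
          paste(ema$prompts$study_day, ema$prompts$window_index))
  ] + 31 * 60
  pp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_ema(ema, pp, rp)
  expect_warning(back <- read_ema(pp, rp), "expiry")
  expect_equal(nrow(back$responses), nrow(ema$responses) - 1L)

  orphan <- ema
  orphan$responses$window_index[2] <- 99L
  write_ema(orphan, pp, rp)
  expect_error(suppressWarnings(read_ema(pp, rp)), "no matching prompt")

  # prompts file alone gives an empty response table
  only <- read_ema(pp)
  expect_equal(nrow(only$prompts), 168L)
  expect_equal(nrow(only$responses), 0L)
})

test_that("out-of-range item values are rejected", {
  cfg <- fx_small_config()
  ema <- generate_ema(cfg, seed = 5)
  ema$responses$ideation_worth[1] <- 7
  pp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_ema(ema, pp, rp)
  expect_error(read_ema(pp, rp), "likert")
})

test_that("lexicon loading normalizes, deduplicates, and self-matches", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# suicide phrases", "kill myself", "end it all",
               "Crying", "crying", ""), path)
  lex <- load_lexicon(path, name = "demo")
  phr <- lexicon_phrases(lex)
  expect_setequal(phr, c("kill myself", "end it all", "cry"))
  expect_equal(lengths(lex$entries)[match(c("kill myself", "end it all"), phr)],
               c(2L, 3L), ignore_attr = TRUE)
  # self-match property: every entry matches itself
  for (e in lex$entries) {
    expect_equal(unname(match_phrases(e, lex)[paste(e, collapse = " ")]), 1L)
  }
  # comments only -> error
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# nothing", "  "), empty)
  expect_error(load_lexicon(empty), "no phrases")
  # write-read round trip of the normalized form
  out <- withr::local_tempfile(fileext = ".txt")
  write_lexicon(lex, out)
  expect_setequal(lexicon_phrases(load_lexicon(out, name = "demo")), phr)
})

test_that("bundled lexicons load and self-match", {
  lexs <- bundled_lexicons()
  expect_true(all(c("suicide", "risk_factors", "crisis_synthetic", "substances")
                  %in% names(lexs)))
  for (lex in lexs) {
    for (e in lex$entries) {
      expect_true(paste(e, collapse = " ") %in% names(match_phrases(e, lex)))
    }
  }
})

test_that("study timeline validates hospitalization windows", {
  tl <- fx_timeline()
  expect_equal(tl$hospitalization_days, 29:32)
  expect_error(study_timeline("P", "2023-03-06", 35, c(29, 31)), "contiguous")
  expect_error(study_timeline("P", "2023-03-06", 35, 34:36), "within")
  expect_silent(study_timeline("P", "2023-03-06", 22, 18:22))
})
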