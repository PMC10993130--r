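test_that("phrase matching is greedy, longest-first, non-overlapping", {
  crisis <- lexicon("crisis", c("i just want this all to end", "hopeless"))
  got <- match_phrases(c("i", "just", "want", "this", "all", "to", "end"), crisis)
  expect_equal(got, c("i just want this all to end" = 1L))

  expect_equal(length(match_phrases(character(0), crisis)), 0L)

  lex <- lexicon("demo", c("end it all", "end"))
  got <- match_phrases(c("end", "it", "all", "end"), lex)
  expect_equal(got[["end it all"]], 1L)
  expect_equal(got[["end"]], 1L)
  # matches the brute-force oracle on the same case
  expect_equal(
    as.integer(got[order(names(got))]),
    as.integer(oracle_match(c("end", "it", "all", "end"),
                            c("end it all", "end"))[order(names(oracle_match(
                              c("end", "it", "all", "end"),
                              c("end it all", "end"))))])
  )
})

test_that("matcher agrees with the brute-force oracle on random screens", {
  set.seed(101)
  alphabet <- c("end", "it", "all", "to", "want", "i", "this", "pain", "x", "be")
  phrases <- c("end it all", "end", "i want", "want this all", "pain")
  lex <- lexicon("rand", phrases, normalizer = make_normalizer(lemmatize = FALSE))
  for (rep in 1:200) {
    toks <- sample(alphabet, sample(0:12, 1), replace = TRUE)
    got <- match_phrases(toks, lex)
    want <- oracle_match(toks, phrases)
    expect_equal(got[order(names(got))], want[order(names(want))],
                 ignore_attr = TRUE,
                 label = paste("tokens:", paste(toks, collapse = " ")))
    expect_equal(sum(got), sum(want))
  }
})

test_that("daily counts bin by study day and are order-invariant and additive", {
  tl <- fx_timeline(n_days = 5, hosp = integer())
  lex <- lexicon("pain", "pain")
  scr <- fx_screens(
    list(c("pain", "x"), c("x", "pain", "pain"), c("zz"), c("pain")),
    days = c(2, 2, 3, 4)
  )
  got <- daily_counts(scr, lex, tl)
  expect_equal(got$raw_count, c(0, 3, 0, 1, 0))
  # permuting screens within a day leaves counts unchanged
  perm <- scr[c(2, 1, 3, 4), ]
  expect_equal(daily_counts(perm, lex, tl)$raw_count, got$raw_count)
  # additivity over any partition of the stream
  parts <- daily_counts(scr[1:2, ], lex, tl)$raw_count +
    daily_counts(scr[3:4, ], lex, tl)$raw_count
  expect_equal(parts, got$raw_count)
  # screens outside the window error
  bad <- fx_screens(list(c("pain")), days = 9)
  expect_error(daily_counts(bad, lex, tl), "outside study days")
})

test_that("ratio scores follow the day-over-total convention", {
  base <- tibble::tibble(person_id = "P1", lexicon = "l",
                         study_day = 1:3, raw_count = c(2, 3, 5))
  expect_equal(ratio_scores(base)$ratio, c(0.2, 0.3, 0.5))
  zero <- dplyr::mutate(base, raw_count = 0)
  expect_equal(ratio_scores(zero)$ratio, c(0, 0, 0))
  one <- base[1, ]
  one$raw_count <- 7
  expect_equal(ratio_scores(one)$ratio, 1)
})

test_that("ratio conservation holds across random count series", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    counts <- if (i <= 5) rep(0, n) else rpois(n, sample(c(0.2, 2, 20), 1))
    s <- tibble::tibble(person_id = "P", lexicon = "l",
                        study_day = seq_len(n), raw_count = counts)
    total <- sum(ratio_scores(s)$ratio)
    expect_true(abs(total - 0) < 1e-12 || abs(total - 1) < 1e-12)
  }
})

test_that("top-k words rank by count with alphabetical ties", {
  lex <- lexicon("risk", c("pain", "alone", "guilty", "numb"))
  scr <- fx_screens(list(
    rep("pain", 5), c("alone", "alone", "guilty"), c("numb", "alone")
  ))
  got <- top_k_words(scr, lex, k = 10)
  expect_equal(got$phrase, c("pain", "alone", "guilty", "numb"))
  expect_equal(got$count, c(5L, 3L, 1L, 1L))
  expect_equal(top_k_words(scr, lex, k = 1)$phrase, "pain")
  none <- fx_screens(list(c("zz", "yy")))
  expect_equal(nrow(top_k_words(none, lex, k = 10)), 0L)
})

test_that("hourly counts partition the day's raw count", {
  lex <- lexicon("pain", "pain")
  scr <- fx_screens(list(c("pain"), c("pain", "pain"), c("x")),
                    hours = c(21, 21, 9))
  got <- hourly_counts(scr, lex)
  expect_equal(got$count[got$hour == 21], 3)
  expect_equal(sum(got$count), 3)
  empty <- fx_screens(list(character(0)))
  expect_equal(sum(hourly_counts(empty, lex)$count), 0)
  mixed <- fx_screens(list(c("pain"), c("pain")), days = c(1, 2))
  expect_error(hourly_counts(mixed, lex), "one day")
})

test_that("app tagging uses the keyword lexicons, both may apply", {
  expect_equal(tag_app_category(c("write", "a", "comment", "now")), "Meta")
  expect_equal(tag_app_category(c("new", "text", "message")), "SMS")
  expect_equal(tag_app_category(c("weather", "today")), character(0))
  both <- tag_app_category(c("text", "message", "on", "facebook"))
  expect_setequal(both, c("SMS", "Meta"))
  # normalized matching: case-insensitive "Instagram"
  norm <- default_normalizer()
  expect_equal(tag_app_category(norm("Open Instagram now")[[1]]), "Meta")
})

test_that("daily app usage counts screens per category", {
  tl <- fx_timeline(n_days = 3, hosp = integer())
  scr <- fx_screens(list(
    c("text", "message", "hi"), c("facebook", "feed"), c("sms", "facebook"),
    c("nothing", "here")
  ), days = c(1, 1, 2, 2))
  got <- app_usage_daily(scr, tl)
  expect_equal(got$count[got$category == "SMS"], c(1L, 1L, 0L))
  expect_equal(got$count[got$category == "Meta"], c(1L, 1L, 0L))
  # a screen never counts more than once per category per day
  expect_true(all(got$count <= c(2, 2, 2, 2, 0, 0)))
})

test_that("social aggregation sums per-day predicted probabilities", {
  tl <- fx_timeline(n_days = 2, hosp = integer())
  ev <- fx_events(list(
    list(social = 1.0), list(social = 1.0), list(social = 1.0),
    list(day = 2, social = 0.5), list(day = 2, social = NULL)
  ))
  got <- aggregate_social(ev, tl)
  expect_equal(got$social_score, c(3.0, 0.5))
  # linearity: ten screens at 0.5 sum to 5
  ev10 <- fx_events(lapply(1:10, function(i) list(social = 0.5)))
  expect_equal(aggregate_social(ev10, tl)$social_score[1], 5.0)
  # missing everywhere -> empty series with warning
  none <- fx_events(list(list(), list()))
  expect_warning(out <- aggregate_social(none, tl), "no social")
  expect_equal(nrow(out), 0L)
})
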