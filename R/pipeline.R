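#' Run the full risk-profiling pipeline on a synthetic person
#'
#' Convenience wrapper chaining every stage on generated data: generate ->
#' confidence-filter -> normalize -> remove EMA screens (for suicide-related
#' lexicons) -> lexicon scoring -> app/social aggregation -> EMA metrics ->
#' usage metrics -> hospitalization-aligned profile. Deterministic for a
#' given `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param conf_threshold OCR confidence threshold (default 0.70).
#' @param normalizer Text normalizer shared by screens and lexicons.
#' @return `list(profile, compliance, person, screens)`: the person-day
#'   profile table, the person's compliance summary, the generated bundle,
#'   and the normalized screens.
#' @export
profile_pipeline <- function(config = synth_config(), seed = 1L,
                             conf_threshold = 0.70,
                             normalizer = default_normalizer()) {
  person <- generate_person(config, seed)
  timeline <- person$timeline
  filtered <- filter_confidence(person$events, conf_threshold)
  screens <- normalize_screens(filtered, normalizer)
  clean <- remove_ema_screens(screens, default_ema_item_phrases(normalizer))
  scores <- lapply(config$text$lexicons, function(lex) {
    ratio_scores(daily_counts(clean, lex, timeline))
  })
  app <- app_usage_daily(screens, timeline,
                         default_app_lexicons(normalizer))
  social <- suppressWarnings(aggregate_social(screens, timeline))
  usage <- daily_screen_counts(person$events, timeline)
  prof <- build_profile(
    timeline, usage = usage, scores = scores, app = app,
    social = if (nrow(social) > 0L) social else NULL,
    ema = list(prompts = person$prompts, responses = person$responses)
  )
  list(
    profile = prof,
    compliance = compliance(person$prompts, person$responses),
    person = person,
    screens = screens
  )
}

#' Write a profile table to CSV
#'
#' Deterministic CSV writer for profile tables: fixed column order and full
#' numeric precision, so identical pipelines produce byte-identical files.
#'
#' @param profile A profile tibble from [build_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(profile, path, progress = FALSE)
  invisible(path)
}
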