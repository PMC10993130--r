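#' Screen-capture event streams
#'
#' A screen-event stream is a tidy tibble with one row per OCR text block:
#' `person_id`, `screen_id` (one captured screen, i.e. one 5-second capture
#' slot), `ts` (`POSIXct`, UTC), `utc_offset` (seconds; one fixed offset per
#' person so local-day binning is unambiguous), `block` (1-based reading
#' order), `text`, `conf` (OCR confidence in `[0, 1]`), and `social_prob`
#' (optional externally produced per-screen probability that the screen shows
#' social-app content; `NA` when absent). A screen whose blocks were all
#' removed keeps a single placeholder row with `block = NA`, so that the
#' capture itself still counts toward phone-use metrics.
#'
#' @param person_id,ts,utc_offset,block,text,conf,social_prob Column values,
#'   recycled to a common length. `screen_id` is assigned from distinct `ts`
#'   when omitted.
#' @param screen_id Optional explicit screen identifier.
#' @return A validated `tbl_df` of class `screen_events`.
#' @export
screen_events <- function(person_id, ts, utc_offset, text = NA_character_,
                          conf = NA_real_, block = NA_integer_,
                          screen_id = NULL, social_prob = NA_real_) {
  df <- tibble::tibble(
    person_id = as.character(person_id),
    ts = ts,
    utc_offset = as.integer(utc_offset),
    block = as.integer(block),
    text = as.character(text),
    conf = as.numeric(conf),
    social_prob = as.numeric(social_prob)
  )
  if (is.null(screen_id)) {
    key <- paste(df$person_id, as.numeric(df$ts))
    df$screen_id <- match(key, unique(key))
  } else {
    df$screen_id <- as.integer(screen_id)
  }
  df <- df[, c("person_id", "screen_id", "ts", "utc_offset", "block",
               "text", "conf", "social_prob")]
  df <- dplyr::arrange(df, .data$person_id, .data$ts, .data$screen_id, .data$block)
  validate_screen_events(df)
}

#' @rdname screen_events
#' @param events A candidate screen-event tibble.
#' @export
validate_screen_events <- function(events) {
  need <- c("person_id", "screen_id", "ts", "utc_offset", "block",
            "text", "conf", "social_prob")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L) {
    stop_screenome("screen events missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!inherits(events$ts, "POSIXct")) {
    stop_screenome("`ts` must be POSIXct")
  }
  conf <- events$conf[!is.na(events$conf)]
  if (any(conf < 0 | conf > 1)) {
    stop_screenome("OCR confidence outside [0, 1]")
  }
  sp <- events$social_prob[!is.na(events$social_prob)]
  if (any(sp < 0 | sp > 1)) {
    stop_screenome("social_prob outside [0, 1]")
  }
  off <- tapply(events$utc_offset, events$person_id, function(o) length(unique(o)))
  if (any(off > 1L)) {
    stop_screenome("each person must have a single fixed UTC offset")
  }
  class(events) <- unique(c("screen_events", class(events)))
  events
}

# One row per captured screen (drops block structure).
distinct_screens <- function(events) {
  dplyr::distinct(
    tibble::as_tibble(events)[, c("person_id", "screen_id", "ts", "utc_offset", "social_prob")]
  )
}

#' Study timeline for one person
#'
#' Anchors calendar dates to 1-based study days and records the (contiguous)
#' hospitalization days used for event alignment.
#'
#' @param person_id Person identifier.
#' @param study_start `Date` of study day 1.
#' @param n_days Number of study days.
#' @param hospitalization_days Integer vector of study days spent
#'   hospitalized; must be contiguous and within `[1, n_days]`. May be empty.
#' @return An object of class `study_timeline`.
#' @examples
#' study_timeline("A", as.Date("2023-03-06"), 35, hospitalization_days = 29:32)
#' @export
study_timeline <- function(person_id, study_start, n_days,
                           hospitalization_days = integer()) {
  study_start <- as.Date(study_start)
  n_days <- as.integer(n_days)
  hosp <- sort(unique(as.integer(hospitalization_days)))
  stopifnot(length(n_days) == 1L, n_days >= 1L, !is.na(study_start))
  if (length(hosp) > 0L) {
    if (min(hosp) < 1L || max(hosp) > n_days) {
      stop_screenome("hospitalization days must lie within [1, n_days]")
    }
    if (!all(diff(hosp) == 1L)) {
      stop_screenome("hospitalization days must be contiguous")
    }
  }
  structure(
    list(person_id = as.character(person_id), study_start = study_start,
         n_days = n_days, hospitalization_days = hosp),
    class = "study_timeline"
  )
}

#' @export
print.study_timeline <- function(x, ...) {
  cat("<study_timeline> person", x$person_id, "starting", format(x$study_start),
      "for", x$n_days, "days")
  if (length(x$hospitalization_days) > 0L) {
    cat("; hospitalized days", min(x$hospitalization_days), "-",
        max(x$hospitalization_days))
  }
  cat("\n")
  invisible(x)
}

#' Phrase lexicons
#'
#' A lexicon is a named, deduplicated set of normalized phrases (each an
#' ordered vector of one or more lowercase alphabetic lemmas) used for
#' dictionary-based scoring of screen text. Phrases are normalized at
#' construction with the same normalizer later applied to screen text, so any
#' loaded entry matches itself.
#'
#' @param name Lexicon name (used in score series).
#' @param phrases Character vector of raw phrases.
#' @param normalizer A normalizer from [make_normalizer()].
#' @return An object of class `lexicon` with fields `name` and `entries`
#'   (a list of token vectors).
#' @examples
#' lex <- lexicon("suicide", c("kill myself", "end it all"))
#' lexicon_phrases(lex)
#' @export
lexicon <- function(name, phrases, normalizer = default_normalizer()) {
  toks <- normalizer(as.character(phrases))
  toks <- toks[vapply(toks, length, integer(1)) > 0L]
  keys <- vapply(toks, paste, character(1), collapse = " ")
  toks <- toks[!duplicated(keys)]
  if (length(toks) == 0L) {
    stop_screenome("lexicon '", name, "' is empty after normalization")
  }
  structure(list(name = as.character(name), entries = toks), class = "lexicon")
}

#' @rdname lexicon
#' @param x A `lexicon`.
#' @export
lexicon_phrases <- function(x) {
  stopifnot(inherits(x, "lexicon"))
  vapply(x$entries, paste, character(1), collapse = " ")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", x$name, "with", length(x$entries), "phrase(s)\n")
  cat(paste(" -", utils::head(lexicon_phrases(x), 10)), sep = "\n")
  if (length(x$entries) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
format.lexicon <- function(x, ...) {
  paste0("<lexicon ", x$name, ": ", length(x$entries), " phrases>")
}

#' EMA item registry
#'
#' Declares the momentary self-report items: response type (`likert` 1-5,
#' `binary` 0/1, or `pain` 0-100), membership in the three summed suicide
#' composites (4 ideation, 3 planning, 2 desire items), and whether the item
#' is asked once per day (sleep items at the morning prompt; pain once daily).
#'
#' @return A tibble with columns `item`, `type`, `composite`, `daily`.
#' @export
ema_item_registry <- function() {
  tibble::tribble(
    ~item,                   ~type,    ~composite, ~daily,
    "ideation_worth",        "likert", "ideation", FALSE,
    "ideation_reasons",      "likert", "ideation", FALSE,
    "ideation_want_die",     "likert", "ideation", FALSE,
    "ideation_taking_life",  "likert", "ideation", FALSE,
    "planning_method",       "likert", "planning", FALSE,
    "planning_acquire",      "likert", "planning", FALSE,
    "planning_prepared",     "likert", "planning", FALSE,
    "desire_attempt_urge",   "likert", "desire",   FALSE,
    "desire_kill_intensity", "likert", "desire",   FALSE,
    "burdensomeness",        "likert", NA,         FALSE,
    "belongingness",         "likert", NA,         FALSE,
    "affect_negative",       "likert", NA,         FALSE,
    "affect_positive",       "likert", NA,         FALSE,
    "urge_nssi",             "likert", NA,         FALSE,
    "urge_alcohol",          "likert", NA,         FALSE,
    "urge_drug",             "likert", NA,         FALSE,
    "conflict",              "binary", NA,         FALSE,
    "behavior_nssi",         "binary", NA,         FALSE,
    "behavior_alcohol",      "binary", NA,         FALSE,
    "nightmares",            "binary", NA,         TRUE,
    "sleep_quality",         "likert", NA,         TRUE,
    "pain",                  "pain",   NA,         TRUE
  )
}

#' Survey-item wordings rendered on screen during a prompt
#'
#' Screens showing the momentary survey itself would otherwise contribute
#' their item wordings ("I want to die", ...) to the suicide dictionaries; the
#' scoring pipeline removes any screen containing at least one full item
#' phrase. These are the default wordings.
#'
#' @param normalizer Normalizer shared with the screen text.
#' @return A `lexicon` of item phrases.
#' @export
default_ema_item_phrases <- function(normalizer = default_normalizer()) {
  lexicon(
    "ema_items",
    c(
      "Life is not worth living for me",
      "There are more reasons to die than to live",
      "I want to die",
      "I think about taking my life",
      "Considered a specific suicide method",
      "Identified how to acquire your suicide method",
      "Made other preparations for your death",
      "How strong is your urge to make a suicide attempt",
      "How intense is your desire to kill yourself"
    ),
    normalizer = normalizer
  )
}

#' Default app-identification keyword lexicons
#'
#' Keywords rendered on screen identify which app is in use: text messaging
#' (SMS) versus Meta-family apps. The single word "text" over-matches by
#' construction; replace the defaults for stricter tagging.
#'
#' @param normalizer Normalizer shared with the screen text.
#' @return Named list of `lexicon` objects (`SMS`, `Meta`).
#' @export
default_app_lexicons <- function(normalizer = default_normalizer()) {
  list(
    SMS = lexicon("SMS", c("text message", "sms", "text"), normalizer),
    Meta = lexicon(
      "Meta",
      c("write a comment", "what's on your mind", "like", "facebook", "instagram"),
      normalizer
    )
  )
}
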