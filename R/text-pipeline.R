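#' Filter OCR blocks by confidence
#'
#' Removes text blocks whose OCR confidence is strictly below `threshold`
#' (default 0.70); blocks exactly at the threshold are retained. Screens that
#' lose every block are kept as empty-capture placeholder rows so phone-use
#' metrics still see them. Idempotent, and monotone in the threshold.
#'
#' @param events A `screen_events` tibble.
#' @param threshold Confidence cut in `[0, 1]`.
#' @return Filtered `screen_events`.
#' @export
filter_confidence <- function(events, threshold = 0.70) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  events <- validate_screen_events(events)
  if (nrow(events) == 0L) return(events)
  keep <- is.na(events$block) | events$conf >= threshold
  kept <- events[keep, ]
  lost_ids <- setdiff(unique(events$screen_id), unique(kept$screen_id))
  if (length(lost_ids) > 0L) {
    ph <- events[!duplicated(events$screen_id) & events$screen_id %in% lost_ids, ]
    ph$block <- NA_integer_
    ph$text <- NA_character_
    ph$conf <- NA_real_
    kept <- dplyr::bind_rows(kept, ph)
  }
  kept <- dplyr::arrange(kept, .data$person_id, .data$ts, .data$screen_id, .data$block)
  validate_screen_events(kept)
}

#' Normalize screen events into token streams
#'
#' Concatenates each screen's surviving blocks in reading order and applies
#' the normalizer (case reduction, punctuation/digit removal, lemmatization).
#' One row per screen; screens with no usable text get an empty token vector.
#'
#' @param events A `screen_events` tibble (typically confidence-filtered).
#' @param normalizer Normalizer from [make_normalizer()].
#' @return A tibble of class `normalized_screens`: `person_id`, `screen_id`,
#'   `ts`, `utc_offset`, `social_prob`, `tokens` (list column).
#' @export
normalize_screens <- function(events, normalizer = default_normalizer()) {
  events <- validate_screen_events(events)
  scr <- distinct_screens(events)
  if (nrow(scr) == 0L) {
    out <- tibble::tibble(
      person_id = character(), screen_id = integer(),
      ts = as.POSIXct(character(), tz = "UTC"), utc_offset = integer(),
      social_prob = numeric(), tokens = list()
    )
    class(out) <- unique(c("normalized_screens", class(out)))
    return(out)
  }
  with_text <- events[!is.na(events$block), ]
  joined <- character(nrow(scr))
  if (nrow(with_text) > 0L) {
    agg <- vapply(
      split(with_text$text[order(with_text$screen_id, with_text$block)],
            with_text$screen_id[order(with_text$screen_id, with_text$block)]),
      paste, character(1), collapse = " "
    )
    hit <- match(as.character(scr$screen_id), names(agg))
    joined[!is.na(hit)] <- agg[hit[!is.na(hit)]]
  }
  out <- scr
  out$tokens <- normalizer(joined)
  out <- dplyr::arrange(out, .data$person_id, .data$ts, .data$screen_id)
  class(out) <- unique(c("normalized_screens", class(out)))
  out
}

# Does `tokens` contain `phrase` (vector of tokens) as a contiguous run?
contains_phrase <- function(tokens, phrase) {
  np <- length(phrase)
  nt <- length(tokens)
  if (np == 0L || nt < np) return(FALSE)
  starts <- which(tokens == phrase[1])
  starts <- starts[starts + np - 1L <= nt]
  for (s in starts) {
    if (all(tokens[s:(s + np - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

#' Remove screens that render the EMA survey itself
#'
#' Before suicide-language dictionaries are applied, screens that contain an
#' EMA prompt are dropped so that item wordings shown by the survey app are
#' not counted as organic suicide-related text. A screen is removed when its
#' token stream contains at least one full item phrase; partial overlap (a
#' shared word) never removes a screen.
#'
#' @param screens A `normalized_screens` tibble.
#' @param ema_item_phrases A non-empty [lexicon()] of item wordings, see
#'   [default_ema_item_phrases()].
#' @return The retained screens, in original order, with attribute
#'   `n_removed` giving the excluded count.
#' @export
remove_ema_screens <- function(screens, ema_item_phrases = default_ema_item_phrases()) {
  if (!inherits(ema_item_phrases, "lexicon") || length(ema_item_phrases$entries) == 0L) {
    stop_screenome("a non-empty EMA item-phrase lexicon is required")
  }
  if (nrow(screens) == 0L) {
    attr(screens, "n_removed") <- 0L
    return(screens)
  }
  entries <- ema_item_phrases$entries
  is_ema <- vapply(screens$tokens, function(tok) {
    for (e in entries) if (contains_phrase(tok, e)) return(TRUE)
    FALSE
  }, logical(1))
  out <- screens[!is_ema, ]
  attr(out, "n_removed") <- sum(is_ema)
  out
}

#' Randomly sample screens from one person-day
#'
#' Uniform sample without replacement of `min(n, available)` screens, used to
#' audit content on high-interest days (e.g. the day prior to
#' hospitalization). Reproducible for a given seed.
#'
#' @param screens Screens from a single person and local calendar day
#'   (`screen_events` or `normalized_screens`).
#' @param n Target sample size (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return The sampled rows in time order.
#' @export
sample_day_screens <- function(screens, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (nrow(screens) == 0L) return(screens)
  days <- unique(local_date(screens$ts, screens$utc_offset))
  if (length(unique(screens$person_id)) > 1L || length(days) > 1L) {
    stop_screenome("screens must come from a single person-day")
  }
  ids <- unique(screens$screen_id)
  pick <- with_seed(seed, sample(ids, size = min(n, length(ids))))
  out <- screens[screens$screen_id %in% pick, ]
  dplyr::arrange(out, .data$ts, .data$screen_id)
}

#' Collapse consecutive identical screens
#'
#' A static screen re-captures every 5 seconds; by default every capture
#' counts (it reflects exposure time). This optional step collapses runs of
#' consecutive screens with identical token streams to their first capture,
#' for analyses of distinct content.
#'
#' @param screens A `normalized_screens` tibble.
#' @return Screens with consecutive duplicate token streams removed.
#' @export
dedup_consecutive <- function(screens) {
  if (nrow(screens) < 2L) return(screens)
  key <- vapply(screens$tokens, paste, character(1), collapse = " ")
  same_person <- c(FALSE, screens$person_id[-1] == screens$person_id[-nrow(screens)])
  dup <- c(FALSE, key[-1] == key[-length(key)]) & same_person
  screens[!dup, ]
}
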