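#' Count lexicon phrase occurrences in one token stream
#'
#' Scans the tokens left to right and counts non-overlapping phrase
#' occurrences, preferring the longest matching entry at each position
#' (ties between equal-length entries broken alphabetically). Greedy
#' longest-first matching prevents a phrase and its sub-phrase ("end it all"
#' vs "end") from both being counted at one position, while both can still
#' match at different positions.
#'
#' @param tokens Character vector of normalized tokens (or a one-row
#'   `normalized_screens` tibble's `tokens[[1]]`).
#' @param lex A [lexicon()] normalized with the same normalizer.
#' @return Named integer vector of counts for the phrases that matched at
#'   least once (empty when nothing matched).
#' @examples
#' lex <- lexicon("demo", c("end it all", "end"))
#' match_phrases(c("end", "it", "all", "end"), lex)
#' @export
match_phrases <- function(tokens, lex) {
  stopifnot(inherits(lex, "lexicon"))
  idx <- lexicon_index(lex)
  counts <- match_count_vec(tokens, idx)
  counts[counts > 0L]
}

# Precompute matcher state: entries ordered longest-first (alphabetical within
# length) and bucketed by first token.
lexicon_index <- function(lex) {
  cached <- attr(lex, ".index")
  if (!is.null(cached)) return(cached)
  phrases <- lexicon_phrases(lex)
  len <- vapply(lex$entries, length, integer(1))
  ord <- order(-len, phrases)
  entries <- lex$entries[ord]
  firsts <- vapply(entries, `[`, character(1), 1L)
  idx <- list(
    entries = entries,
    lengths = len[ord],
    phrases = phrases[ord],
    firsts = firsts,
    by_first = split(seq_along(entries), firsts),
    max_len = max(len)
  )
  idx
}

# Greedy longest-first scan; returns counts aligned with idx$phrases.
match_count_vec <- function(tokens, idx) {
  counts <- integer(length(idx$entries))
  names(counts) <- idx$phrases
  nt <- length(tokens)
  if (nt == 0L) return(counts)
  cand <- which(tokens %in% names(idx$by_first))
  if (length(cand) == 0L) return(counts)
  ci <- 1L
  while (ci <= length(cand)) {
    i <- cand[ci]
    hit <- 0L
    for (j in idx$by_first[[tokens[i]]]) {
      L <- idx$lengths[j]
      if (i + L - 1L <= nt && all(tokens[i:(i + L - 1L)] == idx$entries[[j]])) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      counts[hit] <- counts[hit] + 1L
      nxt <- i + idx$lengths[hit]
      while (ci <= length(cand) && cand[ci] < nxt) ci <- ci + 1L
    } else {
      ci <- ci + 1L
    }
  }
  counts
}

# Total matched occurrences per screen for a list of token vectors.
count_matches <- function(tokens_list, lex) {
  idx <- lexicon_index(lex)
  vapply(tokens_list, function(tok) sum(match_count_vec(tok, idx)), numeric(1))
}

#' Daily lexicon score series
#'
#' `daily_counts()` sums phrase matches per study day (days without screens
#' count 0); `ratio_scores()` converts raw counts to the ratio convention
#' used for display: each day's score divided by the total over the
#' observation window, so ratios sum to 1 (or are all exactly 0 for an
#' all-zero series). For suicide-related lexicons, pass screens through
#' [remove_ema_screens()] first.
#'
#' @param screens A `normalized_screens` tibble for one person.
#' @param lex A [lexicon()].
#' @param timeline The person's [study_timeline()].
#' @return A tibble (`daily_score_series`): `person_id`, `lexicon`,
#'   `study_day` (1..n_days), `raw_count`; `ratio_scores()` adds `ratio`.
#' @export
daily_counts <- function(screens, lex, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  n_days <- timeline$n_days
  out <- tibble::tibble(
    person_id = timeline$person_id,
    lexicon = lex$name,
    study_day = seq_len(n_days),
    raw_count = 0
  )
  if (nrow(screens) > 0L) {
    day <- study_day_of(screens$ts, screens$utc_offset, timeline)
    if (any(day < 1L | day > n_days)) {
      stop_screenome("screen(s) fall outside study days [1, ", n_days, "]")
    }
    per_screen <- count_matches(screens$tokens, lex)
    sums <- rowsum(per_screen, group = day)
    out$raw_count[as.integer(rownames(sums))] <- as.numeric(sums)
  }
  class(out) <- unique(c("daily_score_series", class(out)))
  out
}

#' @rdname daily_counts
#' @param series A raw `daily_score_series` from `daily_counts()` (or any
#'   tibble with `person_id`, `lexicon`, `raw_count`).
#' @export
ratio_scores <- function(series) {
  stopifnot("raw_count" %in% names(series))
  series |>
    dplyr::group_by(.data$person_id, .data$lexicon) |>
    dplyr::mutate(
      ratio = if (sum(.data$raw_count) == 0) 0 else .data$raw_count / sum(.data$raw_count)
    ) |>
    dplyr::ungroup()
}

#' Top-k endorsed lexicon phrases
#'
#' Totals each phrase over all screens and returns the `k` most frequent
#' (ties broken alphabetically); phrases that never match are omitted, so
#' fewer than `k` rows may be returned.
#'
#' @inheritParams daily_counts
#' @param k Number of phrases to keep (>= 1).
#' @return Tibble with columns `phrase`, `count`, sorted by descending count.
#' @export
top_k_words <- function(screens, lex, k = 10) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  idx <- lexicon_index(lex)
  total <- integer(length(idx$phrases))
  for (tok in screens$tokens) total <- total + match_count_vec(tok, idx)
  keep <- total > 0L
  out <- tibble::tibble(phrase = idx$phrases[keep], count = as.integer(total[keep]))
  out <- out[order(-out$count, out$phrase), ]
  utils::head(out, k)
}

#' Within-day hourly lexicon counts
#'
#' For screens from a single local calendar day, counts matches per hour bin
#' `[h, h+1)`; hours sum to the day's raw count.
#'
#' @inheritParams daily_counts
#' @return Tibble `hour` (0-23), `count`.
#' @export
hourly_counts <- function(screens, lex) {
  out <- tibble::tibble(hour = 0:23, count = 0)
  if (nrow(screens) == 0L) return(out)
  days <- unique(local_date(screens$ts, screens$utc_offset))
  if (length(days) > 1L) {
    stop_screenome("screens span multiple calendar days; hourly counts need one day")
  }
  hr <- local_hour(screens$ts, screens$utc_offset)
  per_screen <- count_matches(screens$tokens, lex)
  sums <- rowsum(per_screen, group = hr)
  out$count[as.integer(rownames(sums)) + 1L] <- as.numeric(sums)
  out
}

#' Tag the app category a screen belongs to
#'
#' A screen is tagged with a category when at least one of the category's
#' keyword phrases occurs in its token stream; a screen may carry several
#' categories (or none).
#'
#' @param tokens Normalized token vector for one screen.
#' @param app_lexicons Named list of category lexicons,
#'   see [default_app_lexicons()].
#' @return Character vector of matching category names.
#' @export
tag_app_category <- function(tokens, app_lexicons = default_app_lexicons()) {
  hits <- vapply(app_lexicons, function(lex) {
    for (e in lex$entries) if (contains_phrase(tokens, e)) return(TRUE)
    FALSE
  }, logical(1))
  names(app_lexicons)[hits]
}

#' Daily app-category usage series
#'
#' Counts, per study day and category, the screens whose text identifies the
#' category's app; a screen may count toward several categories.
#'
#' @inheritParams daily_counts
#' @param app_lexicons Named list of category lexicons.
#' @return Tibble `person_id`, `study_day`, `category`, `count` (all days x
#'   categories, zero-filled).
#' @export
app_usage_daily <- function(screens, timeline,
                            app_lexicons = default_app_lexicons()) {
  stopifnot(inherits(timeline, "study_timeline"))
  grid <- tidyr::expand_grid(
    person_id = timeline$person_id,
    study_day = seq_len(timeline$n_days),
    category = names(app_lexicons)
  )
  grid$count <- 0L
  if (nrow(screens) == 0L) return(grid)
  day <- study_day_of(screens$ts, screens$utc_offset, timeline)
  for (cat_name in names(app_lexicons)) {
    lex <- app_lexicons[[cat_name]]
    tagged <- vapply(screens$tokens, function(tok) {
      for (e in lex$entries) if (contains_phrase(tok, e)) return(TRUE)
      FALSE
    }, logical(1))
    if (any(tagged)) {
      tab <- table(day[tagged])
      sel <- grid$category == cat_name &
        grid$study_day %in% as.integer(names(tab))
      grid$count[sel] <- as.integer(tab[as.character(grid$study_day[sel])])
    }
  }
  grid
}

#' Aggregate externally predicted social-content probabilities by day
#'
#' Sums each day's per-screen probabilities that the screen shows social-app
#' content (an expected count of social screens). Screens with no prediction
#' are treated as absent, not as zero.
#'
#' @param screens `screen_events` or `normalized_screens` with a
#'   `social_prob` column.
#' @param timeline The person's [study_timeline()].
#' @return Tibble `person_id`, `study_day`, `social_score`. When no screen
#'   carries a probability the series is empty (zero rows) and a warning is
#'   raised.
#' @export
aggregate_social <- function(screens, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  scr <- if (inherits(screens, "screen_events")) distinct_screens(screens) else screens
  scr <- scr[!is.na(scr$social_prob), ]
  if (nrow(scr) == 0L) {
    warning("no social-content probabilities present; returning empty series",
            call. = FALSE)
    return(tibble::tibble(person_id = character(), study_day = integer(),
                          social_score = numeric()))
  }
  day <- study_day_of(scr$ts, scr$utc_offset, timeline)
  out <- tibble::tibble(
    person_id = timeline$person_id,
    study_day = seq_len(timeline$n_days),
    social_score = 0
  )
  sums <- rowsum(scr$social_prob, group = day)
  out$social_score[as.integer(rownames(sums))] <- as.numeric(sums)
  out
}
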