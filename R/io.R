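#' Read a screen-event stream from JSON-lines
#'
#' One JSON record per line:
#' `{"person_id", "ts" (ISO-8601 with offset), "blocks": [{"text","conf"}],
#' "social_prob"?}`. Events are returned in timestamp order within person.
#' Malformed lines and out-of-range confidences raise errors naming the line.
#'
#' @param path Path to a `.jsonl` file.
#' @return A `screen_events` tibble (see [screen_events()]); zero rows for an
#'   empty file.
#' @seealso [write_screen_events()]
#' @export
read_screen_events <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(empty_screen_events())
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop_screenome("malformed JSON on line ", line_no[i], ": ", conditionMessage(e))
      }
    )
    if (is.null(rec$person_id) || is.null(rec$ts)) {
      stop_screenome("line ", line_no[i], ": record needs 'person_id' and 'ts'")
    }
    parsed <- parse_iso_ts(rec$ts)
    blocks <- rec$blocks %||% list()
    nb <- length(blocks)
    conf <- if (nb) vapply(blocks, function(b) as.numeric(b$conf %||% NA_real_), numeric(1)) else numeric(0)
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      stop_screenome("line ", line_no[i], ": confidence outside [0, 1]")
    }
    rows[[i]] <- tibble::tibble(
      person_id = as.character(rec$person_id),
      screen_id = i,
      ts = parsed$ts,
      utc_offset = parsed$offset,
      block = if (nb) seq_len(nb) else NA_integer_,
      text = if (nb) vapply(blocks, function(b) as.character(b$text %||% ""), character(1)) else NA_character_,
      conf = if (nb) conf else NA_real_,
      social_prob = as.numeric(rec$social_prob %||% NA_real_)
    )
  }
  df <- dplyr::bind_rows(rows)
  df <- dplyr::arrange(df, .data$person_id, .data$ts, .data$screen_id, .data$block)
  validate_screen_events(df)
}

empty_screen_events <- function() {
  validate_screen_events(tibble::tibble(
    person_id = character(), screen_id = integer(),
    ts = as.POSIXct(character(), tz = "UTC"), utc_offset = integer(),
    block = integer(), text = character(), conf = numeric(),
    social_prob = numeric()
  ))
}

#' Write a screen-event stream as JSON-lines
#'
#' Inverse of [read_screen_events()]: writing then reading a valid stream is
#' the identity (up to screen-id relabelling in file order).
#'
#' @param events A `screen_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_events <- function(events, path) {
  events <- validate_screen_events(events)
  idx <- split(seq_len(nrow(events)), events$screen_id)
  ord <- order(vapply(idx, function(i) min(as.numeric(events$ts[i])), numeric(1)),
               vapply(idx, function(i) events$screen_id[i[1]], numeric(1)))
  idx <- idx[ord]
  out <- vapply(idx, function(i) {
    first <- i[1]
    has_blocks <- !all(is.na(events$block[i]))
    rec <- list(
      person_id = events$person_id[first],
      ts = format_iso_ts(events$ts[first], events$utc_offset[first]),
      blocks = if (has_blocks) {
        lapply(i, function(j) list(text = events$text[j], conf = events$conf[j]))
      } else {
        list()
      }
    )
    if (!is.na(events$social_prob[first])) rec$social_prob <- events$social_prob[first]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read EMA prompt and response tables
#'
#' Prompts (`person_id, study_day, window_index, issued_at`) describe the
#' signal-contingent schedule: 6 prompts/day delivered randomly within 2-hour
#' windows, valid for 30 minutes with a reminder at 15. Responses
#' (`person_id, study_day, window_index, completed_at`, plus one column per
#' item) join to exactly one prompt; responses completed after the 30-minute
#' expiry are dropped with a warning, and orphan responses are an error. Item
#' values are validated against the registry (Likert 1-5, binary 0/1,
#' pain 0-100).
#'
#' @param prompt_path,response_path CSV paths; `response_path` may be `NULL`
#'   (prompts only).
#' @param registry Item registry, see [ema_item_registry()].
#' @return `list(prompts = <tibble>, responses = <tibble>)`; prompts carry
#'   computed `expires_at` and `reminder_at`.
#' @export
read_ema <- function(prompt_path, response_path = NULL,
                     registry = ema_item_registry()) {
  prompts <- readr::read_csv(
    prompt_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(person_id = readr::col_character(),
                            issued_at = readr::col_character())
  )
  need <- c("person_id", "study_day", "window_index", "issued_at")
  miss <- setdiff(need, names(prompts))
  if (length(miss)) stop_screenome("prompts missing column(s): ", paste(miss, collapse = ", "))
  pi <- parse_iso_ts(prompts$issued_at)
  prompts <- tibble::tibble(
    person_id = as.character(prompts$person_id),
    study_day = as.integer(prompts$study_day),
    window_index = as.integer(prompts$window_index),
    issued_at = pi$ts, utc_offset = pi$offset,
    reminder_at = pi$ts + 15 * 60,
    expires_at = pi$ts + 30 * 60
  )
  if (any(prompts$study_day < 1L)) stop_screenome("prompt study_day must be >= 1")
  if (any(prompts$window_index < 1L | prompts$window_index > 6L)) {
    stop_screenome("window_index must lie in [1, 6]")
  }
  if (is.null(response_path)) {
    return(list(prompts = prompts, responses = empty_responses(registry)))
  }
  resp <- readr::read_csv(
    response_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(person_id = readr::col_character(),
                            completed_at = readr::col_character())
  )
  need <- c("person_id", "study_day", "window_index", "completed_at")
  miss <- setdiff(need, names(resp))
  if (length(miss)) stop_screenome("responses missing column(s): ", paste(miss, collapse = ", "))
  ri <- parse_iso_ts(resp$completed_at)
  out <- tibble::tibble(
    person_id = as.character(resp$person_id),
    study_day = as.integer(resp$study_day),
    window_index = as.integer(resp$window_index),
    completed_at = ri$ts
  )
  for (it in registry$item) {
    out[[it]] <- if (it %in% names(resp)) as.numeric(resp[[it]]) else NA_real_
  }
  validate_ema_items(out, registry)

  key <- function(d) paste(d$person_id, d$study_day, d$window_index, sep = "/")
  pk <- key(prompts)
  rk <- key(out)
  orphan <- !(rk %in% pk)
  if (any(orphan)) {
    stop_screenome("response(s) with no matching prompt: ",
                   paste(utils::head(unique(rk[orphan]), 5), collapse = ", "))
  }
  expires <- prompts$expires_at[match(rk, pk)]
  late <- out$completed_at > expires
  if (any(late)) {
    warning(sum(late), " response(s) completed after the 30-minute expiry were excluded",
            call. = FALSE)
    out <- out[!late, ]
  }
  list(prompts = prompts, responses = out)
}

empty_responses <- function(registry = ema_item_registry()) {
  out <- tibble::tibble(
    person_id = character(), study_day = integer(), window_index = integer(),
    completed_at = as.POSIXct(character(), tz = "UTC")
  )
  for (it in registry$item) out[[it]] <- numeric(0)
  out
}

validate_ema_items <- function(responses, registry) {
  for (i in seq_len(nrow(registry))) {
    it <- registry$item[i]
    v <- responses[[it]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    ok <- switch(registry$type[i],
      likert = all(v %in% 1:5),
      binary = all(v %in% 0:1),
      pain = all(v >= 0 & v <= 100),
      TRUE
    )
    if (!ok) {
      stop_screenome("item '", it, "' has values outside its ", registry$type[i], " range")
    }
  }
  invisible(responses)
}

#' Write EMA prompt and response tables
#'
#' @param ema `list(prompts, responses)` as returned by [read_ema()] or
#'   [generate_ema()].
#' @param prompt_path,response_path Output CSV paths.
#' @return Invisibly, the paths.
#' @export
write_ema <- function(ema, prompt_path, response_path) {
  p <- ema$prompts
  readr::write_csv(tibble::tibble(
    person_id = p$person_id, study_day = p$study_day,
    window_index = p$window_index,
    issued_at = format_iso_ts(p$issued_at, p$utc_offset)
  ), prompt_path, progress = FALSE)
  r <- ema$responses
  off <- p$utc_offset[match(r$person_id, p$person_id)]
  out <- tibble::tibble(
    person_id = r$person_id, study_day = r$study_day,
    window_index = r$window_index,
    completed_at = format_iso_ts(r$completed_at, off)
  )
  items <- setdiff(names(r), names(out))
  for (it in items) out[[it]] <- r[[it]]
  readr::write_csv(out, response_path, progress = FALSE)
  invisible(c(prompt_path, response_path))
}

#' Load a phrase lexicon from a text file
#'
#' One phrase per line; blank lines and lines starting with `#` are ignored.
#' Phrases are normalized with the supplied normalizer (the same one applied
#' to screen text) and deduplicated.
#'
#' @param path Lexicon file path.
#' @param name Lexicon name; defaults to the file name without extension.
#' @param normalizer Normalizer shared with the screen text.
#' @return A [lexicon()].
#' @export
load_lexicon <- function(path, name = NULL,
                         normalizer = default_normalizer()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop_screenome("lexicon file '", path, "' contains no phrases")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lexicon(name, lines, normalizer = normalizer)
}

#' Write a lexicon back to a text file (normalized form)
#'
#' @param x A `lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(x, path) {
  stopifnot(inherits(x, "lexicon"))
  writeLines(lexicon_phrases(x), path, useBytes = TRUE)
  invisible(path)
}

#' Bundled example lexicons
#'
#' Small plain-text dictionaries shipped with the package: suicide-specific
#' phrases, theoretically linked risk-factor words, a synthetic stand-in for
#' an externally developed crisis-chat dictionary (the published original is
#' not redistributable; placeholder phrases are marked in the file), and a
#' substances list.
#'
#' @param normalizer Normalizer shared with the screen text.
#' @return Named list of `lexicon` objects.
#' @export
bundled_lexicons <- function(normalizer = default_normalizer()) {
  dir <- system.file("extdata", "lexicons", package = "screenome")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  lex <- lapply(files, load_lexicon, normalizer = normalizer)
  names(lex) <- vapply(lex, function(l) l$name, character(1))
  lex
}
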