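# Shared fixtures and independent oracles, built in code at test time.

# Build a screen_events tibble from a compact spec: one element per screen,
# each a list(ts = "HH:MM:SS" (local), day = study day, blocks = list of
# c(text, conf)), all for one person with a fixed -05:00 offset.
fx_events <- function(screens, person = "P1",
                      start = as.Date("2023-03-06"), offset = -5 * 3600) {
  rows <- list()
  for (i in seq_along(screens)) {
    s <- screens[[i]]
    day <- s$day %||% 1L
    wall <- as.POSIXct(paste(start + (day - 1), s$ts %||% "12:00:00"), tz = "UTC")
    blocks <- s$blocks %||% list(list("hello world", 0.95))
    for (b in seq_along(blocks)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = person, screen_id = i, ts = wall - offset,
        utc_offset = offset, block = b,
        text = blocks[[b]][[1]], conf = as.numeric(blocks[[b]][[2]]),
        social_prob = as.numeric(s$social %||% NA_real_)
      )
    }
    if (length(blocks) == 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = person, screen_id = i, ts = wall - offset,
        utc_offset = offset, block = NA_integer_,
        text = NA_character_, conf = NA_real_,
        social_prob = as.numeric(s$social %||% NA_real_)
      )
    }
  }
  validate_screen_events(dplyr::bind_rows(rows))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

fx_timeline <- function(n_days = 35, hosp = 29:32, person = "P1",
                        start = as.Date("2023-03-06")) {
  study_timeline(person, start, n_days, hosp)
}

# Normalized-screens tibble straight from token vectors (one per screen),
# all on one day unless `days` given.
fx_screens <- function(token_list, days = 1L, hours = 12L, person = "P1",
                       start = as.Date("2023-03-06"), offset = -5 * 3600) {
  n <- length(token_list)
  days <- rep_len(days, n)
  hours <- rep_len(hours, n)
  wall <- as.POSIXct(paste0(start + (days - 1), " ",
                            sprintf("%02d", hours), ":00:00"), tz = "UTC") +
    seq_len(n) * 5
  out <- tibble::tibble(
    person_id = person, screen_id = seq_len(n), ts = wall - offset,
    utc_offset = offset, social_prob = NA_real_, tokens = token_list
  )
  class(out) <- unique(c("normalized_screens", class(out)))
  out
}

# Small synthetic configs for stochastic tests (problem size only; rates,
# multipliers and compliance parameters stay at the study-condition defaults).
fx_small_config <- function(...) {
  synth_config(usage = list(sessions_per_day = 2, session_mean_min = 5), ...)
}

# Prompt/response tables with a given completion pattern: `per_day` gives the
# number of completed prompts on each study day.
fx_ema_tables <- function(per_day, n_days = 28, person = "P") {
  start <- as.Date("2023-03-06")
  prompts <- tidyr::expand_grid(study_day = seq_len(n_days), window_index = 1:6)
  prompts$person_id <- person
  prompts$issued_at <- as.POSIXct(paste(start + prompts$study_day - 1, "09:00:00"),
                                  tz = "UTC") + (prompts$window_index - 1) * 7200
  prompts$utc_offset <- 0L
  prompts$expires_at <- prompts$issued_at + 1800
  resp <- dplyr::bind_rows(
    list(tibble::tibble(person_id = character(), study_day = integer(),
                        window_index = integer())),
    lapply(seq_along(per_day), function(d) {
      k <- per_day[d]
      if (k == 0) return(NULL)
      tibble::tibble(person_id = person, study_day = d, window_index = seq_len(k))
    })
  )
  resp$completed_at <- prompts$issued_at[
    match(paste(resp$study_day, resp$window_index),
          paste(prompts$study_day, prompts$window_index))
  ] + 600
  list(prompts = prompts, responses = resp)
}

# Events at a 5-second cadence: `spec` maps (day, hour) -> number of slots.
fx_slots <- function(spec, person = "P1", start = as.Date("2023-03-06"),
                     offset = -5 * 3600) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    wall <- as.POSIXct(paste(start + spec$day[i] - 1,
                             sprintf("%02d:00:00", spec$hour[i])), tz = "UTC") +
      seq_len(n) * 5 - 5
    tibble::tibble(person_id = person, screen_id = NA_integer_, ts = wall - offset,
                   utc_offset = offset, block = 1L, text = "x", conf = 0.9,
                   social_prob = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  out$screen_id <- seq_len(nrow(out))
  validate_screen_events(out)
}

# ---- independent oracles ----------------------------------------------------

# Brute-force greedy longest-first matcher: naive recursive scan trying every
# entry at every position, longest first (alphabetical within a length).
oracle_match <- function(tokens, phrases) {
  toks <- lapply(phrases, function(p) strsplit(p, " ", fixed = TRUE)[[1]])
  ord <- order(-lengths(toks), phrases)
  toks <- toks[ord]
  phrases <- phrases[ord]
  counts <- stats::setNames(integer(length(phrases)), phrases)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    advanced <- FALSE
    for (j in seq_along(toks)) {
      L <- length(toks[[j]])
      if (i + L - 1L <= n && identical(tokens[i:(i + L - 1L)], toks[[j]])) {
        counts[j] <- counts[j] + 1L
        i <- i + L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  counts[counts > 0L]
}

# Linear-interpolation percentile of order statistics, written from the
# definition: h = (n-1)p + 1, interpolate between x_(floor h) and x_(floor h + 1).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Tricube-weighted least squares at a single target, solved with explicit
# (uncentered) normal equations.
oracle_loess_point <- function(x0, xs, ys, span) {
  n <- length(xs)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  d <- abs(xs - x0)
  dq <- sort(d)[q]
  w <- if (dq == 0) as.numeric(d == 0) else (1 - pmin(d / dq, 1)^3)^3
  keep <- w > 0
  X <- cbind(1, xs[keep])
  W <- diag(w[keep], nrow = sum(keep))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% ys[keep])
  as.numeric(beta[1] + beta[2] * x0)
}
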