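#' Configuration for a synthetic study person
#'
#' Parameterizes a complete simulated participant: 35 days of 5-second
#' screenshot capture during usage sessions, 28 days of signal-contingent EMA
#' (6 prompts/day in 2-hour windows across a 12-hour block), a crisis day
#' with hospitalization starting on it, lexical injection effects (elevated
#' rates of risk words on the day before the crisis), a compliance curve that
#' declines to a floor approaching the crisis, and item-level generative
#' parameters (a latent severity trajectory for ordinal items, normal pain
#' scores, binary endorsement probabilities).
#'
#' Defaults emulate the person-A-like study conditions: 5.9 hours/day of
#' collection (12 sessions of mean 30 minutes), phone use increasing across
#' the day, compliance around 60% declining to 10% from three days before the
#' crisis, crisis on day 29 with hospitalization days 29-32, a five-fold
#' injection of each lexicon on crisis-eve (day 28), and daily pain reports
#' with mean 74.4 and SD 16.2.
#'
#' @param n_days Screenshot-collection days (default 35).
#' @param ema_days EMA days (default 28); a full protocol yields
#'   `6 * ema_days` prompts.
#' @param crisis_day Study day of the crisis / first hospitalization day, or
#'   `NULL` for a crisis-free person.
#' @param hospitalization_len Length of the hospitalization in days.
#' @param person_id,study_start,utc_offset Identity and local-time anchoring.
#' @param usage List: `sessions_per_day`, `session_mean_min`, `hour_weights`
#'   (length-24 nonnegative intensity), `crisis_multiplier` applied to the
#'   session rate on crisis-eve.
#' @param text List: `vocab_size`, `tokens_per_screen_mean`, `base_rate`
#'   (expected phrase occurrences per screen per lexicon), `injection_day`
#'   (default crisis-eve), `injection_multiplier`, `injection_lexicons`
#'   (names; default all), `conf_below_share` (share of blocks drawn below
#'   the 0.70 OCR confidence threshold), `app_rate` (chance a screen shows an
#'   app keyword), `lexicons` (named list of [lexicon()]s),
#'   `include_ema_screens` (render survey screens at prompt times).
#' @param compliance List: `p0` baseline answer probability, `floor`,
#'   `decline_days` (ramp reaches the floor this many days before the
#'   crisis), `ramp` (logistic scale in days).
#' @param ema List: `block_start_hour`, `pain_mean`, `pain_sd`,
#'   `latent_base`, `latent_peak`, `rise_days`, `latent_sd`, `binary_p`
#'   (named base endorsement probabilities), `nightmare_peak`.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_days = 35, ema_days = 28, crisis_day = 29,
                         hospitalization_len = 4,
                         person_id = "synthetic-01",
                         study_start = as.Date("2023-03-06"),
                         utc_offset = "-05:00",
                         usage = list(), text = list(), compliance = list(),
                         ema = list()) {
  usage <- utils::modifyList(list(
    sessions_per_day = 12,
    session_mean_min = 30,
    hour_weights = default_hour_weights(),
    crisis_multiplier = 1.5
  ), usage)
  text <- utils::modifyList(list(
    vocab_size = 400,
    tokens_per_screen_mean = 12,
    base_rate = 0.05,
    injection_day = if (is.null(crisis_day)) NULL else crisis_day - 1L,
    injection_multiplier = 5,
    injection_lexicons = NULL,
    conf_below_share = 0.1,
    app_rate = 0.02,
    lexicons = NULL,
    include_ema_screens = TRUE
  ), text, keep.null = TRUE)
  if (is.null(text$lexicons)) text$lexicons <- default_synth_lexicons()
  compliance <- utils::modifyList(list(
    p0 = 0.6, floor = 0.1, decline_days = 3, ramp = 0.25
  ), compliance)
  ema <- utils::modifyList(list(
    block_start_hour = 9,
    pain_mean = 74.4, pain_sd = 16.2,
    latent_base = 0.4, latent_peak = 2.4, rise_days = 7, latent_sd = 0.5,
    binary_p = c(conflict = 0.25, behavior_nssi = 0.05, behavior_alcohol = 0.1),
    nightmare_base = 0.3, nightmare_peak = 0.7
  ), ema)

  cfg <- list(
    n_days = as.integer(n_days), ema_days = as.integer(ema_days),
    crisis_day = if (is.null(crisis_day)) NULL else as.integer(crisis_day),
    hospitalization_len = as.integer(hospitalization_len),
    person_id = as.character(person_id), study_start = as.Date(study_start),
    utc_offset = parse_utc_offset(utc_offset),
    usage = usage, text = text, compliance = compliance, ema = ema
  )
  stopifnot(cfg$n_days >= 1L, cfg$ema_days >= 1L, cfg$ema_days <= cfg$n_days)
  if (!is.null(cfg$crisis_day) &&
      (cfg$crisis_day < 1L || cfg$crisis_day > cfg$n_days)) {
    stop_screenome("crisis_day must lie in [1, n_days]")
  }
  probs <- c(compliance$p0, compliance$floor, text$conf_below_share, text$app_rate)
  if (any(probs < 0 | probs > 1)) stop_screenome("probabilities must lie in [0, 1]")
  if (text$base_rate < 0 || text$injection_multiplier < 0) {
    stop_screenome("rates and multipliers must be nonnegative")
  }
  if (length(usage$hour_weights) != 24L || any(usage$hour_weights < 0)) {
    stop_screenome("hour_weights must be 24 nonnegative values")
  }
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_hour_weights <- function() {
  h <- 0:23
  w <- 0.15 + ifelse(h >= 7, (h - 6) / 17, 0)
  w / sum(w)
}

# Small default lexicons so generated text exercises multiword matching.
default_synth_lexicons <- function(normalizer = default_normalizer()) {
  list(
    pain = lexicon("pain", c("pain", "hurt", "ache"), normalizer),
    risk = lexicon("risk", c("alone", "trapped", "crying", "guilty", "numb"),
                   normalizer),
    crisis = lexicon("crisis",
                     c("end it all", "hate my life", "hopeless",
                       "i just want this all to end"),
                     normalizer)
  )
}

#' Study timeline implied by a synthetic configuration
#'
#' @param config A [synth_config()].
#' @return A [study_timeline()]; hospitalization days start on the crisis
#'   day when one is set.
#' @export
synth_timeline <- function(config) {
  hosp <- if (is.null(config$crisis_day)) {
    integer()
  } else {
    config$crisis_day:min(config$crisis_day + config$hospitalization_len - 1L,
                          config$n_days)
  }
  study_timeline(config$person_id, config$study_start, config$n_days, hosp)
}

# Session-rate multiplier for a given day (phone use rises on crisis-eve).
usage_day_multiplier <- function(config, day) {
  if (is.null(config$crisis_day)) return(rep(1, length(day)))
  ifelse(day == config$crisis_day - 1L, config$usage$crisis_multiplier, 1)
}

#' Generate usage sessions and capture slots
#'
#' Draws usage sessions per day (Poisson count, start hour from the
#' hour-of-day intensity weights, duration from a gamma distribution) and
#' emits one capture per 5-second slot within each session. Overlapping
#' sessions collapse onto the slot grid, so the 720-captures-per-hour
#' capacity holds by construction.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble `person_id`, `ts` (POSIXct UTC), `utc_offset` with one
#'   row per captured screen, in time order.
#' @export
generate_usage <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    u <- config$usage
    day0 <- as.POSIXct(paste(config$study_start, "00:00:00"), tz = "UTC")
    slots <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      lambda <- u$sessions_per_day * usage_day_multiplier(config, d)
      ns <- stats::rpois(1, lambda)
      if (ns == 0L) {
        slots[[d]] <- numeric(0)
        next
      }
      start_hour <- sample(0:23, ns, replace = TRUE, prob = u$hour_weights)
      start_sec <- (d - 1) * 86400 + start_hour * 3600 + stats::runif(ns, 0, 3600)
      dur <- stats::rgamma(ns, shape = 2, scale = u$session_mean_min * 60 / 2)
      day_slots <- unlist(lapply(seq_len(ns), function(i) {
        seq(from = floor(start_sec[i] / 5) * 5,
            to = min(floor((start_sec[i] + dur[i]) / 5) * 5, d * 86400 - 5),
            by = 5)
      }))
      slots[[d]] <- sort(unique(day_slots))
    }
    sec <- unlist(slots)
    tibble::tibble(
      person_id = config$person_id,
      ts = day0 + sec - config$utc_offset,
      utc_offset = config$utc_offset
    )
  })
}

# Deterministic pseudo-word vocabulary, excluding all lexicon tokens.
synth_vocab <- function(config) {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  two <- as.vector(outer(syll, syll, paste0))
  lex_tokens <- unique(unlist(lapply(config$text$lexicons, function(l) l$entries)))
  words <- setdiff(two, lex_tokens)
  # guard against suffix rules folding distinct pseudo-words onto lexicon tokens
  words <- words[!(lemmatize_tokens(words) %in% lex_tokens)]
  utils::head(words, config$text$vocab_size)
}

# Per-day injection multiplier for one lexicon.
injection_multiplier <- function(config, lex_name, day) {
  t <- config$text
  m <- rep(1, length(day))
  applies <- is.null(t$injection_lexicons) || lex_name %in% t$injection_lexicons
  if (!is.null(t$injection_day) && applies) {
    m[day == t$injection_day] <- t$injection_multiplier
  }
  m
}

#' Populate captured screens with text blocks
#'
#' Gives each capture slot a background token stream drawn from a
#' rank-weighted pseudo-word vocabulary, injects lexicon phrases as
#' contiguous token runs at rate `base_rate * multiplier(day)` per screen,
#' occasionally inserts app-identification keywords, splits tokens into one
#' or two OCR blocks, and draws block confidences from a mixture in which a
#' configurable share falls below the 0.70 threshold. Each screen also
#' receives a synthetic social-content probability.
#'
#' @param usage Output of [generate_usage()].
#' @param config A [synth_config()].
#' @param seed Integer seed, or `NULL`.
#' @return A `screen_events` tibble.
#' @export
generate_text <- function(usage, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(usage)
  if (n == 0L) return(empty_screen_events())
  with_seed(seed, {
    t <- config$text
    timeline <- synth_timeline(config)
    day <- study_day_of(usage$ts, usage$utc_offset, timeline)
    vocab <- synth_vocab(config)
    vprob <- 1 / seq_along(vocab)

    n_tok <- 1L + stats::rpois(n, max(t$tokens_per_screen_mean - 1, 0))
    background <- sample(vocab, sum(n_tok), replace = TRUE, prob = vprob)
    toks <- unname(split(background, rep.int(seq_len(n), n_tok)))

    for (lex_name in names(t$lexicons)) {
      lex <- t$lexicons[[lex_name]]
      lam <- t$base_rate * injection_multiplier(config, lex_name, day)
      k <- stats::rpois(n, lam)
      for (i in which(k > 0L)) {
        cur <- toks[[i]]
        for (e in sample(lex$entries, k[i], replace = TRUE)) {
          at <- sample.int(length(cur) + 1L, 1L)
          cur <- append(cur, e, after = at - 1L)
        }
        toks[[i]] <- cur
      }
    }
    app_lex <- default_app_lexicons()
    app_hit <- stats::runif(n) < t$app_rate
    for (i in which(app_hit)) {
      lex <- app_lex[[sample.int(length(app_lex), 1L)]]
      e <- lex$entries[[sample.int(length(lex$entries), 1L)]]
      at <- sample.int(length(toks[[i]]) + 1L, 1L)
      toks[[i]] <- append(toks[[i]], e, after = at - 1L)
    }

    len <- lengths(toks)
    two_blocks <- stats::runif(n) < 0.25 & len >= 2L
    social_prob <- round(stats::rbeta(n, 1.2, 6), 4)
    text1 <- vapply(toks, paste, character(1), collapse = " ")
    text2 <- rep(NA_character_, n)
    for (i in which(two_blocks)) {
      cut <- sample.int(len[i] - 1L, 1L)
      text1[i] <- paste(toks[[i]][seq_len(cut)], collapse = " ")
      text2[i] <- paste(toks[[i]][-seq_len(cut)], collapse = " ")
    }
    draw_conf <- function(k) {
      below <- stats::runif(k) < t$conf_below_share
      # keep the below-threshold component strictly under 0.70 after rounding
      round(ifelse(below, stats::runif(k, 0.30, 0.695),
                   stats::runif(k, 0.70, 1.00)), 4)
    }
    idx2 <- which(two_blocks)
    df <- tibble::tibble(
      person_id = rep(usage$person_id, 2L)[c(seq_len(n), n + idx2)],
      screen_id = c(seq_len(n), idx2),
      ts = usage$ts[c(seq_len(n), idx2)],
      utc_offset = usage$utc_offset[c(seq_len(n), idx2)],
      block = c(rep(1L, n), rep(2L, length(idx2))),
      text = c(text1, text2[idx2]),
      conf = c(draw_conf(n), draw_conf(length(idx2))),
      social_prob = social_prob[c(seq_len(n), idx2)]
    )
    df <- dplyr::arrange(df, .data$person_id, .data$ts, .data$screen_id, .data$block)
    validate_screen_events(df)
  })
}

# Per-day prompt-answer probability: logistic ramp from p0 down to the floor,
# reaching the floor `decline_days` before the crisis.
compliance_prob <- function(config, day) {
  cp <- config$compliance
  if (is.null(config$crisis_day)) return(rep(cp$p0, length(day)))
  onset <- config$crisis_day - cp$decline_days
  cp$floor + (cp$p0 - cp$floor) * stats::plogis(-(day - onset + 0.5) / cp$ramp)
}

# Piecewise-linear latent severity rising to the crisis day.
latent_severity <- function(config, day) {
  e <- config$ema
  if (is.null(config$crisis_day)) return(rep(e$latent_base, length(day)))
  frac <- clamp((day - (config$crisis_day - e$rise_days)) / e$rise_days, 0, 1)
  e$latent_base + (e$latent_peak - e$latent_base) * frac
}

likert_from_latent <- function(latent) {
  clamp(1L + findInterval(latent, c(0.5, 1.25, 2.0, 2.75)), 1, 5)
}

#' Generate the EMA prompt schedule and responses
#'
#' Emits exactly `6 * ema_days` prompts, each issued uniformly at random
#' within its 2-hour window of the person's 12-hour block. Each prompt is
#' answered with a day-specific probability that declines along a logistic
#' ramp to a floor approaching the crisis day; answered prompts are completed
#' uniformly within the 30-minute validity window and receive item values
#' from a latent severity trajectory (ordinal items via fixed cut-points),
#' binary endorsement draws, daily sleep items at the morning prompt, and one
#' daily pain report.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed, or `NULL`.
#' @param registry Item registry.
#' @return `list(prompts, responses)` matching [read_ema()]'s contract.
#' @export
generate_ema <- function(config, seed = NULL, registry = ema_item_registry()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    e <- config$ema
    day0 <- as.POSIXct(paste(config$study_start, "00:00:00"), tz = "UTC")
    grid <- tidyr::expand_grid(study_day = seq_len(config$ema_days),
                               window_index = 1:6)
    n <- nrow(grid)
    win_start <- (grid$study_day - 1) * 86400 +
      (e$block_start_hour + (grid$window_index - 1) * 2) * 3600
    issued <- day0 + win_start + stats::runif(n, 0, 2 * 3600) - config$utc_offset
    prompts <- tibble::tibble(
      person_id = config$person_id,
      study_day = grid$study_day,
      window_index = grid$window_index,
      issued_at = issued,
      utc_offset = config$utc_offset,
      reminder_at = issued + 15 * 60,
      expires_at = issued + 30 * 60
    )
    p_answer <- compliance_prob(config, prompts$study_day)
    answered <- stats::runif(n) < p_answer
    resp <- prompts[answered, c("person_id", "study_day", "window_index")]
    resp$completed_at <- prompts$issued_at[answered] +
      stats::runif(sum(answered), 0, 30 * 60)

    m <- nrow(resp)
    latent_day <- latent_severity(config, resp$study_day)
    for (it in registry$item[registry$composite %in% c("ideation", "planning", "desire")]) {
      resp[[it]] <- likert_from_latent(latent_day + stats::rnorm(m, 0, e$latent_sd))
    }
    for (it in c("burdensomeness", "belongingness", "affect_negative")) {
      resp[[it]] <- likert_from_latent(0.8 + 0.3 * latent_day + stats::rnorm(m, 0, 0.6))
    }
    resp$affect_positive <- likert_from_latent(2.0 - 0.3 * latent_day + stats::rnorm(m, 0, 0.6))
    for (it in c("urge_nssi", "urge_alcohol", "urge_drug")) {
      resp[[it]] <- likert_from_latent(0.6 + 0.2 * latent_day + stats::rnorm(m, 0, 0.7))
    }
    for (it in names(e$binary_p)) {
      resp[[it]] <- stats::rbinom(m, 1, e$binary_p[[it]])
    }
    # daily items: sleep questions at the morning prompt, pain once per day
    morning <- resp$window_index == 1L
    resp$nightmares <- NA_real_
    resp$sleep_quality <- NA_real_
    if (any(morning)) {
      p_night <- e$nightmare_base +
        (e$nightmare_peak - e$nightmare_base) *
          clamp(latent_severity(config, resp$study_day[morning]) /
                  max(e$latent_peak, 1e-9), 0, 1)
      resp$nightmares[morning] <- stats::rbinom(sum(morning), 1, clamp(p_night, 0, 1))
      resp$sleep_quality[morning] <- likert_from_latent(
        2.2 - 0.3 * latent_severity(config, resp$study_day[morning]) +
          stats::rnorm(sum(morning), 0, 0.6)
      )
    }
    resp$pain <- NA_real_
    first_of_day <- !duplicated(resp$study_day)
    resp$pain[first_of_day] <- clamp(
      round(stats::rnorm(sum(first_of_day), e$pain_mean, e$pain_sd)), 0, 100
    )
    for (it in setdiff(registry$item, names(resp))) resp[[it]] <- NA_real_
    list(prompts = prompts, responses = resp)
  })
}

#' Generate a complete synthetic person
#'
#' Bundles usage, screen text, EMA prompts/responses, and the study timeline
#' for one simulated participant. Identical `(config, seed)` pairs give
#' byte-identical datasets; ground-truth parameters are returned alongside
#' for parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return `list(events, prompts, responses, timeline, truth)` where `truth`
#'   records the injected signal (injection day and multiplier, per-day
#'   compliance probabilities, pain mean/SD, hour weights).
#' @export
generate_person <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    usage <- generate_usage(config, seed = NULL)
    events <- generate_text(usage, config, seed = NULL)
    ema <- generate_ema(config, seed = NULL)
    if (config$text$include_ema_screens) {
      events <- add_ema_screens(events, ema$prompts, config)
    }
    list(
      events = events,
      prompts = ema$prompts,
      responses = ema$responses,
      timeline = synth_timeline(config),
      truth = list(
        injection_day = config$text$injection_day,
        injection_multiplier = config$text$injection_multiplier,
        base_rate = config$text$base_rate,
        compliance_prob = compliance_prob(config, seq_len(config$ema_days)),
        pain_mean = config$ema$pain_mean,
        pain_sd = config$ema$pain_sd,
        hour_weights = config$usage$hour_weights
      )
    )
  })
}

# Render survey screens at prompt times (three 5-second captures showing item
# wordings) so the EMA-screen removal step has realistic work to do.
add_ema_screens <- function(events, prompts, config) {
  wordings <- c(
    "In this moment: I want to die",
    "In this moment: Life is not worth living for me",
    "Since the last prompt: Considered a specific suicide method"
  )
  n <- nrow(prompts)
  if (n == 0L) return(events)
  # snap survey screens to the 5-second capture grid and keep one capture per
  # slot (a slot already occupied by a usage capture wins)
  base <- floor(as.numeric(prompts$issued_at) / 5) * 5
  ts <- as.POSIXct(rep(base, each = 3L) + c(0, 5, 10),
                   origin = "1970-01-01", tz = "UTC")
  new <- tibble::tibble(
    person_id = rep(prompts$person_id, each = 3L),
    screen_id = NA_integer_,
    ts = ts,
    utc_offset = rep(prompts$utc_offset, each = 3L),
    block = 1L,
    text = rep(wordings, times = n),
    conf = 0.97,
    social_prob = 0
  )
  occupied <- unique(paste(events$person_id, as.numeric(events$ts)))
  new <- new[!(paste(new$person_id, as.numeric(new$ts)) %in% occupied), ]
  new <- new[!duplicated(paste(new$person_id, as.numeric(new$ts))), ]
  out <- dplyr::bind_rows(tibble::as_tibble(events), new)
  out <- dplyr::arrange(out, .data$person_id, .data$ts, .data$block)
  key <- paste(out$person_id, as.numeric(out$ts))
  out$screen_id <- match(key, unique(key))
  validate_screen_events(out)
}
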