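#' EMA compliance summary
#'
#' Compliance is the number of prompts completed within their 30-minute
#' validity window versus the number received. Three views are reported per
#' person: overall percentage (completed / received), the percentage counting
#' only response days (calendar days with at least one completed prompt,
#' denominator 6 per day), and the mean completed prompts per response day.
#' Percentages are rounded half-away-from-zero to one decimal; raw values are
#' kept in `*_raw` columns.
#'
#' @param prompts,responses Tibbles as returned by [read_ema()] or
#'   [generate_ema()].
#' @return One row per person: `person_id`, `prompts_received`,
#'   `prompts_completed`, `response_days`, `overall_pct`, `response_day_pct`,
#'   `mean_per_response_day`, plus unrounded `overall_pct_raw`,
#'   `response_day_pct_raw`. Day-level metrics are `NA` when there are no
#'   response days.
#' @examples
#' # person A's printed counts: 101 completed of 168 over 25 response days
#' @export
compliance <- function(prompts, responses) {
  if (nrow(prompts) == 0L) stop_screenome("no prompts received")
  if (nrow(responses) > 0L && "completed_at" %in% names(responses) &&
      "expires_at" %in% names(prompts)) {
    key <- function(d) paste(d$person_id, d$study_day, d$window_index, sep = "/")
    expires <- prompts$expires_at[match(key(responses), key(prompts))]
    ok <- is.na(expires) | responses$completed_at <= expires
    responses <- responses[ok, ]
  }
  received <- table(prompts$person_id)
  people <- names(received)
  out <- lapply(people, function(p) {
    r <- as.integer(received[[p]])
    resp <- responses[responses$person_id == p, ]
    completed <- nrow(resp)
    if (completed > r) {
      stop_screenome("person ", p, ": more completed responses (", completed,
                     ") than prompts received (", r, ")")
    }
    rd <- length(unique(resp$study_day))
    overall <- 100 * completed / r
    rd_pct <- if (rd > 0L) 100 * completed / (6L * rd) else NA_real_
    tibble::tibble(
      person_id = p,
      prompts_received = r,
      prompts_completed = completed,
      response_days = rd,
      overall_pct = round_half_up(overall, 1),
      response_day_pct = round_half_up(rd_pct, 1),
      mean_per_response_day = if (rd > 0L) completed / rd else NA_real_,
      overall_pct_raw = overall,
      response_day_pct_raw = rd_pct
    )
  })
  dplyr::bind_rows(out)
}

#' Composite momentary suicide scores
#'
#' Sums the registry-declared constituent items of each completed response
#' into three composites: suicidal ideation (4 items, range 4-20), suicidal
#' planning (3 items, range 3-15), and suicidal desire (2 items, range 2-10).
#' A composite is missing for a response whenever any of its constituent
#' items is missing (no prorating).
#'
#' @param responses Response tibble with one column per item.
#' @param registry Item registry, see [ema_item_registry()].
#' @return `responses`' key columns plus `ideation`, `planning`, `desire`.
#' @export
composite_scores <- function(responses, registry = ema_item_registry()) {
  comps <- unique(registry$composite[!is.na(registry$composite)])
  out <- responses[, intersect(c("person_id", "study_day", "window_index", "completed_at"),
                               names(responses))]
  for (comp in comps) {
    items <- registry$item[!is.na(registry$composite) & registry$composite == comp]
    missing_cols <- setdiff(items, names(responses))
    if (length(missing_cols) > 0L) {
      stop_screenome("registry item(s) not present in responses: ",
                     paste(missing_cols, collapse = ", "))
    }
    m <- as.matrix(responses[, items])
    out[[comp]] <- ifelse(rowSums(is.na(m)) > 0L, NA_real_, rowSums(m))
  }
  out
}

#' Person-specific high-score flags
#'
#' Flags observations at or above the 90th percentile of the person's own
#' empirical distribution of the variable. The threshold uses linear
#' interpolation between order statistics (`stats::quantile()` type 7); the
#' flag rule is `value >= threshold`.
#'
#' @param values Numeric vector (>= 2 nonmissing values required).
#' @param prob Percentile (default 0.9).
#' @return A tibble `value`, `flag`, with the threshold in attribute
#'   `threshold`.
#' @examples
#' f <- high_flags(1:10)
#' attr(f, "threshold") # 9.1
#' @export
high_flags <- function(values, prob = 0.9) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    stop_screenome("high_flags needs at least 2 nonmissing values")
  }
  thr <- unname(stats::quantile(v, probs = prob, type = 7, names = FALSE))
  out <- tibble::tibble(value = values, flag = !is.na(values) & values >= thr)
  attr(out, "threshold") <- thr
  out
}

#' Daily series for a binary EMA item
#'
#' Day value is 1 when any completed response that day endorses the item, 0
#' when at least one response was completed and none endorses, and missing
#' when the day has no completed responses.
#'
#' @param responses Response tibble.
#' @param item Name of a binary item.
#' @param registry Item registry (the item must be declared binary).
#' @param days Study days to report; defaults to the days observed in
#'   `responses`.
#' @return Tibble `study_day`, `value` (0/1/NA).
#' @export
daily_binary_series <- function(responses, item, registry = ema_item_registry(),
                                days = NULL) {
  reg_row <- registry[registry$item == item, ]
  if (nrow(reg_row) == 0L || reg_row$type != "binary") {
    stop_screenome("item '", item, "' is not registered as binary")
  }
  if (is.null(days)) days <- sort(unique(responses$study_day))
  vals <- vapply(days, function(d) {
    v <- responses[[item]][responses$study_day == d]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    as.numeric(any(v == 1))
  }, numeric(1))
  tibble::tibble(study_day = as.integer(days), value = vals)
}

#' Summarize a numeric EMA item
#'
#' @param responses Response tibble.
#' @param item Numeric item name.
#' @return Tibble `n`, `mean`, `sd` (sample SD, n-1 denominator; `NA` for a
#'   single observation). Errors when there are no nonmissing values.
#' @export
summarize_item <- function(responses, item) {
  if (!item %in% names(responses)) {
    stop_screenome("item '", item, "' not present in responses")
  }
  v <- responses[[item]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop_screenome("item '", item, "' has no nonmissing values")
  tibble::tibble(
    n = length(v),
    mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else NA_real_
  )
}
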