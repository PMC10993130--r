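#' Align a daily series to the first hospitalization day
#'
#' Re-indexes a per-day series so that relative day 0 is the first day of the
#' person's hospitalization (negative values precede it). Values are not
#' altered and order is preserved; the original `study_day` column is kept so
#' the alignment is invertible.
#'
#' @param series A tibble with a `study_day` column.
#' @param timeline A [study_timeline()] with at least one hospitalization
#'   day.
#' @return `series` with an added `relative_day` column.
#' @export
align_to_event <- function(series, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  if (length(timeline$hospitalization_days) == 0L) {
    stop_screenome("timeline has no hospitalization days to align to")
  }
  if (!"study_day" %in% names(series)) {
    stop_screenome("series must have a `study_day` column")
  }
  event_day <- timeline$hospitalization_days[1]
  dplyr::mutate(series, relative_day = .data$study_day - event_day,
                .after = "study_day")
}

#' Loess trend curve
#'
#' Locally weighted degree-1 regression with tricube weights, the smoother
#' drawn through daily risk series. At each target point the
#' `q = ceiling(span * n)` nearest neighbours receive weights
#' `(1 - (d/d_q)^3)^3` (zero beyond the q-th distance) and a weighted linear
#' fit is evaluated at the target. No robustness iterations. Constant and
#' exactly linear inputs are reproduced exactly, and the fit commutes with
#' affine transformations of `y`.
#'
#' @param x Numeric predictor (e.g. study day).
#' @param y Numeric response; missing values are ignored for fitting and
#'   returned as `NA`.
#' @param span Fraction of points in each local neighbourhood, in `(0, 1]`;
#'   default 0.75.
#' @return Fitted values aligned with `x` (`NA` where `y` is missing).
#' @export
loess_trend <- function(x, y, span = 0.75) {
  stopifnot(length(x) == length(y), is.numeric(span), length(span) == 1L)
  if (span <= 0 || span > 1) stop_screenome("span must lie in (0, 1]")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4L) {
    stop_screenome("loess_trend needs at least 4 nonmissing points")
  }
  xs <- x[ok]
  ys <- y[ok]
  fit <- vapply(x[ok], function(x0) loess_point(x0, xs, ys, span), numeric(1))
  out <- rep(NA_real_, length(x))
  out[ok] <- fit
  out
}

# Weighted local-linear fit at a single target point.
loess_point <- function(x0, xs, ys, span) {
  n <- length(xs)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  d <- abs(xs - x0)
  dq <- sort(d, partial = q)[q]
  if (dq == 0) {
    w <- as.numeric(d == 0)
  } else {
    u <- pmin(d / dq, 1)
    w <- (1 - u^3)^3
  }
  pos <- w > 0
  xw <- xs[pos] - x0
  yw <- ys[pos]
  wp <- w[pos]
  if (length(unique(xw)) < 2L) {
    return(sum(wp * yw) / sum(wp))
  }
  sw <- sum(wp)
  sx <- sum(wp * xw)
  sxx <- sum(wp * xw * xw)
  sy <- sum(wp * yw)
  sxy <- sum(wp * xw * yw)
  det <- sw * sxx - sx * sx
  if (det <= .Machine$double.eps * sw * sxx) {
    return(sum(wp * yw) / sum(wp))
  }
  # intercept of the centered fit is the value at x0
  (sxx * sy - sx * sxy) / det
}

#' Assemble the person-day risk profile table
#'
#' Full outer join of every daily series on (person, study day), one row per
#' study day in the window: phone-use counts and collection hours
#' (zero-filled on days without collection), one `<lexicon>_count` /
#' `<lexicon>_ratio` pair per score series, app-category counts, the social
#' content score, and the EMA-derived columns (per-day prompt counts, daily
#' means of the three suicide composites, and daily values of the registered
#' daily items). EMA columns stay missing on days without completed
#' responses, so compliance gaps remain visible in the profile.
#'
#' @param timeline A [study_timeline()].
#' @param usage Output of [daily_screen_counts()] (optional).
#' @param scores A list of ratio-scored series from [ratio_scores()]
#'   (optional).
#' @param app Output of [app_usage_daily()] (optional).
#' @param social Output of [aggregate_social()] (optional).
#' @param ema `list(prompts, responses)` (optional).
#' @param registry Item registry used for composites and daily items.
#' @return A tibble keyed by (`person_id`, `study_day`) with a
#'   `relative_day` column (`NA` when the timeline records no
#'   hospitalization).
#' @export
build_profile <- function(timeline, usage = NULL, scores = NULL, app = NULL,
                          social = NULL, ema = NULL,
                          registry = ema_item_registry()) {
  stopifnot(inherits(timeline, "study_timeline"))
  prof <- tibble::tibble(
    person_id = timeline$person_id,
    study_day = seq_len(timeline$n_days)
  )
  prof$relative_day <- if (length(timeline$hospitalization_days) > 0L) {
    prof$study_day - timeline$hospitalization_days[1]
  } else {
    NA_integer_
  }
  check_person <- function(d, what) {
    p <- unique(d$person_id)
    if (length(p) > 0L && !all(p == timeline$person_id)) {
      stop_screenome(what, " belongs to person(s) ", paste(p, collapse = ", "),
                     " but the timeline is for ", timeline$person_id)
    }
  }
  if (!is.null(usage)) {
    check_person(usage, "usage series")
    prof <- dplyr::left_join(prof, usage, by = c("person_id", "study_day"))
    prof$n_screens[is.na(prof$n_screens)] <- 0L
    prof$collection_hours <- collection_hours(prof$n_screens)
  }
  for (s in scores %||% list()) {
    check_person(s, "score series")
    nm <- unique(s$lexicon)
    stopifnot(length(nm) == 1L)
    wide <- tibble::tibble(
      person_id = s$person_id,
      study_day = s$study_day
    )
    wide[[paste0(nm, "_count")]] <- s$raw_count
    if ("ratio" %in% names(s)) wide[[paste0(nm, "_ratio")]] <- s$ratio
    prof <- dplyr::left_join(prof, wide, by = c("person_id", "study_day"))
    prof[[paste0(nm, "_count")]][is.na(prof[[paste0(nm, "_count")]])] <- 0
  }
  if (!is.null(app)) {
    check_person(app, "app-usage series")
    wide <- tidyr::pivot_wider(
      app, names_from = "category", values_from = "count",
      names_glue = "{tolower(category)}_count"
    )
    prof <- dplyr::left_join(prof, wide, by = c("person_id", "study_day"))
    for (nm in setdiff(names(wide), c("person_id", "study_day"))) {
      prof[[nm]][is.na(prof[[nm]])] <- 0L
    }
  }
  if (!is.null(social) && nrow(social) > 0L) {
    check_person(social, "social series")
    prof <- dplyr::left_join(prof, social, by = c("person_id", "study_day"))
    prof$social_score[is.na(prof$social_score)] <- 0
  }
  if (!is.null(ema)) {
    check_person(ema$prompts, "EMA prompts")
    pr <- dplyr::count(ema$prompts, .data$person_id, .data$study_day,
                       name = "prompts_received")
    prof <- dplyr::left_join(prof, pr, by = c("person_id", "study_day"))
    prof$prompts_received[is.na(prof$prompts_received)] <- 0L
    rs <- dplyr::count(ema$responses, .data$person_id, .data$study_day,
                       name = "prompts_completed")
    prof <- dplyr::left_join(prof, rs, by = c("person_id", "study_day"))
    prof$prompts_completed[prof$prompts_received > 0L &
                             is.na(prof$prompts_completed)] <- 0L
    comp <- composite_scores(ema$responses, registry)
    daily_comp <- comp |>
      dplyr::group_by(.data$person_id, .data$study_day) |>
      dplyr::summarise(
        ideation_mean = mean(.data$ideation, na.rm = TRUE),
        planning_mean = mean(.data$planning, na.rm = TRUE),
        desire_mean = mean(.data$desire, na.rm = TRUE),
        .groups = "drop"
      )
    daily_comp <- dplyr::mutate(
      daily_comp,
      dplyr::across(dplyr::ends_with("_mean"), ~ ifelse(is.nan(.x), NA_real_, .x))
    )
    prof <- dplyr::left_join(prof, daily_comp, by = c("person_id", "study_day"))
    for (it in registry$item[registry$daily]) {
      if (!it %in% names(ema$responses)) next
      v <- vapply(prof$study_day, function(d) {
        x <- ema$responses[[it]][ema$responses$study_day == d]
        x <- x[!is.na(x)]
        if (length(x) == 0L) NA_real_ else mean(x)
      }, numeric(1))
      prof[[it]] <- v
    }
  }
  prof
}
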