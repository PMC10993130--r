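#' Daily screenshot counts
#'
#' Each captured screen represents one 5-second slot of phone use; daily
#' counts are taken over local calendar days. Duplicate captures within one
#' 5-second slot are collapsed with a warning. Events outside the study
#' window are an error.
#'
#' @param events A `screen_events` or `normalized_screens` tibble for one
#'   person.
#' @param timeline The person's [study_timeline()].
#' @return Tibble `person_id`, `study_day` (1..n_days), `n_screens`
#'   (zero-filled).
#' @export
daily_screen_counts <- function(events, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  scr <- usage_slots(events)
  out <- tibble::tibble(
    person_id = timeline$person_id,
    study_day = seq_len(timeline$n_days),
    n_screens = 0L
  )
  if (nrow(scr) == 0L) return(out)
  day <- study_day_of(scr$ts, scr$utc_offset, timeline)
  if (any(day < 1L | day > timeline$n_days)) {
    stop_screenome("event(s) fall outside study days [1, ", timeline$n_days, "]")
  }
  tab <- table(day)
  out$n_screens[as.integer(names(tab))] <- as.integer(tab)
  out
}

# One row per screen, collapsed to unique 5-second slots.
usage_slots <- function(events) {
  scr <- if (inherits(events, "screen_events")) distinct_screens(events) else events
  scr <- dplyr::distinct(
    tibble::as_tibble(scr)[, intersect(c("person_id", "screen_id", "ts", "utc_offset"),
                                       names(scr))]
  )
  if (nrow(scr) == 0L) return(scr)
  slot <- floor(as.numeric(scr$ts) / 5)
  dup <- duplicated(paste(scr$person_id, slot))
  if (any(dup)) {
    warning(sum(dup), " duplicate capture(s) within a 5-second slot collapsed",
            call. = FALSE)
    scr <- scr[!dup, ]
  }
  scr
}

#' Day-by-hour phone-use matrix
#'
#' Screenshot counts binned by study day (rows) and local hour of day
#' (columns, bins `[h, h+1)`). At the 5-second cadence one hour holds at most
#' 720 captures; exceeding that capacity is an error. Row sums match
#' [daily_screen_counts()].
#'
#' @inheritParams daily_screen_counts
#' @return An integer matrix of class `usage_matrix` (`n_days` x 24) with
#'   `dimnames` `day`, `hour`.
#' @export
hour_matrix <- function(events, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  m <- matrix(0L, nrow = timeline$n_days, ncol = 24L,
              dimnames = list(day = seq_len(timeline$n_days), hour = 0:23))
  scr <- usage_slots(events)
  if (nrow(scr) > 0L) {
    day <- study_day_of(scr$ts, scr$utc_offset, timeline)
    if (any(day < 1L | day > timeline$n_days)) {
      stop_screenome("event(s) fall outside study days [1, ", timeline$n_days, "]")
    }
    hr <- local_hour(scr$ts, scr$utc_offset)
    tab <- table(factor(day, levels = seq_len(timeline$n_days)),
                 factor(hr, levels = 0:23))
    m[] <- as.integer(tab)
  }
  if (any(m > 720L)) {
    stop_screenome("hour bin exceeds the 720-capture capacity of the 5-second cadence")
  }
  structure(m, class = c("usage_matrix", class(m)),
            person_id = timeline$person_id)
}

#' Fraction of each hour spent on the phone
#'
#' Converts capture counts to use fractions: `count * 5 / 3600`, i.e. 360
#' captures correspond to 50% of the hour.
#'
#' @param m A [hour_matrix()].
#' @return Numeric matrix of fractions in `[0, 1]`.
#' @export
usage_fraction <- function(m) {
  unclass(m) * 5 / 3600
}

#' Mean hourly use fraction across days
#'
#' Per hour of day, the mean of daily use fractions over all days in the
#' window, including days with zero collection.
#'
#' @param m A [hour_matrix()].
#' @return Named numeric vector, hours `"0"`..`"23"`.
#' @export
mean_hourly_fraction <- function(m) {
  stopifnot(nrow(m) >= 1L)
  colMeans(usage_fraction(m))
}

#' Hours of intensive phone use
#'
#' Day-hour cells in which the phone was in use more than 50% of the time
#' (strictly greater; a fraction of exactly 0.5 is not flagged).
#'
#' @param m A [hour_matrix()].
#' @return Tibble `study_day`, `hour`, `fraction`.
#' @export
intensive_hours <- function(m) {
  f <- usage_fraction(m)
  idx <- which(f > 0.5, arr.ind = TRUE)
  out <- tibble::tibble(
    study_day = as.integer(rownames(f)[idx[, 1]]),
    hour = as.integer(colnames(f)[idx[, 2]]),
    fraction = f[idx]
  )
  dplyr::arrange(out, .data$study_day, .data$hour)
}

#' Screenshot counts as hours of collection
#'
#' @param count Numeric vector of capture counts.
#' @return `count * 5 / 3600` hours.
#' @examples
#' collection_hours(720) # one hour
#' @export
collection_hours <- function(count) {
  stopifnot(all(count >= 0, na.rm = TRUE))
  count * 5 / 3600
}
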