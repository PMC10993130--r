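# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generator calls do not perturb an enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (report convention for percentages): 45.65 -> 45.7.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_screenome <- function(...) stop(..., call. = FALSE)

# ---- timestamp handling -----------------------------------------------------
# Timestamps carry one fixed UTC offset per person; day/hour binning is in the
# participant's local wall clock (no daylight-saving transitions by design).

# "+05:30", "-0500" or "Z" -> seconds.
parse_utc_offset <- function(x) {
  vapply(x, function(o) {
    if (is.na(o) || !nzchar(o)) return(NA_integer_)
    if (o %in% c("Z", "z")) return(0L)
    m <- regmatches(o, regexec("^([+-])([0-9]{2}):?([0-9]{2})$", o))[[1]]
    if (length(m) == 0L) stop_screenome("invalid UTC offset: '", o, "'")
    s <- if (m[2] == "-") -1L else 1L
    s * (as.integer(m[3]) * 3600L + as.integer(m[4]) * 60L)
  }, integer(1), USE.NAMES = FALSE)
}

format_utc_offset <- function(sec) {
  a <- abs(sec)
  sprintf("%s%02d:%02d", ifelse(sec < 0, "-", "+"), a %/% 3600L, (a %% 3600L) %/% 60L)
}

# ISO-8601 with explicit offset -> list(ts = POSIXct UTC, offset = seconds).
parse_iso_ts <- function(x) {
  m <- regmatches(
    x,
    regexec("^([0-9]{4}-[0-9]{2}-[0-9]{2})[T ]([0-9]{2}:[0-9]{2}:[0-9]{2})(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  )
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop_screenome("unparseable timestamp(s): ", paste(utils::head(x[bad], 3), collapse = ", "))
  }
  wall <- as.POSIXct(
    paste(vapply(m, `[`, "", 2), vapply(m, `[`, "", 3)),
    tz = "UTC"
  )
  offset <- parse_utc_offset(vapply(m, `[`, "", 4))
  list(ts = wall - offset, offset = offset)
}

# POSIXct UTC + offset seconds -> ISO-8601 string in local wall time.
format_iso_ts <- function(ts, offset) {
  paste0(
    format(ts + offset, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    format_utc_offset(offset)
  )
}

# Local wall-clock views of an instant.
local_date <- function(ts, offset) as.Date(ts + offset, tz = "UTC")
local_hour <- function(ts, offset) {
  as.integer(format(ts + offset, "%H", tz = "UTC"))
}

# Study day (1-based) relative to a timeline's start date.
study_day_of <- function(ts, offset, timeline) {
  as.integer(local_date(ts, offset) - timeline$study_start) + 1L
}
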