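#' Plot a daily series with the hospitalization marker
#'
#' Line-and-point plot of one profile column across study days, with a
#' vertical red line on the first hospitalization day and an optional loess
#' trend curve, mirroring the study's figure style.
#'
#' @param profile A profile tibble from [build_profile()].
#' @param var Column name to plot.
#' @param timeline The person's [study_timeline()].
#' @param trend Add a [loess_trend()] curve?
#' @param span Loess span.
#' @return A ggplot object.
#' @export
plot_daily_series <- function(profile, var, timeline, trend = TRUE,
                              span = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_screenome("plotting requires the ggplot2 package")
  }
  df <- tibble::tibble(study_day = profile$study_day, value = profile[[var]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$study_day, y = .data$value)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Study day", y = var)
  if (length(timeline$hospitalization_days) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = timeline$hospitalization_days[1],
                                 colour = "red")
  }
  if (trend && sum(!is.na(df$value)) >= 4L) {
    df$trend <- loess_trend(df$study_day, df$value, span = span)
    p <- p + ggplot2::geom_line(data = df[!is.na(df$trend), ],
                                ggplot2::aes(y = .data$trend), colour = "blue")
  }
  p
}

#' Heatmap of the day-by-hour phone-use matrix
#'
#' @param m A [hour_matrix()].
#' @return A ggplot object (tile heatmap of capture counts).
#' @export
plot_usage_matrix <- function(m) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_screenome("plotting requires the ggplot2 package")
  }
  df <- tibble::as_tibble(as.table(unclass(m)), .name_repair = "minimal")
  names(df) <- c("day", "hour", "count")
  df$day <- as.integer(df$day)
  df$hour <- as.integer(df$hour)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$hour,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Study day", y = "Hour of day", fill = "Captures")
}
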