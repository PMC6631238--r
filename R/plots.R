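#' Plot the time-of-day meal probability profile
#'
#' @param centers_h,sigma_h profile parameters; see [meal_probability()].
#' @param threshold decision threshold drawn as a reference line.
#' @return a ggplot object.
#' @export
plot_meal_profile <- function(centers_h = c(8, 12.5, 20), sigma_h = 1.5,
                              threshold = 0.5) {
  df <- tibble(hour = seq(0, 24, by = 0.05)) %>%
    mutate(p = meal_probability(.data$hour, centers_h, sigma_h))
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "hour of day", y = "meal probability",
                  title = "Probability of a meal by time of day") +
    ggplot2::theme_minimal()
}

#' Plot a sensor stream
#'
#' Accelerometer and gyroscope channels against time of day; long streams
#' are thinned to at most `max_points` samples per channel.
#'
#' @param object a [sensor_stream()].
#' @param max_points thinning limit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sensor_stream <- function(object, max_points = 20000, ...) {
  n <- nrow(object)
  idx <- if (n > max_points) round(seq(1, n, length.out = max_points)) else seq_len(n)
  df <- as_tibble(object[idx, ]) %>%
    mutate(t_h = (stream_t0(object) + (idx - 1) / stream_fs(object)) / 3600) %>%
    tidyr::pivot_longer(c("ax", "ay", "az", "gx", "gy", "gz"),
                        names_to = "channel", values_to = "value") %>%
    mutate(sensor = ifelse(substr(.data$channel, 1, 1) == "a",
                           "accelerometer (m/s²)", "gyroscope (deg/s)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_h, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sensor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "hour of day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a prediction timeline
#'
#' Eating-branch window probabilities and positive drinking windows over
#' the day.
#'
#' @param object a `"prediction_timeline"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.prediction_timeline <- function(object, ...) {
  eat <- mutate(object$eat, t_h = .data$start_s / 3600)
  drink_pos <- filter(object$drink, .data$p > 0.5) %>%
    mutate(t_h = .data$start_s / 3600)
  ggplot2::ggplot(eat, ggplot2::aes(.data$t_h, .data$p)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_point(data = drink_pos,
                        ggplot2::aes(y = .data$p), colour = "darkorange",
                        size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "hour of day", y = "positive-class probability",
                  title = "Branch output (line: eating windows; points: positive drinking windows)") +
    ggplot2::theme_minimal()
}

#' Plot detected events against ground truth
#'
#' @param object an `"intake_predictions"`.
#' @param truth optional [label_track()] drawn underneath.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.intake_predictions <- function(object, truth = NULL, ...) {
  ev <- tidy(object) %>% mutate(source = "predicted")
  if (!is.null(truth)) {
    tv <- as_tibble(truth) %>%
      filter(.data$label != "other") %>%
      mutate(event = ifelse(.data$label == "eat", "meal", "drink"),
             source = "truth") %>%
      select("event", "start_s", "end_s", "source")
    ev <- bind_rows(ev, tv)
  }
  ggplot2::ggplot(ev) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_s / 3600,
                                       xend = .data$end_s / 3600,
                                       y = .data$source, yend = .data$source,
                                       colour = .data$event),
                          linewidth = 4) +
    ggplot2::labs(x = "hour of day", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics of an evaluation
#'
#' @param object an `"intake_eval"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.intake_eval <- function(object, ...) {
  df <- tidy(object) %>%
    filter(.data$class != "weighted") %>%
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
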