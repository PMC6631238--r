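#' Time-of-day meal probability profile
#'
#' Sum of one unit-peak Gaussian per main meal (breakfast, lunch, dinner),
#' clipped at 1. With the default centres (08:00, 12:30, 20:00) and sigma
#' (1.5 h), the profile peaks at 1 at each meal centre and falls close to 0
#' in the night hours. There is no wrap-around at midnight.
#'
#' @param t_hours time of day in hours, vectorized, in `[0, 24)`.
#' @param centers_h Gaussian centres (hours).
#' @param sigma_h common standard deviation (hours).
#' @return probabilities in `[0, 1]`, same length as `t_hours`.
#' @export
#' @examples
#' meal_probability(c(3, 8, 12.5, 20))
meal_probability <- function(t_hours, centers_h = c(8, 12.5, 20),
                             sigma_h = 1.5) {
  comps <- vapply(centers_h, function(mu) {
    exp(-(t_hours - mu)^2 / (2 * sigma_h^2))
  }, numeric(length(t_hours)))
  p <- if (is.matrix(comps)) rowSums(comps) else sum(comps)
  pmin(1, p)
}

#' Meal-probability gating of eating predictions (E1)
#'
#' Fuses the classifier probabilities with the time-of-day meal
#' probability:
#' `pmeal(i) = sum_{n=0..N} pclass(i-n) * ptime(i-n) / N`
#' (N + 1 products divided by N, taken literally from the published
#' formula), flagging window `i` as eating iff `pmeal(i) > threshold`
#' (strict). For the first windows, where fewer than N previous windows
#' exist, the sum runs over the available terms only, still divided by N.
#'
#' @param pclass classifier probabilities on the 10 s window grid.
#' @param ptime meal probability of each window's time of day (same
#'   length).
#' @param N number of previous windows fused (default 3).
#' @param threshold decision threshold (default 0.5, strict).
#' @return logical eating flags, one per window.
#' @export
apply_E1 <- function(pclass, ptime, N = 3, threshold = 0.5) {
  if (length(pclass) != length(ptime)) {
    abort("pclass and ptime must have the same length")
  }
  prod <- pclass * ptime
  pmeal <- numeric(length(prod))
  for (i in seq_along(prod)) {
    lo <- max(1, i - N)
    pmeal[i] <- sum(prod[lo:i]) / N
  }
  pmeal > threshold
}

#' Minute smoothing of window-level eating labels
#'
#' Windows are grouped into consecutive non-overlapping blocks of six,
#' anchored at the stream start (six 10 s windows = one minute). A block is
#' an eating minute iff strictly more than three of its windows are
#' positive. A trailing partial block uses the same strict `> 3` count.
#'
#' @param window_flags logical eating flags on the 10 s window grid.
#' @return logical flags, one per minute block.
#' @export
minute_smooth <- function(window_flags) {
  if (length(window_flags) == 0) return(logical())
  n_blocks <- ceiling(length(window_flags) / 6)
  vapply(seq_len(n_blocks), function(j) {
    b <- window_flags[seq((j - 1) * 6 + 1, min(j * 6, length(window_flags)))]
    sum(b) > 3
  }, logical(1))
}

#' Minimum meal duration (E2)
#'
#' Deletes maximal runs of eating minutes shorter than `min_meal_min`;
#' surviving runs become meal intervals. Idempotent.
#'
#' @param minute_flags logical eating flags on the minute grid.
#' @param min_meal_min minimum duration in minutes (default 5).
#' @return tibble of meal intervals with 1-based inclusive minute indices
#'   `start_min`, `end_min`.
#' @export
apply_E2 <- function(minute_flags, min_meal_min = 5) {
  r <- rle(as.logical(minute_flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_meal_min
  tibble(start_min = starts[keep], end_min = ends[keep])
}

#' Acceleration energy signal and the pre-meal energy restriction (E3)
#'
#' `energy_signal()` is the causal rolling mean, over `win_s`, of the
#' squared gravity-removed acceleration magnitude `(|a| - g)^2`.
#' `apply_E3()` keeps a meal only if the maximum energy within
#' `lookback_s` before its start exceeds `k` times the median energy of
#' the stream (meals starting before the lookback horizon are judged on
#' the available history). The restriction is off in the default pipeline.
#'
#' @param stream a [sensor_stream()].
#' @param win_s rolling window in seconds.
#' @param gravity gravity constant (m/s^2).
#' @return `energy_signal()`: numeric vector, one value per sample.
#' @export
energy_signal <- function(stream, win_s = 10, gravity = .G0) {
  stopifnot(inherits(stream, "sensor_stream"))
  fs <- stream_fs(stream)
  sq <- (sqrt(stream$ax^2 + stream$ay^2 + stream$az^2) - gravity)^2
  w <- max(1L, as.integer(round(win_s * fs)))
  e <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  ## causal head: mean over available history
  head_n <- min(w - 1L, length(sq))
  if (head_n > 0) e[seq_len(head_n)] <- cumsum(sq[seq_len(head_n)]) / seq_len(head_n)
  e
}

#' @rdname energy_signal
#' @param meals meal-interval tibble with `start_s`, `end_s`.
#' @param energy output of `energy_signal()`.
#' @param fs sample rate of `energy`.
#' @param t0 stream start, seconds since midnight.
#' @param lookback_s how far before the meal start to look for a peak.
#' @param k multiple of the stream's median energy a peak must exceed.
#' @return `apply_E3()`: the filtered meal tibble.
#' @export
apply_E3 <- function(meals, energy, fs, t0, lookback_s = 120, k = 3) {
  if (nrow(meals) == 0) return(meals)
  med <- median(energy)
  keep <- vapply(seq_len(nrow(meals)), function(i) {
    start_idx <- floor((meals$start_s[i] - t0) * fs) + 1
    lo <- max(1, start_idx - round(lookback_s * fs))
    hi <- max(1, min(length(energy), start_idx - 1))
    if (hi < lo) return(FALSE)
    max(energy[lo:hi]) > k * med
  }, logical(1))
  meals[keep, , drop = FALSE]
}

#' Thresholded local maxima of a signal
#'
#' Strict local maxima above `thresh`, thinned so that surviving peaks are
#' at least `min_sep` samples apart (greedy, highest first).
#'
#' @param x numeric signal.
#' @param thresh height threshold.
#' @param min_sep minimum separation in samples.
#' @return integer vector of peak indices, increasing.
#' @export
find_rot_peaks <- function(x, thresh, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > thresh]
  if (length(cand) <= 1 || min_sep <= 1) return(cand)
  ord <- cand[order(-x[cand])]
  keep <- integer()
  for (p in ord) {
    if (all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Rotational-magnitude peak restriction for drinking (D1)
#'
#' Keeps a positive drinking window only if it contains at least one local
#' maximum of the gyroscope rotational magnitude above `peak_thresh`;
#' surviving contiguous windows are merged into drink events.
#'
#' @param windows positive drinking windows (tibble with `start_idx`,
#'   `end_idx` on the magnitude signal's sample grid).
#' @param gyro_mag the rotational magnitude signal ([gyro_magnitude()]).
#' @param fs sample rate (Hz).
#' @param t0 stream start, seconds since midnight.
#' @param peak_thresh peak height threshold (deg/s, default 60).
#' @param min_sep_s minimum peak separation in seconds (default 0.25).
#' @return tibble of drink events with `start_s`, `end_s`.
#' @export
apply_D1 <- function(windows, gyro_mag, fs, t0, peak_thresh = 60,
                     min_sep_s = 0.25) {
  if (nrow(windows) == 0) {
    return(tibble(start_s = numeric(), end_s = numeric()))
  }
  peaks <- find_rot_peaks(gyro_mag, peak_thresh,
                          max(1L, as.integer(round(min_sep_s * fs))))
  keep <- vapply(seq_len(nrow(windows)), function(i) {
    any(peaks >= windows$start_idx[i] & peaks <= windows$end_idx[i])
  }, logical(1))
  kept <- windows[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(tibble(start_s = numeric(), end_s = numeric()))
  kept <- arrange(kept, .data$start_idx)
  ## merge windows that touch (share a boundary sample neighbourhood)
  grp <- cumsum(c(1, as.integer(kept$start_idx[-1] >
                                  kept$end_idx[-nrow(kept)] + 1L)))
  kept %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(start_idx = min(.data$start_idx),
              end_idx = max(.data$end_idx), .groups = "drop") %>%
    mutate(start_s = t0 + (.data$start_idx - 1) / fs,
           end_s = t0 + .data$end_idx / fs) %>%
    select("start_s", "end_s")
}

#' Fuse meal intervals and drink events into per-unit labels
#'
#' Labels each 10 s unit of the stream: `drink` if a drink event overlaps
#' the unit, else `eat` if the unit midpoint lies inside a meal interval,
#' else `other`.
#'
#' @param meals meal tibble with `start_s`, `end_s`.
#' @param drinks drink-event tibble with `start_s`, `end_s`.
#' @param t0 stream start, seconds since midnight.
#' @param duration_s stream duration in seconds.
#' @param unit_s grid unit (default 10 s).
#' @return tibble with `start_s`, `end_s`, `label` --
#'   `ceiling(duration_s / unit_s)` rows.
#' @export
fuse_events <- function(meals, drinks, t0, duration_s, unit_s = 10) {
  n_units <- ceiling(duration_s / unit_s)
  starts <- t0 + (seq_len(n_units) - 1) * unit_s
  mids <- starts + unit_s / 2
  lab <- rep("other", n_units)
  if (nrow(meals) > 0) {
    for (r in seq_len(nrow(meals))) {
      lab[mids >= meals$start_s[r] & mids < meals$end_s[r]] <- "eat"
    }
  }
  if (nrow(drinks) > 0) {
    for (r in seq_len(nrow(drinks))) {
      lab[starts < drinks$end_s[r] & (starts + unit_s) > drinks$start_s[r]] <- "drink"
    }
  }
  tibble(start_s = starts, end_s = starts + unit_s, label = lab)
}

#' Apply the daily-evidence restriction layer
#'
#' Runs the full post-processing stack on a [run_semi_hierarchical()]
#' timeline. Eating: meal-probability gating (E1) on the 10 s window grid,
#' minute smoothing (> 3 positive windows in a block of six), then the
#' minimum meal duration (E2); optionally the pre-meal energy restriction
#' (E3, off by default -- it is not part of the selected pipeline).
#' Drinking: positive dynamic windows filtered by the rotational-peak
#' restriction (D1) and merged into events. Also records the *raw*
#' minute-smoothed eating flags (threshold on the classifier probability
#' only) so the effect of the restrictions can be measured.
#'
#' @param timeline a `"prediction_timeline"`.
#' @param config an [intake_config()].
#' @param stream optional: the preprocessed stream, needed only when
#'   `config$use_E3` is TRUE.
#' @return an object of class `"intake_predictions"`: meals and drink
#'   events (second intervals), fused 10 s unit labels, raw and restricted
#'   minute flags, and bookkeeping.
#' @export
apply_restrictions <- function(timeline, config = intake_config(),
                               stream = NULL) {
  stopifnot(inherits(timeline, "prediction_timeline"))
  t0 <- timeline$t0
  dur <- timeline$n / timeline$fs

  mid_h <- ((timeline$eat$start_s + timeline$eat$end_s) / 2) / 3600
  ptime <- meal_probability(mid_h, config$meal_centers_h, config$meal_sigma_h)
  e1 <- apply_E1(timeline$eat$p, ptime, config$smoothing_N,
                 config$meal_threshold)
  restricted_min <- minute_smooth(e1)
  raw_min <- minute_smooth(timeline$eat$p > 0.5)
  meals_idx <- apply_E2(restricted_min, config$min_meal_min)
  meals <- tibble(start_s = t0 + (meals_idx$start_min - 1) * 60,
                  end_s = t0 + meals_idx$end_min * 60)
  if (isTRUE(config$use_E3)) {
    if (is.null(stream)) abort("E3 requires the preprocessed stream")
    en <- energy_signal(stream, config$energy_win_s, config$gravity)
    meals <- apply_E3(meals, en, timeline$fs, t0,
                      config$energy_lookback_s, config$energy_k)
  }

  pos <- filter(timeline$drink, .data$p > 0.5)
  drinks <- apply_D1(pos, timeline$gyro_mag, timeline$fs, t0,
                     config$peak_thresh, config$peak_min_sep_s)

  units <- fuse_events(meals, drinks, t0, dur, unit_s = 10)
  structure(list(
    meals = meals,
    drinks = drinks,
    units = units,
    minute_flags = restricted_min,
    raw_minute_flags = raw_min,
    t0 = t0, duration_s = dur, fs = timeline$fs,
    config = config
  ), class = "intake_predictions")
}

#' @export
print.intake_predictions <- function(x, ...) {
  cat(sprintf(
    "<intake_predictions> %.2f h: %d meal(s), %d drink event(s)\n",
    x$duration_s / 3600, nrow(x$meals), nrow(x$drinks)))
  invisible(x)
}

#' @export
tidy.intake_predictions <- function(x, ...) {
  bind_rows(
    mutate(x$meals, event = "meal"),
    mutate(x$drinks, event = "drink")
  ) %>%
    arrange(.data$start_s) %>%
    select("event", "start_s", "end_s")
}
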