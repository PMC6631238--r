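#' Plan of a synthetic free-living day
#'
#' Describes a day of wrist-IMU data to synthesize: meal blocks, drink
#' events, a background activity schedule and noise levels. The default
#' plan is a 16 h waking day (06:00--22:00) with three meals -- breakfast
#' 08:30 (10 min), lunch 12:00 (13.5 min), dinner 19:30 (13 min), 36.5 min
#' in total so eating covers 3.8 % of the day -- and 34 drink events of
#' 12 s whose central ~7 s carry the two-peak drinking gesture (0.7 % of
#' the day). Each meal is preceded, 30--120 s before its start, by a
#' high-energy acceleration burst (meal preparation). Background blocks
#' cycle desk work, idle sitting and walking; when `distractors = TRUE`
#' the afternoon additionally contains a 45 min board-game block and a
#' 10 min nail-biting block, the activities most frequently confused with
#' eating and drinking.
#'
#' @param seed integer seed; all of the day's randomness flows from it.
#' @param day_start_h,day_length_h day start (hour of day) and length (h).
#' @param meals tibble with `start_h`, `duration_min`, `gesture_period_s`,
#'   `pre_burst`.
#' @param drinks tibble with `start_h`, `duration_s`; events must not
#'   overlap each other (a drink may lie inside a meal).
#' @param distractors include the board-game / nail-biting blocks.
#' @param background_kinds activity kinds cycled through to fill the
#'   non-event parts of the day.
#' @param noise list of channel noise levels.
#' @return a list of class `"day_plan"`.
#' @export
day_plan <- function(seed = 1,
                     day_start_h = 6, day_length_h = 16,
                     meals = NULL, drinks = NULL,
                     distractors = TRUE,
                     background_kinds = c("desk", "idle", "walk"),
                     noise = list(acc = 0.05, gyro = 1)) {
  if (is.null(meals)) {
    meals <- tibble(start_h = c(8.5, 12.0, 19.5),
                    duration_min = c(10, 13.5, 13),
                    gesture_period_s = c(6, 6, 6),
                    pre_burst = c(TRUE, TRUE, TRUE))
  }
  if (is.null(drinks)) {
    drinks <- withr::with_seed(seed, {
      ## 34 occasions, one per equal slot of the day, jittered within slots
      slot_h <- (day_length_h - 0.2) / 34
      starts <- day_start_h + 0.1 + (seq_len(34) - 1) * slot_h +
        runif(34, 0, slot_h - 15 / 3600)
      tibble(start_h = starts, duration_s = rep(12, 34))
    })
  }
  plan <- structure(list(
    seed = as.integer(seed),
    day_start_h = day_start_h, day_length_h = day_length_h,
    meals = meals, drinks = drinks,
    distractors = isTRUE(distractors),
    background_kinds = background_kinds,
    noise = noise,
    fs = 100
  ), class = "day_plan")
  validate_day_plan(plan)
  plan
}

validate_day_plan <- function(plan) {
  end_h <- plan$day_start_h + plan$day_length_h
  m <- plan$meals
  if (nrow(m) > 0) {
    if (any(m$duration_min < 1)) abort("meal durations must be >= 1 min")
    if (any(m$start_h < plan$day_start_h |
              m$start_h + m$duration_min / 60 > end_h)) {
      abort("meal outside the day")
    }
  }
  d <- plan$drinks
  if (nrow(d) > 0) {
    if (any(d$duration_s < 2 | d$duration_s > 15)) {
      abort("drink durations must lie in [2, 15] s")
    }
    if (any(d$start_h < plan$day_start_h |
              d$start_h + d$duration_s / 3600 > end_h)) {
      abort("drink outside the day")
    }
    d <- arrange(d, .data$start_h)
    if (nrow(d) >= 2) {
      ov <- which(d$start_h[-1] * 3600 < d$start_h[-nrow(d)] * 3600 +
                    d$duration_s[-nrow(d)])
      if (length(ov) > 0) {
        abort(sprintf("drink events %d and %d overlap", ov[1], ov[1] + 1))
      }
    }
  }
  invisible(plan)
}

## smooth unit bump (raised cosine) of given width in samples, centred at c
bump <- function(n, center, width) {
  i <- seq_len(n)
  u <- (i - center) / (width / 2)
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}

.SEGMENT_KINDS <- c("eat", "drink", "walk", "desk", "idle",
                    "table_game", "nail_biting", "burst")

#' Generate one activity segment
#'
#' Synthesizes `duration_s` seconds of six-channel wrist-IMU signal for a
#' single activity, using the additive model gravity + activity template +
#' white noise. Kinds: `idle` and `desk` are low-variance; `walk` carries a
#' ~2 Hz periodic arm swing; `eat` shows sparse low-amplitude hand-to-mouth
#' rotations (~40--70 deg/s) every `gesture_period_s` over a manipulative
#' jitter floor; `drink` contains exactly two large rotational-magnitude
#' peaks (grab/raise and put-down, ~120--180 deg/s) with a quiet tilted
#' hold between them; `table_game` and `nail_biting` are distractors that
#' mimic eating-like manipulation and small repetitive wrist rotations;
#' `burst` is a short high-energy acceleration burst (meal preparation).
#'
#' @param kind one of `eat, drink, walk, desk, idle, table_game,
#'   nail_biting, burst`.
#' @param duration_s segment duration in seconds.
#' @param fs sample rate (default 100 Hz).
#' @param params optional list: `gesture_period_s` (eat), `peak_amp`
#'   (drink, deg/s), `noise` (list with `acc`, `gyro`).
#' @param seed optional seed; when NULL the current RNG state is used (so
#'   [generate_day()] can drive everything from one seed).
#' @return a [sensor_stream()] at `fs`.
#' @export
generate_activity_segment <- function(kind, duration_s, fs = 100,
                                      params = list(), seed = NULL) {
  if (!kind %in% .SEGMENT_KINDS) {
    abort(paste0("unknown activity kind: ", kind))
  }
  gen <- function() segment_matrix(kind, duration_s, fs, params)
  mat <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  new_stream_like(mat, fs = fs, t0 = 0)
}

segment_matrix <- function(kind, duration_s, fs, params = list()) {
  n <- max(2L, as.integer(round(duration_s * fs)))
  noise <- params$noise %||% list(acc = 0.05, gyro = 1)
  acc <- matrix(rnorm(3 * n, 0, noise$acc), n, 3)
  gyr <- matrix(rnorm(3 * n, 0, noise$gyro), n, 3)
  acc[, 3] <- acc[, 3] + .G0          # gravity baseline along z
  t <- (seq_len(n) - 1) / fs

  add_gesture <- function(acc, gyr, center_s, width_s, amp_dps, tilt_ms2) {
    b <- bump(n, center_s * fs, width_s * fs)
    gyr[, 1] <- gyr[, 1] + amp_dps * b
    gyr[, 2] <- gyr[, 2] + 0.35 * amp_dps * b
    acc[, 1] <- acc[, 1] + tilt_ms2 * b
    acc[, 3] <- acc[, 3] - 0.6 * tilt_ms2 * b
    list(acc = acc, gyr = gyr)
  }

  if (kind == "idle") {
    ## nothing beyond gravity + floor noise
  } else if (kind == "desk") {
    gyr <- gyr + matrix(rnorm(3 * n, 0, 2), n, 3)
    acc <- acc + matrix(rnorm(3 * n, 0, 0.1), n, 3)
    ## occasional small reach
    k <- max(0L, stats::rpois(1, duration_s / 20))
    for (i in seq_len(k)) {
      g <- add_gesture(acc, gyr, runif(1, 1, duration_s - 1), 1.2,
                       runif(1, 10, 25), runif(1, 0.3, 0.8))
      acc <- g$acc; gyr <- g$gyr
    }
  } else if (kind == "walk") {
    f <- runif(1, 1.8, 2.2)
    ph <- runif(3, 0, 2 * pi)
    acc[, 1] <- acc[, 1] + 2.5 * sin(2 * pi * f * t + ph[1]) +
      rnorm(n, 0, 0.3)
    acc[, 2] <- acc[, 2] + 1.5 * sin(2 * pi * f * t + ph[2]) +
      rnorm(n, 0, 0.3)
    acc[, 3] <- acc[, 3] + 0.8 * sin(2 * pi * f * t + ph[3])
    gyr[, 1] <- gyr[, 1] + 35 * sin(2 * pi * f * t + ph[1]) + rnorm(n, 0, 2)
    gyr[, 2] <- gyr[, 2] + 18 * sin(2 * pi * f * t + ph[2]) + rnorm(n, 0, 2)
  } else if (kind == "eat" || kind == "table_game") {
    ## manipulative jitter floor
    jit <- if (kind == "eat") 8 else 7
    gyr <- gyr + matrix(rnorm(3 * n, 0, jit), n, 3)
    acc <- acc + matrix(rnorm(3 * n, 0, 0.12), n, 3)
    period <- params$gesture_period_s %||% if (kind == "eat") 6 else 7.5
    centers <- seq(period / 2, duration_s - 1, by = period)
    centers <- centers + runif(length(centers), -0.15 * period, 0.15 * period)
    centers <- centers[centers > 1 & centers < duration_s - 1]
    for (cs in centers) {
      g <- add_gesture(acc, gyr, cs, 1.8, runif(1, 40, 70),
                       runif(1, 1.2, 2.2))
      acc <- g$acc; gyr <- g$gyr
    }
  } else if (kind == "drink") {
    amp <- params$peak_amp %||% runif(1, 120, 180)
    ## grab/raise and put-down rotations near the ends: quick ~0.6 s wrist
    ## turns with a tilted, tremoring hold between them
    c1 <- 0.18 * duration_s; c2 <- 0.82 * duration_s
    b1 <- bump(n, c1 * fs, 0.6 * fs); b2 <- bump(n, c2 * fs, 0.6 * fs)
    gyr[, 1] <- gyr[, 1] + amp * b1 + 0.9 * amp * b2
    gyr[, 3] <- gyr[, 3] + 0.4 * amp * (b1 - b2)
    hold <- bump(n, (c1 + c2) / 2 * fs, (c2 - c1) * fs)
    acc[, 1] <- acc[, 1] + 3.0 * hold       # tilted while sipping
    acc[, 3] <- acc[, 3] - 1.8 * hold
    ## a held vessel is never gyro-silent: low-amplitude tremor while
    ## sipping keeps the rotational magnitude wiggling between the peaks
    gyr[, 2] <- gyr[, 2] + hold * rnorm(n, 0, 3)
  } else if (kind == "nail_biting") {
    f <- runif(1, 2.5, 3.2)
    env <- 0.5 + 0.5 * sin(2 * pi * t / runif(1, 8, 14))
    gyr[, 1] <- gyr[, 1] + 28 * env * sin(2 * pi * f * t)
    gyr[, 2] <- gyr[, 2] + 14 * env * sin(2 * pi * f * t + 1)
    acc[, 1] <- acc[, 1] + 2.2            # hand held near mouth
    acc[, 3] <- acc[, 3] - 1.2
  } else if (kind == "burst") {
    ## high-energy movement: meal preparation, washing hands
    acc <- acc + matrix(rnorm(3 * n, 0, 2.5), n, 3)
    gyr <- gyr + matrix(rnorm(3 * n, 0, 30), n, 3)
  }
  cbind(acc, gyr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labeled synthetic day
#'
#' Renders a [day_plan()] into a 100 Hz [sensor_stream()] plus the exactly
#' matching [label_track()]. The signal model is additive: a gravity
#' baseline, per-activity templates (see [generate_activity_segment()])
#' and white noise. Background blocks are laid down first, then meal
#' blocks, pre-meal energy bursts and drink events are overlaid in that
#' order, so a drink during a meal replaces the eating signal and is
#' labeled `drink` (precedence drink > eat).
#'
#' @param plan a [day_plan()].
#' @return list with `stream` (a [sensor_stream()] with
#'   `day_length_h * 3600 * 100` samples, `t0 = day_start_h * 3600`) and
#'   `labels` (a [label_track()]).
#' @export
#' @examples
#' d <- generate_day(day_plan(seed = 42, day_length_h = 0.2,
#'                            meals = tibble::tibble(start_h = 6.05,
#'                              duration_min = 2, gesture_period_s = 6,
#'                              pre_burst = FALSE),
#'                            drinks = tibble::tibble(start_h = 6.15,
#'                              duration_s = 12),
#'                            distractors = FALSE))
#' d$stream
generate_day <- function(plan) {
  stopifnot(inherits(plan, "day_plan"))
  validate_day_plan(plan)
  fs <- plan$fs
  t0 <- plan$day_start_h * 3600
  n <- as.integer(round(plan$day_length_h * 3600 * fs))

  withr::with_seed(plan$seed, {
    mat <- matrix(0, n, 6)

    ## --- background schedule: cycle desk / idle / walk (+ distractors)
    sched <- background_schedule(plan)
    for (r in seq_len(nrow(sched))) {
      i0 <- as.integer(round((sched$start_h[r] - plan$day_start_h) * 3600 * fs)) + 1L
      seg <- segment_matrix(sched$kind[r], sched$duration_s[r], fs,
                            list(noise = plan$noise))
      i1 <- min(n, i0 + nrow(seg) - 1L)
      mat[i0:i1, ] <- seg[seq_len(i1 - i0 + 1L), ]
    }

    ## --- meals
    labels <- list()
    for (r in seq_len(nrow(plan$meals))) {
      m <- plan$meals[r, ]
      start_s <- m$start_h * 3600
      dur_s <- m$duration_min * 60
      i0 <- as.integer(round((start_s - t0) * fs)) + 1L
      seg <- segment_matrix("eat", dur_s, fs,
                            list(gesture_period_s = m$gesture_period_s,
                                 noise = plan$noise))
      i1 <- min(n, i0 + nrow(seg) - 1L)
      mat[i0:i1, ] <- seg[seq_len(i1 - i0 + 1L), ]
      labels[[length(labels) + 1L]] <-
        tibble(start_s = start_s, end_s = start_s + dur_s, label = "eat")
      if (isTRUE(m$pre_burst)) {
        lead <- runif(1, 30, 120)
        b0 <- as.integer(round((start_s - lead - t0) * fs)) + 1L
        if (b0 >= 1) {
          bseg <- segment_matrix("burst", 10, fs, list(noise = plan$noise))
          b1 <- min(n, b0 + nrow(bseg) - 1L)
          mat[b0:b1, ] <- bseg[seq_len(b1 - b0 + 1L), ]
        }
      }
    }

    ## --- drinks (overlaid last: precedence drink > eat)
    for (r in seq_len(nrow(plan$drinks))) {
      d <- plan$drinks[r, ]
      start_s <- d$start_h * 3600
      i0 <- as.integer(round((start_s - t0) * fs)) + 1L
      seg <- segment_matrix("drink", d$duration_s, fs,
                            list(noise = plan$noise))
      i1 <- min(n, i0 + nrow(seg) - 1L)
      mat[i0:i1, ] <- seg[seq_len(i1 - i0 + 1L), ]
      labels[[length(labels) + 1L]] <-
        tibble(start_s = start_s, end_s = start_s + d$duration_s,
               label = "drink")
    }

    stream <- new_stream_like(mat, fs = fs, t0 = t0)
    track <- label_track(bind_rows(labels))
    list(stream = stream, labels = track)
  })
}

## background layout: base blocks first, distractor overlays last (the
## rendering loop overwrites in row order, so later rows win)
background_schedule <- function(plan) {
  end_h <- plan$day_start_h + plan$day_length_h
  kinds <- plan$background_kinds
  durs_min <- c(desk = 35, idle = 20, walk = 10,
                table_game = 30, nail_biting = 10)
  rows <- list()
  cur <- plan$day_start_h
  k <- 1L
  while (cur < end_h) {
    kind <- kinds[(k - 1L) %% length(kinds) + 1L]
    d_min <- min(durs_min[[kind]] %||% 20, (end_h - cur) * 60)
    rows[[k]] <- tibble(start_h = cur, duration_s = d_min * 60, kind = kind)
    cur <- cur + d_min / 60
    k <- k + 1L
  }
  sched <- bind_rows(rows)
  if (plan$distractors && plan$day_length_h >= 12) {
    sched <- bind_rows(
      sched,
      tibble(start_h = plan$day_start_h + 9.25, duration_s = 45 * 60,
             kind = "table_game"),
      tibble(start_h = plan$day_start_h + 11.5, duration_s = 10 * 60,
             kind = "nail_biting")
    )
  }
  sched
}
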