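#' Label windows from a ground-truth track
#'
#' Assigns each window the label of the interval covering its midpoint
#' (precedence drink > eat > other; uncovered midpoints are `other`),
#' mirroring the grid rasterization rule.
#'
#' @param windows window tibble (`start_idx`, `end_idx`, 1-based
#'   inclusive).
#' @param track a [label_track()].
#' @param fs sample rate of the windowed stream.
#' @param t0 stream start, seconds since midnight.
#' @return the windows tibble with a `label` column appended.
#' @export
label_windows <- function(windows, track, fs, t0) {
  if (nrow(windows) == 0) return(mutate(windows, label = character()))
  mid_s <- t0 + ((windows$start_idx + windows$end_idx) / 2 - 0.5) / fs
  lab <- rep("other", nrow(windows))
  for (cls in c("eat", "drink")) {
    iv <- track[track$label == cls, , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      lab[mid_s >= iv$start_s[r] & mid_s < iv$end_s[r]] <- cls
    }
  }
  mutate(windows, label = lab)
}

#' Build labeled training tables for both branches
#'
#' Preprocesses a labeled recording and produces the two per-branch
#' feature tables: the eating table from fixed windows (10 s, 25 %
#' overlap -- overlap augments the training windows), the drinking table
#' from dynamic fixed windows of the gyroscope magnitude. For the drinking
#' table, non-drinking windows are subsampled (seeded) to the curated
#' ratio `config$drink_neg_ratio` non-drinking windows per drinking
#' window, mimicking the curated composition of the reference training
#' set.
#'
#' @param stream a raw (100 Hz) [sensor_stream()].
#' @param track the matching [label_track()].
#' @param config an [intake_config()].
#' @param seed seed for the negative subsampling.
#' @return list with tibbles `eat` and `drink`, each feature columns plus
#'   `label`.
#' @export
build_training_tables <- function(stream, track, config = intake_config(),
                                  seed = config$seed) {
  pp <- preprocess_stream(stream, config)
  fs <- stream_fs(pp); t0 <- stream_t0(pp)

  fw <- fixed_windows(nrow(pp), fs, config$fw_length_s, config$fw_overlap)
  eat <- extract_features(pp, fw, config$gravity, config$eps) %>%
    label_windows(track, fs, t0)

  mag <- gyro_magnitude(pp)
  dfw <- dynamic_fixed_windows(mag, fs, config$dfw_t_s, config$dw_N,
                               config$dw_scale, config$dw_floor) %>%
    filter(.data$end_idx - .data$start_idx + 1 >= 2)
  drink <- extract_features(pp, dfw, config$gravity, config$eps) %>%
    label_windows(track, fs, t0)

  pos <- which(drink$label == "drink")
  neg <- which(drink$label != "drink")
  n_keep <- min(length(neg),
                max(1L, round(config$drink_neg_ratio * length(pos))))
  keep_neg <- withr::with_seed(seed, sort(sample(neg, n_keep)))
  drink <- drink[sort(c(pos, keep_neg)), , drop = FALSE]

  list(eat = eat, drink = drink)
}

#' Default training cohort of scripted synthetic sessions
#'
#' Generates `n_sessions` scripted acquisition sessions (dense eating
#' blocks, frequent drink events, walking / desk / idle background; no
#' distractor activities, which are deliberately held out for testing) and
#' stacks their training tables.
#'
#' @param config an [intake_config()].
#' @param seed cohort seed; session `i` uses `seed + i`.
#' @param n_sessions number of sessions (default 2).
#' @return list with stacked `eat` and `drink` training tibbles.
#' @export
generate_training_cohort <- function(config = intake_config(),
                                     seed = config$seed, n_sessions = 2) {
  tabs <- purrr::map(seq_len(n_sessions), function(i) {
    plan <- training_session_plan(seed + i)
    d <- generate_day(plan)
    build_training_tables(d$stream, d$labels, config, seed = seed + i)
  })
  list(eat = bind_rows(purrr::map(tabs, "eat")),
       drink = bind_rows(purrr::map(tabs, "drink")))
}

## a 1.5 h scripted session: three eating blocks, 25 drinks, varied
## background; times are hour-of-day but irrelevant for training
training_session_plan <- function(seed) {
  drinks <- withr::with_seed(seed, {
    slots <- seq(10.02, 11.45, length.out = 25)
    tibble(start_h = slots + runif(25, 0, 0.012), duration_s = 12)
  })
  day_plan(
    seed = seed,
    day_start_h = 10, day_length_h = 1.5,
    meals = tibble(start_h = c(10.1, 10.6, 11.1),
                   duration_min = c(8, 8, 8),
                   gesture_period_s = c(5, 6, 7),
                   pre_burst = c(FALSE, FALSE, FALSE)),
    drinks = drinks,
    distractors = FALSE
  )
}
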