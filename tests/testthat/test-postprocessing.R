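test_that("the meal probability profile matches its closed form", {
  ## lunch centre: clipped at 1 (tail contributions push the sum past 1)
  expect_equal(meal_probability(12.5), 1)
  ## night: essentially zero
  expect_lt(meal_probability(3), 0.005)
  expect_equal(meal_probability(3),
               sum(exp(-(3 - c(8, 12.5, 20))^2 / (2 * 1.5^2))))
  ## symmetry around lunch: the lunch component is identical at 11 h and
  ## 14 h, so the difference equals exactly the other components' tails
  tails <- function(t) exp(-(t - 8)^2 / 4.5) + exp(-(t - 20)^2 / 4.5)
  expect_equal(meal_probability(11) - meal_probability(14),
               tails(11) - tails(14))
  ## bounded in [0, 1]; day maximum at a meal centre
  grid <- seq(0, 23.99, by = 0.01)
  p <- meal_probability(grid)
  expect_true(all(p >= 0 & p <= 1))
  ## the day maximum (the clipped plateau) is attained only near centres
  at_max <- grid[p == max(p)]
  expect_true(all(vapply(at_max, function(t) {
    min(abs(t - c(8, 12.5, 20))) < 0.5
  }, logical(1))))
  expect_equal(meal_probability(c(8, 12.5, 20)), rep(1, 3))
})

test_that("meal-probability gating follows the published fusion literally", {
  ## all products 1: pmeal = (N+1)/N = 4/3 -> eating
  expect_true(apply_E1(rep(1, 10), rep(1, 10))[10])
  ## all zero -> not eating
  expect_false(any(apply_E1(rep(0, 10), rep(1, 10))))
  ## boundary: (0.6+0.7+0.8+0.9) * 0.5 / 3 = 0.5, strict > -> not eating
  expect_false(apply_E1(c(0.6, 0.7, 0.8, 0.9), rep(0.5, 4))[4])
  ## just above the boundary -> eating
  expect_true(apply_E1(c(0.6, 0.7, 0.8, 0.91), rep(0.5, 4))[4])
  ## early windows: available history only, still divided by N
  expect_equal(apply_E1(c(0.9, 0.9), c(1, 1)),
               c(0.9 / 3 > 0.5, 1.8 / 3 > 0.5))
})

test_that("minute smoothing needs strictly more than three positive windows of six", {
  expect_true(minute_smooth(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_false(minute_smooth(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_false(minute_smooth(rep(FALSE, 6)))
  ## blocks are anchored at the stream start and independent
  flags <- c(rep(TRUE, 6), rep(FALSE, 6), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(minute_smooth(flags), c(TRUE, FALSE, TRUE))
  ## block ordering is positional, not lexicographic, beyond 10 minutes
  long <- rep(c(rep(TRUE, 6), rep(FALSE, 6)), 8)   # alternating 16 minutes
  expect_equal(minute_smooth(long), rep(c(TRUE, FALSE), 8))
  ## trailing partial block keeps the strict rule
  expect_equal(minute_smooth(rep(TRUE, 10)), c(TRUE, TRUE))
  expect_equal(minute_smooth(rep(TRUE, 9)), c(TRUE, FALSE))
})

test_that("the minimum-meal-duration rule deletes short runs and is idempotent", {
  f <- function(runs) rep(runs$v, runs$l)
  ## 4-minute run deleted
  expect_equal(nrow(apply_E2(c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3)))), 0)
  ## 5-minute run kept, boundary inclusive
  m5 <- apply_E2(c(rep(FALSE, 2), rep(TRUE, 5), FALSE))
  expect_equal(m5, tibble::tibble(start_min = 3, end_min = 7))
  ## two 3-minute runs separated by one negative minute: both deleted
  flags <- c(rep(TRUE, 3), FALSE, rep(TRUE, 3))
  expect_equal(nrow(apply_E2(flags)), 0)
  ## idempotence and the >= 5 min output guarantee
  withr::with_seed(33, {
    for (k in 1:10) {
      flags <- runif(120) > 0.6
      m <- apply_E2(flags)
      if (nrow(m) > 0) expect_true(all(m$end_min - m$start_min + 1 >= 5))
      kept <- rep(FALSE, 120)
      for (r in seq_len(nrow(m))) kept[m$start_min[r]:m$end_min[r]] <- TRUE
      expect_equal(apply_E2(kept), m)
    }
  })
})

test_that("acceleration energy flags pre-meal bursts (E3)", {
  ## stationary stream: energy ~ 0
  qs <- sensor_stream(data.frame(ax = 0, ay = 0, az = 9.80665,
                                 gx = 0, gy = 0, gz = 0)[rep(1, 2000), ],
                      fs = 50)
  expect_lt(max(energy_signal(qs, 10)), 1e-12)

  ## synthetic day with pre-meal bursts: the meal passes E3; with bursts
  ## removed it is rejected
  mk <- function(burst) {
    p <- day_plan(seed = 17, day_start_h = 8, day_length_h = 0.4,
                  meals = tibble::tibble(start_h = 8.2, duration_min = 6,
                                         gesture_period_s = 6,
                                         pre_burst = burst),
                  drinks = tibble::tibble(start_h = numeric(),
                                          duration_s = numeric()),
                  distractors = FALSE, background_kinds = "idle")
    generate_day(p)
  }
  for (burst in c(TRUE, FALSE)) {
    d <- mk(burst)
    pp <- preprocess_stream(d$stream, intake_config())
    en <- energy_signal(pp, 10)
    meals <- tibble::tibble(start_s = 8.2 * 3600, end_s = 8.2 * 3600 + 360)
    kept <- apply_E3(meals, en, 50, 8 * 3600, lookback_s = 120, k = 3)
    expect_equal(nrow(kept), if (burst) 1 else 0)
  }
})

test_that("the rotational-peak restriction keeps only windows containing peaks", {
  ## synthetic sip: two peaks -> window kept
  dr <- generate_activity_segment("drink", 7, seed = 2)
  mag <- gyro_magnitude(dr)
  w <- tibble::tibble(start_idx = 1L, end_idx = as.integer(length(mag)),
                      method = "DFW")
  ev <- apply_D1(w, mag, fs = 100, t0 = 0, peak_thresh = 60)
  expect_equal(nrow(ev), 1)
  ## flat gyro -> dropped; threshold above the global maximum -> dropped
  expect_equal(nrow(apply_D1(w, rep(0, length(mag)), 100, 0, 60)), 0)
  expect_equal(nrow(apply_D1(w, mag, 100, 0, max(mag) + 1)), 0)
  ## contiguous surviving windows merge into one event
  w2 <- tibble::tibble(start_idx = c(1L, 351L), end_idx = c(350L, 700L),
                       method = "DFW")
  ev2 <- apply_D1(w2, mag, 100, 0, 60)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$start_s, 0)
  expect_equal(ev2$end_s, 7)
})

test_that("peak finding agrees with an independent peak detector", {
  skip_if_not_installed("pracma")
  withr::with_seed(41, {
    for (k in 1:5) {
      x <- abs(cumsum(rnorm(800))) + 50 * bump_vec(800, 200, 80) +
        70 * bump_vec(800, 600, 60)
      mine <- find_rot_peaks(x, 30, min_sep = 1)
      pm <- pracma::findpeaks(x, minpeakheight = 30)
      expect_setequal(mine, pm[, 2])
    }
  })
})

test_that("fusion labels units with drink > eat > other precedence", {
  meals <- tibble::tibble(start_s = 100, end_s = 400)
  drinks <- tibble::tibble(start_s = 205, end_s = 212)
  units <- fuse_events(meals, drinks, t0 = 0, duration_s = 600)
  expect_equal(nrow(units), 60)
  ## the sip overlaps units [200,210) and [210,220)
  expect_equal(units$label[21:22], c("drink", "drink"))
  expect_equal(units$label[20], "eat")
  expect_equal(units$label[23], "eat")
  expect_equal(units$label[1], "other")
  ## no events -> all other; unit count = ceil(duration / 10)
  e <- fuse_events(tibble::tibble(start_s = numeric(), end_s = numeric()),
                   tibble::tibble(start_s = numeric(), end_s = numeric()),
                   0, 95)
  expect_equal(nrow(e), 10)
  expect_true(all(e$label == "other"))
})
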