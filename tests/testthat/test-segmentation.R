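test_that("gyro magnitude is the per-sample Euclidean norm", {
  s <- sensor_stream(data.frame(ax = 0, ay = 0, az = 0,
                                gx = 3, gy = 4, gz = 0), fs = 50)
  expect_equal(gyro_magnitude(s), 5)
  z <- sensor_stream(data.frame(ax = 1, ay = 1, az = 1,
                                gx = 0, gy = 0, gz = 0)[rep(1, 10), ], fs = 50)
  expect_equal(gyro_magnitude(z), rep(0, 10))
  ## invariant to axis permutation
  s1 <- random_stream(50, seed = 1)
  perm <- as.data.frame(s1)[, c("ax", "ay", "az", "gz", "gx", "gy")]
  names(perm) <- c("ax", "ay", "az", "gx", "gy", "gz")
  expect_equal(gyro_magnitude(sensor_stream(perm, 50)), gyro_magnitude(s1))
})

test_that("fixed windows have exact length, stride and trailing discard", {
  w <- fixed_windows(5000, 50, 10, 0.25)
  expect_equal(nrow(w), 13)                       # floor((5000-500)/375)+1
  expect_equal(unique(diff(w$start_idx)), 375L)
  expect_true(all(w$end_idx - w$start_idx + 1 == 500))
  expect_true(all(w$method == "FW"))

  w0 <- fixed_windows(5000, 50, 10, 0)            # 100 s stream, no overlap
  expect_equal(nrow(w0), 10)
  expect_equal(w0$start_idx, seq(1L, 4501L, 500L))

  expect_equal(nrow(fixed_windows(499, 50, 10, 0.25)), 0)
})

test_that("dynamic windows split at the end of threshold-exceeding descents", {
  ## strictly non-decreasing: no descending run, single window
  x_up <- cumsum(abs(sin(1:500)) + 0.01)
  expect_equal(nrow(dynamic_windows(x_up)), 1)

  ## flat signal with a floor: single window
  expect_equal(nrow(dynamic_windows(rep(1, 400), floor = 0.5)), 1)

  ## hand-traced construction: small +-0.02 jitter (drops of 0.04 stay
  ## under the 0.05 floor), then a monotone drop of 10 ending at sample
  ## 320, then jitter that stays above the drop bottom. Exactly one split,
  ## at the end of the drop.
  x <- c(rep(c(0.02, -0.02), 150),                       # 1..300
         seq(-0.52, -10, length.out = 20),               # 301..320
         rep(c(-9.96, -9.92), 100))                      # 321..520
  dw <- dynamic_windows(x, N = 100, scale = 1, floor = 0.05)
  expect_equal(nrow(dw), 2)
  expect_equal(dw$end_idx[1], 320L)
  expect_equal(dw$start_idx[2], 321L)
  expect_equal(dw$end_idx[2], 520L)
})

test_that("dynamic fixed windows force boundaries every t seconds", {
  ## constant 60 s signal at 50 Hz, t = 10 s: six 500-sample windows
  w <- dynamic_fixed_windows(rep(0, 3000), fs = 50, t_s = 10)
  expect_equal(nrow(w), 6)
  expect_true(all(w$end_idx - w$start_idx + 1 == 500))

  ## single large drop at 4 s: [0, drop-end), [drop-end, 10 s), [10, 20)...
  x <- c(rep(100, 200), seq(100, 0, length.out = 20), rep(0.5, 780))
  w2 <- dynamic_fixed_windows(x, fs = 50, t_s = 10, N = 100, scale = 3,
                              floor = 0.1)
  expect_equal(w2$end_idx[1], 220L)     # end of the descent
  expect_equal(w2$end_idx[2], 500L)     # forced block boundary
  expect_equal(w2$end_idx[nrow(w2)], 1000L)
})

test_that("DW/DFW partition any signal and DFW window length is bounded", {
  withr::with_seed(42, {
    for (k in 1:8) {
      n <- sample(300:3000, 1)
      x <- cumsum(rnorm(n)) + rnorm(n) * sample(c(0.1, 5, 50), 1)
      for (w in list(dynamic_windows(x),
                     dynamic_fixed_windows(x, fs = 50, t_s = 10))) {
        expect_equal(w$start_idx[1], 1L)
        expect_equal(w$end_idx[nrow(w)], n)
        if (nrow(w) > 1) {
          expect_equal(w$start_idx[-1], w$end_idx[-nrow(w)] + 1L)
        }
        expect_true(all(w$end_idx >= w$start_idx))
      }
      expect_lte(max(with(dynamic_fixed_windows(x, fs = 50, t_s = 10),
                          end_idx - start_idx + 1)), 500)
    }
  })
})

test_that("DFW equals DW applied independently per t-block, and both match the reference scan", {
  withr::with_seed(7, {
    for (k in 1:5) {
      n <- sample(800:2600, 1)
      x <- abs(cumsum(rnorm(n, 0, 3))) + rexp(n, 1)
      ## package DFW vs per-block package DW through the public API
      dfw <- dynamic_fixed_windows(x, fs = 50, t_s = 10)
      block <- 500L
      per_block <- integer()
      b <- 1L
      while (b <= n) {
        to <- min(n, b + block - 1L)
        dwb <- dynamic_windows(x[b:to])
        per_block <- c(per_block, dwb$end_idx + b - 1L)
        b <- b + block
      }
      expect_equal(dfw$end_idx, per_block)
      ## both methods vs the independent pure-R scan
      expect_equal(as.data.frame(dynamic_windows(x)[, 1:2]),
                   ref_dw_windows(x))
      expect_equal(as.data.frame(dfw[, 1:2]), ref_dfw_windows(x, fs = 50))
    }
  })
})

test_that("DFW places a boundary shortly after each drink peak's descending flank", {
  d <- generate_day(day_plan(
    seed = 31, day_start_h = 10, day_length_h = 0.25,
    meals = tibble::tibble(start_h = numeric(), duration_min = numeric(),
                           gesture_period_s = numeric(), pre_burst = logical()),
    drinks = tibble::tibble(start_h = c(10.05, 10.12, 10.2), duration_s = 12),
    distractors = FALSE, background_kinds = "idle"))
  pp <- preprocess_stream(d$stream, intake_config())
  mag <- gyro_magnitude(pp)
  w <- dynamic_fixed_windows(mag, fs = 50, t_s = 10)
  peaks <- find_rot_peaks(mag, 60, min_sep = 50)
  expect_gte(length(peaks), 6)    # two rotational peaks per drink
  for (p in peaks) {
    ## the descending flank ends where the magnitude falls below 10 % of
    ## the peak; a window boundary must appear within 1 s after that
    fe <- p + which(mag[seq(p, min(p + 500, length(mag)))] < 0.1 * mag[p])[1] - 1
    expect_true(any(w$end_idx >= p & w$end_idx <= fe + 50),
                info = paste("no boundary within 1 s after the flank of peak at", p))
  }
})
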