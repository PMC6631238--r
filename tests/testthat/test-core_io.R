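test_that("sensor CSV round-trips at full precision", {
  s <- random_stream(100, fs = 100, seed = 3, t0 = 3600)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, f)
  expect_length(readLines(f), 101)  # header + one row per sample
  r <- read_stream_csv(f)
  expect_equal(nrow(r), 100)
  expect_equal(stream_fs(r), 100)
  expect_equal(stream_t0(r), 3600)
  expect_equal(as.data.frame(r), as.data.frame(s), tolerance = 1e-9)

  ## n = 0 stream -> header-only file
  s0 <- sensor_stream(data.frame(ax = numeric(), ay = numeric(),
                                 az = numeric(), gx = numeric(),
                                 gy = numeric(), gz = numeric()), fs = 100)
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s0, f0)
  expect_length(readLines(f0), 1)
})

test_that("malformed sensor CSVs are rejected with the offending row named", {
  s <- random_stream(10, fs = 100, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, f)

  ## NaN in ax at data row 5
  lines <- readLines(f)
  parts <- strsplit(lines[6], ",")[[1]]
  parts[2] <- "NaN"
  lines[6] <- paste(parts, collapse = ",")
  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, fbad)
  expect_error(read_stream_csv(fbad), "row 5")

  ## non-numeric cell
  lines2 <- readLines(f)
  lines2[4] <- sub("^[-0-9.e]+", "oops", lines2[4])
  fbad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines2, fbad2)
  expect_error(read_stream_csv(fbad2), "row 3")

  ## non-monotone timestamps
  lines3 <- readLines(f)
  p <- strsplit(lines3[5], ",")[[1]]; p[1] <- "0"
  lines3[5] <- paste(p, collapse = ",")
  fbad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines3, fbad3)
  expect_error(read_stream_csv(fbad3), "non-monotone")

  ## missing column
  fbad4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,ax,ay,az,gx,gy", "0,1,2,3,4,5"), fbad4)
  expect_error(read_stream_csv(fbad4), "missing column")
})

test_that("label CSV validation and round-trip behave as specified", {
  ## drink-in-eat overlap is legal
  tr <- label_track(data.frame(start_s = c(0, 30), end_s = c(60, 35),
                               label = c("eat", "drink")))
  expect_equal(nrow(tr), 2)

  f <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(tr, f)
  rt <- read_labels_csv(f)
  expect_equal(as.data.frame(rt), as.data.frame(tr))

  ## inverted interval rejected
  expect_error(label_track(data.frame(start_s = 10, end_s = 5, label = "eat")),
               "start_s < end_s")
  ## unknown label rejected
  expect_error(label_track(data.frame(start_s = 0, end_s = 1, label = "nap")),
               "unknown label")
  ## same-class overlap rejected
  expect_error(label_track(data.frame(start_s = c(0, 5), end_s = c(10, 15),
                                      label = c("eat", "eat"))),
               "illegal overlap")

  ## empty file -> empty track
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("start_s,end_s,label", f2)
  expect_equal(nrow(read_labels_csv(f2)), 0)
})

test_that("rasterization uses midpoint coverage with drink > eat precedence", {
  tr <- label_track(data.frame(start_s = 0, end_s = 600, label = "eat"))
  expect_equal(rasterize_labels(tr, 0, 10, 60), rep("eat", 60))

  ## drink [25, 32) inside the meal: only the unit whose midpoint (25 s,
  ## third unit [20, 30)) falls inside becomes drink
  tr2 <- label_track(data.frame(start_s = c(0, 25), end_s = c(600, 32),
                                label = c("eat", "drink")))
  lab <- rasterize_labels(tr2, 0, 10, 60)
  expect_equal(lab[3], "drink")
  expect_equal(lab[-3], rep("eat", 59))

  ## empty track -> all other; length always n_units
  expect_equal(rasterize_labels(label_track(), 0, 10, 7), rep("other", 7))
  withr::with_seed(11, {
    for (k in 1:5) {
      n <- sample(1:50, 1)
      iv <- data.frame(start_s = c(0, 40), end_s = c(50, 45),
                       label = c("eat", "drink"))
      lab <- rasterize_labels(label_track(iv), 0, runif(1, 1, 20), n)
      expect_length(lab, n)
      expect_true(all(lab %in% c("eat", "drink", "other")))
    }
  })
})

test_that("configuration round-trips through the flat config file", {
  cfg <- intake_config(seed = 9, min_meal_min = 4, meal_centers_h = c(7, 13, 19))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
  expect_error(intake_config(bogus_field = 1), "unknown configuration")
  expect_error(intake_config(fw_overlap = 1), "fw_overlap")
  expect_error(intake_config(dfw_t_s = -1), "positive")
})
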