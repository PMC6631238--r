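test_that("all 33 features match the brute-force oracle within 1e-9", {
  withr::with_seed(19, {
    for (k in 1:4) {
      n <- sample(c(50, 200, 500), 1)
      fs <- sample(c(50, 100), 1)
      s <- random_stream(n, fs = fs, seed = 100 + k)
      w <- tibble::tibble(start_idx = 1L, end_idx = as.integer(n),
                          method = "FW")
      got <- extract_features(s, w)
      want <- ref_features(as.matrix(as.data.frame(s)), fs)
      expect_equal(unlist(got[1, feature_names()]), want, tolerance = 1e-9)
    }
  })
})

test_that("degenerate and structured windows produce the documented values", {
  ## constant window: zero variance/haar/zcr/manipulation, corr convention 0
  cst <- sensor_stream(data.frame(ax = 1, ay = 2, az = 2,
                                  gx = 0, gy = 0, gz = 0)[rep(1, 100), ],
                       fs = 50)
  f <- extract_features(cst, tibble::tibble(start_idx = 1L, end_idx = 100L,
                                            method = "FW"))
  expect_equal(unname(unlist(f[1, paste0("var_", c("ax", "ay", "az"))])),
               rep(0, 3))
  expect_equal(unname(unlist(f[1, grep("^haar_", names(f))])), rep(0, 6))
  expect_equal(unname(unlist(f[1, grep("^zcr_", names(f))])), rep(0, 3))
  expect_equal(f$manipulation, 0)
  expect_equal(f$linear_acceleration, abs(3 - 9.80665))  # | |a| - g |
  expect_equal(unname(unlist(f[1, grep("^corr_", names(f))])), rep(0, 6))

  ## proportional axes: correlation exactly 1
  s <- random_stream(200, fs = 50, seed = 2)
  s2 <- as.data.frame(s); s2$gy <- 2 * s2$gx
  f2 <- extract_features(sensor_stream(s2, 50),
                         tibble::tibble(start_idx = 1L, end_idx = 200L,
                                        method = "FW"))
  expect_equal(f2$corr_gx_gy, 1)

  ## ramp of slope m over L samples: |haar| = m * L / 2 (haar here is
  ## first-half mean minus second-half mean, so the sign is negative)
  L <- 100; m <- 0.3
  ramp <- data.frame(ax = m * (0:(L - 1)), ay = 0, az = 0,
                     gx = 0, gy = 0, gz = 0)
  fr <- extract_features(sensor_stream(ramp, 50),
                         tibble::tibble(start_idx = 1L, end_idx = as.integer(L),
                                        method = "FW"))
  expect_equal(abs(fr$haar_ax), m * L / 2)

  ## windows of fewer than 2 samples are rejected
  expect_error(extract_features(s, tibble::tibble(start_idx = 5L,
                                                  end_idx = 5L,
                                                  method = "FW")),
               "degenerate")
})

test_that("feature scaling behaves as documented", {
  s <- random_stream(300, fs = 50, seed = 8)
  w <- tibble::tibble(start_idx = 1L, end_idx = 300L, method = "FW")
  f1 <- extract_features(s, w)
  sg <- as.data.frame(s) * 4
  f4 <- extract_features(sensor_stream(sg, 50), w)
  ## mean and haar scale linearly with gain; correlations are invariant
  expect_equal(f4$mean_gx, 4 * f1$mean_gx)
  expect_equal(f4$haar_ay, 4 * f1$haar_ay)
  expect_equal(f4$corr_gx_gy, f1$corr_gx_gy, tolerance = 1e-12)
  expect_equal(f4$var_gz, 16 * f1$var_gz)
  ## bounds on random windows
  expect_true(all(abs(unlist(f1[1, grep("^corr_", names(f1))])) <= 1))
  expect_true(all(unlist(f1[1, grep("^var_", names(f1))]) >= 0))
  expect_true(all(unlist(f1[1, grep("^zcr_", names(f1))]) >= 0))
  expect_gte(f1$rms_acc_magnitude, 0)
})

test_that("the correlation filter drops the costlier member of collinear pairs", {
  withr::with_seed(3, {
    n <- 200
    df <- tibble::tibble(
      mean_ax = rnorm(n),
      haar_ax = rnorm(n),
      zcr_gx = rnorm(n)
    )
    df$corr_ax_ay <- 2 * df$mean_ax          # collinear pair, corr_ costlier
    kept <- correlation_filter(df, names = names(df))
    expect_true("mean_ax" %in% kept)
    expect_false("corr_ax_ay" %in% kept)
    expect_setequal(kept, c("mean_ax", "haar_ax", "zcr_gx"))

    ## independent features all kept
    ind <- tibble::as_tibble(matrix(rnorm(n * 4), n, 4,
                                    dimnames = list(NULL, c("a", "b", "c", "d"))))
    expect_setequal(correlation_filter(ind, names = names(ind)), names(ind))

    ## three mutually collinear features leave exactly one survivor
    tri <- tibble::tibble(var_ax = rnorm(n))
    tri$haar_ay <- 3 * tri$var_ax
    tri$corr_gx_gy <- -1 * tri$var_ax
    kept3 <- correlation_filter(tri, names = names(tri))
    expect_length(kept3, 1)
    expect_equal(kept3, "var_ax")  # cheapest family survives the greedy order

    ## constant columns are never dropped by this rule
    cc <- tibble::tibble(a = rnorm(n), b = rep(1, n))
    expect_true("b" %in% correlation_filter(cc, names = names(cc)))
  })
})

test_that("the importance filter removes noise features and keeps informative ones", {
  withr::with_seed(4, {
    n <- 500
    eat <- rep(c(TRUE, FALSE), length.out = n)
    drink <- rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n)
    ## features informative for BOTH activities (the rule eliminates
    ## anything below threshold in at least one model, so only shared
    ## signal survives) plus one pure-noise column
    f <- as.data.frame(matrix(0, n, 0))
    for (i in 1:8) {
      f[[paste0("shared_f", i)]] <- 2 * eat + 3 * drink + rnorm(n, 0, 0.5)
    }
    f$pure_noise <- rnorm(n)
    res <- importance_filter(f, eat, drink, threshold = 0.01, seed = 11,
                             names = names(f))
    expect_false("pure_noise" %in% res$kept)
    expect_setequal(res$kept, paste0("shared_f", 1:8))
    expect_equal(sum(res$importance_eat), 1)
    expect_equal(sum(res$importance_drink), 1)

    ## threshold 0 keeps everything
    res0 <- importance_filter(f, eat, drink, threshold = 0, seed = 11,
                              names = names(f))
    expect_setequal(res0$kept, names(f))

    expect_error(importance_filter(f, rep(TRUE, n), drink, seed = 1,
                                   names = names(f)), "single-class")
  })
})

test_that("the canonical feature list has 33 unique names in family order", {
  fn <- feature_names()
  expect_length(fn, 33)
  expect_equal(anyDuplicated(fn), 0L)
  expect_equal(sum(grepl("^mean_", fn)), 6)
  expect_equal(sum(grepl("^var_", fn)), 6)
  expect_equal(sum(grepl("^haar_", fn)), 6)
  expect_equal(sum(grepl("^corr_", fn)), 6)
  expect_equal(sum(grepl("^cov_", fn)), 3)
  expect_equal(sum(grepl("^zcr_", fn)), 3)
})
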