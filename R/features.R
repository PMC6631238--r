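#' Names of the 33 time-domain features, in canonical order
#'
#' Order: per-axis means (acc x/y/z, gyro x/y/z), per-axis population
#' variances, per-axis Haar-like step responses, pairwise correlations
#' (acc xy/xz/yz, gyro xy/xz/yz), accelerometer pairwise covariances,
#' gyroscope per-axis zero-crossing rates, manipulation, linear
#' acceleration, and the RMS of the accelerometer magnitude.
#'
#' @return character vector of length 33.
#' @export
feature_names <- function() {
  ax6 <- c("ax", "ay", "az", "gx", "gy", "gz")
  c(paste0("mean_", ax6),
    paste0("var_", ax6),
    paste0("haar_", ax6),
    "corr_ax_ay", "corr_ax_az", "corr_ay_az",
    "corr_gx_gy", "corr_gx_gz", "corr_gy_gz",
    "cov_ax_ay", "cov_ax_az", "cov_ay_az",
    "zcr_gx", "zcr_gy", "zcr_gz",
    "manipulation", "linear_acceleration", "rms_acc_magnitude")
}

## population moments
pop_var <- function(x) mean(x^2) - mean(x)^2
pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)
pop_cor <- function(x, y) {
  vx <- pop_var(x); vy <- pop_var(y)
  if (vx <= 0 || vy <= 0) return(0)
  pop_cov(x, y) / sqrt(vx * vy)
}

## mean of first half minus mean of second half (single-scale Haar response)
haar_feature <- function(x) {
  h <- length(x) %/% 2
  mean(x[seq_len(h)]) - mean(x[seq(h + 1, length(x))])
}

## mean-removed sign-change count per second
zcr_feature <- function(x, fs) {
  s <- x - mean(x)
  sum(s[-length(s)] * s[-1] < 0) / (length(x) / fs)
}

feature_row <- function(mat, fs, gravity, eps) {
  acc <- mat[, 1:3, drop = FALSE]
  gyr <- mat[, 4:6, drop = FALSE]
  amag <- sqrt(rowSums(acc^2))
  means <- colMeans(mat)
  vars <- apply(mat, 2, pop_var)
  haars <- apply(mat, 2, haar_feature)
  corrs <- c(pop_cor(acc[, 1], acc[, 2]), pop_cor(acc[, 1], acc[, 3]),
             pop_cor(acc[, 2], acc[, 3]),
             pop_cor(gyr[, 1], gyr[, 2]), pop_cor(gyr[, 1], gyr[, 3]),
             pop_cor(gyr[, 2], gyr[, 3]))
  covs <- c(pop_cov(acc[, 1], acc[, 2]), pop_cov(acc[, 1], acc[, 3]),
            pop_cov(acc[, 2], acc[, 3]))
  zcrs <- c(zcr_feature(gyr[, 1], fs), zcr_feature(gyr[, 2], fs),
            zcr_feature(gyr[, 3], fs))
  manip <- mean((abs(gyr[, 1]) + abs(gyr[, 2]) + abs(gyr[, 3])) /
                  pmax(amag, eps))
  linacc <- mean(abs(amag - gravity))
  rmsa <- sqrt(mean(amag^2))
  c(means, vars, haars, corrs, covs, zcrs, manip, linacc, rmsa)
}

#' Extract the 33 time-domain features for each window
#'
#' Computes, per window: per-axis population mean and variance; a Haar-like
#' step response (mean of the first half minus mean of the second half of
#' the window); pairwise population correlations of the accelerometer and
#' gyroscope axes (defined as 0 when either axis has zero variance);
#' accelerometer pairwise population covariances; gyroscope per-axis
#' zero-crossing rates of the mean-removed signal, in crossings per second;
#' manipulation (window mean of `(|gx|+|gy|+|gz|) / max(|a|, eps)`); linear
#' acceleration (window mean of `| |a| - g |`); and the RMS of the
#' accelerometer magnitude.
#'
#' @param stream a [sensor_stream()].
#' @param windows a window tibble from one of the segmentation functions;
#'   every window must contain at least 2 samples.
#' @param gravity gravity constant (m/s^2) for the gravity-referenced
#'   features.
#' @param eps guard against division by a near-zero acceleration magnitude.
#' @return the `windows` tibble with 33 feature columns appended (see
#'   [feature_names()]).
#' @export
extract_features <- function(stream, windows, gravity = .G0, eps = 1e-6) {
  stopifnot(inherits(stream, "sensor_stream"))
  fs <- stream_fs(stream)
  mat <- stream_matrix(stream)
  n <- nrow(mat)
  if (nrow(windows) == 0) {
    empty <- matrix(numeric(), 0, 33, dimnames = list(NULL, feature_names()))
    return(bind_cols(windows, as_tibble(empty)))
  }
  if (any(windows$start_idx < 1 | windows$end_idx > n |
            windows$end_idx < windows$start_idx)) {
    abort("window indices out of stream bounds")
  }
  if (any(windows$end_idx - windows$start_idx + 1 < 2)) {
    abort("degenerate window: every window needs >= 2 samples")
  }
  feats <- t(vapply(seq_len(nrow(windows)), function(i) {
    feature_row(mat[windows$start_idx[i]:windows$end_idx[i], , drop = FALSE],
                fs, gravity, eps)
  }, numeric(33)))
  colnames(feats) <- feature_names()
  bind_cols(windows, as_tibble(feats))
}

feature_columns <- function(df) {
  as.matrix(df[, intersect(feature_names(), names(df)), drop = FALSE])
}
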