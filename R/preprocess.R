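#' Downsample a stream by an integer factor
#'
#' Keeps every `factor`-th sample starting at the first one; the sample
#' rate is divided accordingly. The default factor of 2 takes the raw
#' 100 Hz acquisition down to the 50 Hz working rate.
#'
#' @param stream a [sensor_stream()].
#' @param factor integer >= 1.
#' @return a [sensor_stream()] with `ceiling(n / factor)` samples.
#' @export
downsample <- function(stream, factor = 2) {
  stopifnot(inherits(stream, "sensor_stream"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) abort("factor must be an integer >= 1")
  if (factor == 1) return(stream)
  keep <- seq(1, nrow(stream), by = factor)
  new_stream_like(stream_matrix(stream)[keep, , drop = FALSE],
                  fs = stream_fs(stream) / factor, t0 = stream_t0(stream))
}

#' Causal Butterworth low-pass filter
#'
#' Filters every channel with a single forward pass of a Butterworth
#' low-pass design (DC gain 1), so the output at sample `i` depends only on
#' samples `<= i` -- the filter is usable online.
#'
#' @param stream a [sensor_stream()].
#' @param cutoff_hz cutoff frequency, `0 < cutoff_hz < fs/2`.
#' @param order filter order.
#' @return a filtered [sensor_stream()].
#' @export
lowpass <- function(stream, cutoff_hz = 5, order = 4) {
  stopifnot(inherits(stream, "sensor_stream"))
  fs <- stream_fs(stream)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff_hz must lie in (0, fs/2) = (0, %g)", fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  mat <- stream_matrix(stream)
  out <- apply(mat, 2, function(x) as.numeric(signal::filter(bf, x)))
  new_stream_like(out, fs = fs, t0 = stream_t0(stream))
}

## causal half-Gaussian kernel, truncated at 3 sigma, normalized to sum 1
half_gaussian_kernel <- function(sigma_s, fs) {
  k <- ceiling(3 * sigma_s * fs)
  w <- exp(-((0:k) / (sigma_s * fs))^2 / 2)
  w / sum(w)
}

#' Causal half-Gaussian smoothing
#'
#' Convolves each channel with the past-facing half of a Gaussian kernel
#' (weights normalized to sum 1, truncated at 3 sigma). Output at sample
#' `i` depends only on samples `<= i`; for the first samples the truncated
#' kernel is renormalized over the available history, so a constant signal
#' is left unchanged everywhere.
#'
#' @param stream a [sensor_stream()].
#' @param sigma_s kernel standard deviation in seconds (> 0).
#' @return a smoothed [sensor_stream()].
#' @export
half_gaussian_smooth <- function(stream, sigma_s = 0.5) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is.numeric(sigma_s) || sigma_s <= 0) abort("sigma_s must be > 0")
  fs <- stream_fs(stream)
  w <- half_gaussian_kernel(sigma_s, fs)
  k <- length(w) - 1
  mat <- stream_matrix(stream)
  out <- apply(mat, 2, function(x) {
    y <- as.numeric(stats::filter(x, w, method = "convolution", sides = 1))
    head_n <- min(k, length(x))
    for (i in seq_len(head_n)) {
      wi <- w[seq_len(i)]
      y[i] <- sum(wi * x[i:1]) / sum(wi)
    }
    y
  })
  new_stream_like(out, fs = fs, t0 = stream_t0(stream))
}

#' Full preprocessing pipeline
#'
#' Runs the conditioning chain in order: integer downsampling to the
#' working rate, causal Butterworth low-pass, causal half-Gaussian
#' smoothing. Every step is causal so the chain is usable online.
#'
#' @param stream a raw [sensor_stream()].
#' @param config an [intake_config()].
#' @return a conditioned [sensor_stream()] at `config$fs_target`.
#' @export
preprocess_stream <- function(stream, config = intake_config()) {
  factor <- round(stream_fs(stream) / config$fs_target)
  if (factor < 1) factor <- 1
  stream %>%
    downsample(factor) %>%
    lowpass(config$lowpass_cutoff_hz, config$lowpass_order) %>%
    half_gaussian_smooth(config$smooth_sigma_s)
}
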