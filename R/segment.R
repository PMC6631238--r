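#' Gyroscope rotational magnitude
#'
#' Per-sample Euclidean norm of the three gyroscope channels (deg/s). This
#' is the input signal of both dynamic segmentation methods.
#'
#' @param stream a [sensor_stream()].
#' @return numeric vector of length `nrow(stream)`.
#' @export
gyro_magnitude <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  sqrt(stream$gx^2 + stream$gy^2 + stream$gz^2)
}

new_windows <- function(start, end, method) {
  tibble(start_idx = as.integer(start), end_idx = as.integer(end),
         method = method)
}

#' Fixed-length overlapping windows (FW)
#'
#' Windows of exactly `length_s * fs` samples with stride
#' `round(length_s * fs * (1 - overlap))`; a trailing partial window is
#' discarded. Indices are 1-based and inclusive, so a window covers samples
#' `start_idx:end_idx` with `end_idx - start_idx + 1` equal to the window
#' length.
#'
#' @param n number of samples in the stream.
#' @param fs sample rate (Hz).
#' @param length_s window length in seconds (default 10).
#' @param overlap overlap fraction in `[0, 1)` (default 0.25).
#' @return a tibble of windows (`start_idx`, `end_idx`, `method = "FW"`);
#'   empty when the stream is shorter than one window.
#' @export
#' @examples
#' nrow(fixed_windows(5000, 50))  # 13 windows, stride 375
fixed_windows <- function(n, fs, length_s = 10, overlap = 0.25) {
  len <- round(length_s * fs)
  if (len < 1) abort("length_s * fs must be >= 1")
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  n <- as.integer(n)
  if (n < len) return(new_windows(integer(), integer(), character()))
  stride <- max(1L, as.integer(round(len * (1 - overlap))))
  starts <- seq(1L, n - len + 1L, by = stride)
  new_windows(starts, starts + len - 1L, "FW")
}

#' Dynamic windows (DW)
#'
#' Scans the signal left to right maintaining the current maximal
#' descending run. A run restarts whenever the signal rises more than
#' `floor` above its running minimum. When the run's drop (max - min)
#' exceeds the dynamic threshold
#' `theta(i) = max(floor, scale * robust sd(previous N samples))`, a
#' window boundary is placed at the end of the descent (the run minimum).
#' A final window covers any tail, so the windows partition the signal
#' exactly. Until `N` samples of history exist, `theta = floor`.
#'
#' The history dispersion is the robust standard deviation
#' `1.4826 * MAD`: identical to the plain standard deviation under
#' Gaussian background noise, but insensitive to a gesture transient
#' inside the history window -- a transient must not inflate the very
#' threshold that is supposed to detect it.
#'
#' @param signal numeric vector (typically [gyro_magnitude()]).
#' @param N history length in samples (default 100, i.e. 2 s at 50 Hz).
#' @param scale multiplier on the robust history dispersion (default 3).
#' @param floor threshold floor in signal units (default 0.1 deg/s).
#' @return a tibble of windows (`method = "DW"`).
#' @export
dynamic_windows <- function(signal, N = 100, scale = 3, floor = 0.1) {
  check_dw_params(N, scale, floor)
  ends <- dw_scan_cpp(as.numeric(signal), as.integer(N), scale, floor, 0L)
  ends_to_windows(ends, "DW")
}

#' Dynamic fixed windows (DFW)
#'
#' Dynamic windowing with a forced boundary -- and a full reset of the
#' descending-run state and threshold history -- every `t_s` seconds. Each
#' `t_s` block is segmented independently with the [dynamic_windows()]
#' logic, so no window is ever longer than `t_s * fs` samples and within a
#' block `theta = floor` until `N` samples accrue.
#'
#' @inheritParams dynamic_windows
#' @param fs sample rate of the signal (Hz).
#' @param t_s reset period in seconds (default 10).
#' @return a tibble of windows (`method = "DFW"`).
#' @export
dynamic_fixed_windows <- function(signal, fs, t_s = 10, N = 100, scale = 3,
                                  floor = 0.1) {
  check_dw_params(N, scale, floor)
  if (t_s <= 0) abort("t_s must be > 0")
  block <- as.integer(round(t_s * fs))
  if (block < 1) abort("t_s * fs must be >= 1")
  ends <- dw_scan_cpp(as.numeric(signal), as.integer(N), scale, floor, block)
  ends_to_windows(ends, "DFW")
}

check_dw_params <- function(N, scale, floor) {
  if (N < 2) abort("N must be >= 2")
  if (scale <= 0) abort("scale must be > 0")
  if (floor < 0) abort("floor must be >= 0")
  invisible(TRUE)
}

## 0-based exclusive ends -> 1-based inclusive window tibble
ends_to_windows <- function(ends, method) {
  if (length(ends) == 0) return(new_windows(integer(), integer(), character()))
  starts <- c(0L, ends[-length(ends)]) + 1L
  new_windows(starts, ends, method)
}

#' Segment a stream with one of the three windowing methods
#'
#' Convenience dispatcher used by the command-line tool: `"fw"` windows the
#' sample grid directly; `"dw"` and `"dfw"` segment the gyroscope
#' rotational magnitude.
#'
#' @param stream a [sensor_stream()].
#' @param method one of `"fw"`, `"dw"`, `"dfw"`.
#' @param config an [intake_config()].
#' @return a tibble of windows.
#' @export
segment_stream <- function(stream, method = c("fw", "dw", "dfw"),
                           config = intake_config()) {
  method <- match.arg(method)
  fs <- stream_fs(stream)
  switch(method,
    fw = fixed_windows(nrow(stream), fs, config$fw_length_s, config$fw_overlap),
    dw = dynamic_windows(gyro_magnitude(stream), config$dw_N,
                         config$dw_scale, config$dw_floor),
    dfw = dynamic_fixed_windows(gyro_magnitude(stream), fs, config$dfw_t_s,
                                config$dw_N, config$dw_scale, config$dw_floor)
  )
}
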