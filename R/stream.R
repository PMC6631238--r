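#' Sensor streams
#'
#' A sensor stream is a tibble with one row per sample and six channel
#' columns -- `ax, ay, az` (accelerometer, m/s^2) and `gx, gy, gz`
#' (gyroscope, deg/s) -- carrying the sample rate `fs` (Hz) and the
#' absolute start time of day `t0` (seconds since midnight) as attributes.
#' Sample `i` (1-based) covers the half-open interval
#' `[t0 + (i-1)/fs, t0 + i/fs)`.
#'
#' @param data a data frame with numeric columns `ax, ay, az, gx, gy, gz`.
#' @param fs sample rate in Hz (> 0).
#' @param t0 start time of day in seconds since midnight.
#' @return a tibble of class `"sensor_stream"`.
#' @export
#' @examples
#' s <- sensor_stream(data.frame(ax = 0, ay = 0, az = 9.81,
#'                               gx = 0, gy = 0, gz = 0), fs = 100)
#' stream_fs(s)
sensor_stream <- function(data, fs, t0 = 0) {
  chans <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(chans, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing channel column(s): ", paste(missing, collapse = ", ")))
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("fs must be a single positive number")
  }
  x <- as_tibble(data[, chans])
  for (ch in chans) {
    if (!is.numeric(x[[ch]])) abort(paste0("channel ", ch, " is not numeric"))
    bad <- which(!is.finite(x[[ch]]))
    if (length(bad) > 0) {
      abort(paste0("non-finite value in channel ", ch, " at row ", bad[1]))
    }
  }
  structure(x, fs = as.numeric(fs), t0 = as.numeric(t0),
            class = c("sensor_stream", class(x)))
}

#' @rdname sensor_stream
#' @param stream a `sensor_stream`.
#' @export
stream_fs <- function(stream) attr(stream, "fs")

#' @rdname sensor_stream
#' @export
stream_t0 <- function(stream) attr(stream, "t0")

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples @ %g Hz, t0 = %gs (%.2f h of day)\n",
              nrow(x), stream_fs(x), stream_t0(x), stream_t0(x) / 3600))
  NextMethod()
}

## rebuild a stream from a channel matrix, keeping bookkeeping
new_stream_like <- function(mat, fs, t0) {
  colnames(mat) <- c("ax", "ay", "az", "gx", "gy", "gz")
  sensor_stream(as_tibble(mat), fs = fs, t0 = t0)
}

stream_matrix <- function(stream) {
  as.matrix(stream[, c("ax", "ay", "az", "gx", "gy", "gz")])
}

#' Read and write sensor CSV files
#'
#' The on-disk format is a header line `timestamp,ax,ay,az,gx,gy,gz`
#' followed by one numeric row per sample; `timestamp` is seconds since
#' midnight and must be strictly increasing. Values are written at full
#' double precision so that `read_stream_csv(write_stream_csv(s))`
#' round-trips exactly.
#'
#' @param path CSV file path.
#' @param fs sample rate; inferred from the median timestamp step when NULL.
#' @param t0 start time of day; taken from the first timestamp when NULL.
#' @return `read_stream_csv()` a [sensor_stream()]; `write_stream_csv()`
#'   the path, invisibly.
#' @export
read_stream_csv <- function(path, fs = NULL, t0 = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- c("timestamp", "ax", "ay", "az", "gx", "gy", "gz")
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    ## readr counts the header line, so data row = reported row - 1
    abort(sprintf("%s: non-numeric value at data row %d, column %d",
                  path, probs$row[1] - 1L, probs$col[1]))
  }
  for (ch in cols) {
    bad <- which(!is.finite(df[[ch]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-finite value in column %s at data row %d",
                    path, ch, bad[1]))
    }
  }
  ts <- df$timestamp
  if (nrow(df) >= 2) {
    nonmono <- which(diff(ts) <= 0)
    if (length(nonmono) > 0) {
      abort(sprintf("%s: non-monotone timestamp at data row %d",
                    path, nonmono[1] + 1L))
    }
  }
  if (is.null(fs)) {
    fs <- if (nrow(df) >= 2) 1 / median(diff(ts)) else 1
  }
  if (is.null(t0)) t0 <- if (nrow(df) >= 1) ts[1] else 0
  sensor_stream(df[, c("ax", "ay", "az", "gx", "gy", "gz")], fs = fs, t0 = t0)
}

#' @rdname read_stream_csv
#' @param stream a [sensor_stream()].
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- nrow(stream)
  out <- bind_cols(
    tibble(timestamp = stream_t0(stream) + seq_len(n) / stream_fs(stream) -
             1 / stream_fs(stream)),
    as_tibble(stream)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

## ---- labels ----------------------------------------------------------------

.CLASSES <- c("eat", "drink", "other")

#' Labeled activity intervals
#'
#' A label track is a tibble of half-open intervals `[start_s, end_s)` in
#' seconds since midnight with a `label` column in `{eat, drink, other}`,
#' sorted by start. Overlaps are permitted only between a drink and an eat
#' interval (a sip during a meal); on any overlap, rasterization precedence
#' is drink > eat > other.
#'
#' @param data a data frame with columns `start_s`, `end_s`, `label`.
#' @return a tibble of class `"label_track"`.
#' @export
label_track <- function(data = NULL) {
  if (is.null(data) || nrow(data) == 0) {
    x <- tibble(start_s = numeric(), end_s = numeric(), label = character())
    return(structure(x, class = c("label_track", class(x))))
  }
  need <- c("start_s", "end_s", "label")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing label column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(data[, need])
  bad <- which(!(x$label %in% .CLASSES))
  if (length(bad) > 0) {
    abort(sprintf("unknown label '%s' at interval %d (allowed: %s)",
                  x$label[bad[1]], bad[1], paste(.CLASSES, collapse = ", ")))
  }
  bad <- which(!(x$start_s >= 0 & x$end_s > x$start_s))
  if (length(bad) > 0) {
    abort(sprintf("invalid interval %d: require 0 <= start_s < end_s (got %g, %g)",
                  bad[1], x$start_s[bad[1]], x$end_s[bad[1]]))
  }
  x <- arrange(x, .data$start_s, .data$end_s)
  ## overlaps legal only between drink and eat
  if (nrow(x) >= 2) {
    for (i in seq_len(nrow(x) - 1)) {
      j <- which(x$start_s[seq(i + 1, nrow(x))] < x$end_s[i]) + i
      for (k in j) {
        pair <- sort(c(x$label[i], x$label[k]))
        if (!identical(pair, c("drink", "eat"))) {
          abort(sprintf(
            "illegal overlap between interval %d (%s) and %d (%s)",
            i, x$label[i], k, x$label[k]))
        }
      }
    }
  }
  structure(x, class = c("label_track", class(x)))
}

#' Read and write label CSV files
#'
#' Columns `start_s,end_s,label`; see [label_track()] for validation rules.
#'
#' @param path CSV file path.
#' @return `read_labels_csv()` a [label_track()]; `write_labels_csv()` the
#'   path, invisibly.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    start_s = readr::col_double(),
    end_s = readr::col_double(),
    label = readr::col_character()
  ), progress = FALSE)
  label_track(df)
}

#' @rdname read_labels_csv
#' @param track a [label_track()].
#' @export
write_labels_csv <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  readr::write_csv(as_tibble(track), path, progress = FALSE)
  invisible(path)
}

#' Rasterize a label track onto a regular grid
#'
#' Each grid unit takes the label of the interval covering its midpoint,
#' with precedence drink > eat > other on overlap; uncovered units are
#' `"other"`. Unit `i` (1-based) covers
#' `[t0 + (i-1)*unit_s, t0 + i*unit_s)`.
#'
#' @param track a [label_track()].
#' @param t0 grid start, seconds since midnight.
#' @param unit_s unit duration in seconds (> 0).
#' @param n_units number of units.
#' @return character vector of length `n_units`.
#' @export
#' @examples
#' tr <- label_track(data.frame(start_s = 0, end_s = 600, label = "eat"))
#' table(rasterize_labels(tr, 0, 10, 60))
rasterize_labels <- function(track, t0, unit_s, n_units) {
  stopifnot(inherits(track, "label_track"))
  if (unit_s <= 0) abort("unit_s must be > 0")
  n_units <- as.integer(n_units)
  mid <- t0 + (seq_len(n_units) - 0.5) * unit_s
  out <- rep("other", n_units)
  for (lab in c("eat", "drink")) {  # drink applied last => precedence
    iv <- track[track$label == lab, , drop = FALSE]
    if (nrow(iv) == 0) next
    hit <- rep(FALSE, n_units)
    for (r in seq_len(nrow(iv))) {
      hit <- hit | (mid >= iv$start_s[r] & mid < iv$end_s[r])
    }
    out[hit] <- lab
  }
  out
}
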