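#' Pipeline configuration
#'
#' Builds the flat configuration object used by every stage of the
#' recognition pipeline. All durations are in seconds, rates in Hz and
#' times of day in hours unless stated otherwise. Defaults reproduce the
#' reference pipeline: 50 Hz working rate, 10 s eating windows, dynamic
#' fixed windows reset every 10 s for drinking, three meal-probability
#' Gaussians centred at 08:00, 12:30 and 20:00 with sigma 1.5 h, a 5 min
#' minimum meal duration, and a 60 deg/s rotational-peak drink filter.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Fields:
#' \describe{
#'   \item{fs_target}{working sample rate after downsampling (Hz, 50).}
#'   \item{lowpass_cutoff_hz, lowpass_order}{causal Butterworth low-pass
#'     (5 Hz, order 4).}
#'   \item{smooth_sigma_s}{half-Gaussian smoothing sigma (0.2 s, truncated
#'     at 3 sigma) -- strong enough to kill sensor noise, short enough not
#'     to flatten a quick wrist rotation.}
#'   \item{fw_length_s, fw_overlap}{fixed-window length (10 s) and the
#'     overlap fraction used when building training windows (0.25).
#'     Inference runs the eating branch on non-overlapping 10 s windows so
#'     six windows make exactly one minute.}
#'   \item{dw_N, dw_scale, dw_floor}{dynamic-window history length in
#'     samples (100 = 2 s at 50 Hz), threshold multiplier on the robust
#'     history dispersion (3.0) and threshold floor (0.1 deg/s).}
#'   \item{dfw_t_s}{forced split / threshold reset period of the dynamic
#'     fixed windows (10 s).}
#'   \item{smoothing_N}{number of previous windows in the meal-probability
#'     fusion (3).}
#'   \item{meal_centers_h, meal_sigma_h, meal_threshold}{time-of-day meal
#'     probability profile: Gaussian centres (8, 12.5, 20 h), common sigma
#'     (1.5 h) and the decision threshold on the fused probability (0.5).}
#'   \item{min_meal_min}{minimum meal duration in minutes (5).}
#'   \item{peak_thresh, peak_min_sep_s}{rotational-magnitude peak filter for
#'     drink windows: height threshold (60 deg/s) and minimum peak
#'     separation (0.25 s).}
#'   \item{energy_win_s, energy_lookback_s, energy_k, use_E3}{pre-meal
#'     acceleration-energy restriction; disabled by default.}
#'   \item{drink_match_tol_s}{tolerance for event-based drink matching
#'     (10 s).}
#'   \item{n_trees, smote_k, enn_k, drink_neg_ratio}{classifier settings:
#'     forest size (100), SMOTE neighbours (5), ENN neighbours (3), and the
#'     curated non-drinking:drinking window ratio of the drinking training
#'     set (3.5).}
#'   \item{gravity}{gravity constant used by gravity-referenced features
#'     (9.80665 m/s^2).}
#'   \item{seed}{integer seed from which all pipeline randomness flows.}
#' }
#'
#' @return a list with class `"intake_config"`.
#' @export
#' @examples
#' cfg <- intake_config(seed = 7, min_meal_min = 4)
#' cfg$fs_target
intake_config <- function(...) {
  cfg <- list(
    fs_raw = 100,
    fs_target = 50,
    downsample_factor = 2,
    lowpass_cutoff_hz = 5,
    lowpass_order = 4,
    smooth_sigma_s = 0.2,
    fw_length_s = 10,
    fw_overlap = 0.25,
    dw_N = 100L,
    dw_scale = 3.0,
    dw_floor = 0.1,
    dfw_t_s = 10,
    smoothing_N = 3L,
    meal_centers_h = c(8.0, 12.5, 20.0),
    meal_sigma_h = 1.5,
    meal_threshold = 0.5,
    min_meal_min = 5,
    peak_thresh = 60,
    peak_min_sep_s = 0.25,
    energy_win_s = 10,
    energy_lookback_s = 120,
    energy_k = 3,
    use_E3 = FALSE,
    drink_match_tol_s = 10,
    n_trees = 100L,
    smote_k = 5L,
    enn_k = 3L,
    drink_neg_ratio = 3.5,
    gravity = .G0,
    eps = 1e-6,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "intake_config")
}

validate_config <- function(cfg) {
  pos <- c("fs_raw", "fs_target", "lowpass_cutoff_hz", "lowpass_order",
           "smooth_sigma_s", "fw_length_s", "dfw_t_s", "min_meal_min",
           "peak_thresh", "peak_min_sep_s", "energy_win_s",
           "energy_lookback_s", "energy_k", "drink_match_tol_s",
           "meal_sigma_h", "dw_scale")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      abort(paste0("configuration field '", f, "' must be a positive number"))
    }
  }
  if (cfg$fw_overlap < 0 || cfg$fw_overlap >= 1) {
    abort("fw_overlap must lie in [0, 1)")
  }
  if (cfg$dw_N < 2) abort("dw_N must be >= 2")
  if (cfg$dw_floor < 0) abort("dw_floor must be >= 0")
  if (length(cfg$meal_centers_h) < 1 ||
      any(cfg$meal_centers_h < 0 | cfg$meal_centers_h >= 24)) {
    abort("meal_centers_h must be hours of day in [0, 24)")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as a flat key-value text file (YAML scalar
#' mapping); vector fields such as `meal_centers_h` are comma-separated.
#'
#' @param path file path.
#' @param cfg an [intake_config()] object.
#' @return `read_config()` an `intake_config`; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  vec_fields <- "meal_centers_h"
  for (f in intersect(vec_fields, names(raw))) {
    if (is.character(raw[[f]])) {
      raw[[f]] <- as.numeric(strsplit(raw[[f]], ",")[[1]])
    } else {
      raw[[f]] <- as.numeric(raw[[f]])
    }
  }
  do.call(intake_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "intake_config"))
  flat <- unclass(cfg)
  flat$meal_centers_h <- paste(flat$meal_centers_h, collapse = ",")
  yaml::write_yaml(flat, path)
  invisible(path)
}
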