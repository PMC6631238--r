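#' Train one binary recognition branch
#'
#' Balances the training windows with [balance_classes()] (SMOTE + ENN)
#' and fits a probability random forest. The positive class is `"eat"` for
#' the eating branch and `"drink"` for the drinking branch; anything else
#' is `"rest"`.
#'
#' @param features data frame holding the feature columns (extra window
#'   bookkeeping columns are ignored).
#' @param labels character vector of window labels, one per row; windows
#'   whose label equals the branch class are the positives.
#' @param branch `"eat"` or `"drink"`.
#' @param config an [intake_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `"intake_branch"` with the fitted forest,
#'   the feature-name list and training metadata.
#' @export
train_branch <- function(features, labels, branch = c("eat", "drink"),
                         config = intake_config(), seed = config$seed) {
  branch <- match.arg(branch)
  fnames <- intersect(feature_names(), colnames(features))
  if (length(fnames) == 0) abort("no feature columns found")
  y <- ifelse(labels == branch, branch, "rest")
  if (length(unique(y)) < 2) {
    abort(sprintf("training data contains a single class for branch '%s'", branch))
  }
  bal <- balance_classes(features[, fnames, drop = FALSE], y, seed = seed,
                         k_smote = config$smote_k, k_enn = config$enn_k)
  df <- as.data.frame(bal$x)
  df$.y <- factor(bal$y, levels = c(branch, "rest"))
  fit <- ranger::ranger(.y ~ ., data = df, num.trees = config$n_trees,
                        probability = TRUE, seed = seed, num.threads = 1)
  structure(list(
    branch = branch,
    fit = fit,
    feature_names = fnames,
    seed = seed,
    counts_before = bal$counts_before,
    counts_after = bal$counts_after
  ), class = "intake_branch")
}

#' Positive-class probabilities from a trained branch
#'
#' @param model an `"intake_branch"` from [train_branch()].
#' @param features data frame containing the model's feature columns.
#' @return numeric vector of probabilities of the branch's positive class,
#'   one per row, in `[0, 1]`.
#' @export
predict_branch <- function(model, features) {
  stopifnot(inherits(model, "intake_branch"))
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing) > 0) {
    abort(paste0("feature column(s) missing from new data: ",
                 paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(features[, model$feature_names, drop = FALSE])
  p <- stats::predict(model$fit, data = df, num.threads = 1)$predictions
  as.numeric(p[, model$branch])
}

#' @export
print.intake_branch <- function(x, ...) {
  cat(sprintf("<intake_branch> %s vs rest: %d trees on %d features\n",
              x$branch, x$fit$num.trees, length(x$feature_names)))
  cat("  training windows (before balancing): ",
      paste(names(x$counts_before), x$counts_before, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.intake_branch <- function(x, ...) {
  tibble(branch = x$branch,
         term = x$feature_names)
}

#' @export
glance.intake_branch <- function(x, ...) {
  tibble(branch = x$branch,
         num_trees = x$fit$num.trees,
         n_features = length(x$feature_names),
         oob_brier = x$fit$prediction.error,
         n_pos_before = unname(x$counts_before[x$branch]),
         n_rest_before = unname(x$counts_before["rest"]),
         n_pos_after = unname(x$counts_after[x$branch]),
         n_rest_after = unname(x$counts_after["rest"]),
         seed = x$seed)
}

#' Run both recognition branches over a preprocessed stream
#'
#' The eating branch windows the stream with non-overlapping 10 s fixed
#' windows and scores each with the eating forest; the drinking branch
#' segments the gyroscope rotational magnitude with dynamic fixed windows
#' (reset every 10 s) and scores each window with the drinking forest. No
#' daily-evidence restriction is applied here -- see
#' [apply_restrictions()].
#'
#' @param stream a preprocessed [sensor_stream()] at the working rate.
#' @param eat_model,drink_model `"intake_branch"` models.
#' @param config an [intake_config()].
#' @return an object of class `"prediction_timeline"`: a list with the
#'   per-window tibbles `eat` and `drink` (window spans in samples and
#'   seconds plus positive-class probability `p`), the gyroscope magnitude
#'   signal, and stream bookkeeping.
#' @export
run_semi_hierarchical <- function(stream, eat_model, drink_model,
                                  config = intake_config()) {
  stopifnot(inherits(stream, "sensor_stream"))
  fs <- stream_fs(stream)
  t0 <- stream_t0(stream)
  n <- nrow(stream)
  fw <- fixed_windows(n, fs, config$fw_length_s, overlap = 0)
  if (nrow(fw) == 0) abort("stream shorter than one fixed window")
  eat_feats <- extract_features(stream, fw, config$gravity, config$eps)
  eat <- fw %>%
    mutate(start_s = t0 + (.data$start_idx - 1) / fs,
           end_s = t0 + .data$end_idx / fs,
           p = predict_branch(eat_model, eat_feats))

  mag <- gyro_magnitude(stream)
  dfw <- dynamic_fixed_windows(mag, fs, config$dfw_t_s, config$dw_N,
                               config$dw_scale, config$dw_floor)
  dfw <- filter(dfw, .data$end_idx - .data$start_idx + 1 >= 2)
  drink_feats <- extract_features(stream, dfw, config$gravity, config$eps)
  drink <- dfw %>%
    mutate(start_s = t0 + (.data$start_idx - 1) / fs,
           end_s = t0 + .data$end_idx / fs,
           p = predict_branch(drink_model, drink_feats))

  structure(list(
    eat = eat,
    drink = drink,
    gyro_mag = mag,
    fs = fs, t0 = t0, n = n,
    config = config
  ), class = "prediction_timeline")
}

#' @export
print.prediction_timeline <- function(x, ...) {
  cat(sprintf(
    "<prediction_timeline> %.2f h of stream @ %g Hz: %d eating windows, %d drinking windows\n",
    x$n / x$fs / 3600, x$fs, nrow(x$eat), nrow(x$drink)))
  invisible(x)
}

#' @export
tidy.prediction_timeline <- function(x, ...) {
  bind_rows(
    mutate(x$eat, branch = "eat"),
    mutate(x$drink, branch = "drink")
  ) %>%
    select("branch", "method", "start_idx", "end_idx", "start_s", "end_s", "p")
}
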