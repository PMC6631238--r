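#' Confusion matrix of per-unit labels
#'
#' @param truth,pred equal-length label vectors.
#' @param classes class vocabulary (row/column order); rows are truth,
#'   columns predictions.
#' @return an integer matrix with `classes` as dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes = c("eat", "drink", "other")) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad) > 0) {
    abort(paste0("label(s) outside class vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- unclass(m)
  dimnames(m) <- list(truth = classes, pred = classes)
  m
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per-class precision = diagonal / column sum, recall = diagonal / row
#' sum, F1 = harmonic mean; any 0/0 is defined as 0. Weighted averages are
#' weighted by the row totals (class supports).
#'
#' @param m a square confusion matrix (rows truth, columns predictions).
#' @return tibble with one row per class plus a final `"weighted"` row;
#'   columns `class`, `support`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' m <- matrix(c(150, 0, 66, 5, 24, 11, 79, 10, 5380), 3, byrow = TRUE,
#'             dimnames = list(c("eat", "drink", "other"),
#'                             c("eat", "drink", "other")))
#' prf_metrics(m)
prf_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("confusion matrix must be square")
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(diag(m), colSums(m))
  rec <- safe_div(diag(m), rowSums(m))
  f1 <- safe_div(2 * prec * rec, prec + rec)
  sup <- rowSums(m)
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(m)))
  w <- if (sum(sup) == 0) rep(0, 3) else {
    c(sum(prec * sup), sum(rec * sup), sum(f1 * sup)) / sum(sup)
  }
  bind_rows(
    tibble(class = cls, support = as.numeric(sup),
           precision = unname(prec), recall = unname(rec), f1 = unname(f1)),
    tibble(class = "weighted", support = sum(sup),
           precision = w[1], recall = w[2], f1 = w[3])
  )
}

#' Sensitivity, specificity and false positives per hour
#'
#' Treats `positive_class` against everything else. FP/h is the number of
#' false-positive units divided by the acquisition duration in hours; the
#' unit is whatever grid the labels live on (minutes for eating, 10 s
#' units or events for drinking).
#'
#' @param truth,pred equal-length label vectors.
#' @param positive_class the class scored as positive.
#' @param hours acquisition duration in hours (> 0).
#' @return tibble with `sensitivity`, `specificity`, `fp_per_hour`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec_fph <- function(truth, pred, positive_class, hours) {
  if (hours <= 0) abort("hours must be > 0")
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  tp <- sum(truth == positive_class & pred == positive_class)
  fn <- sum(truth == positive_class & pred != positive_class)
  fp <- sum(truth != positive_class & pred == positive_class)
  tn <- sum(truth != positive_class & pred != positive_class)
  safe <- function(a, b) if (b == 0) 0 else a / b
  tibble(sensitivity = safe(tp, tp + fn),
         specificity = safe(tn, tn + fp),
         fp_per_hour = fp / hours,
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Tolerance-based matching of drink events
#'
#' Greedy one-to-one matching in time order: each predicted event is
#' matched to the earliest unmatched true event lying within `tol_s`
#' (interval gap; overlapping intervals have gap 0). Matched pairs are
#' true positives; unmatched predictions false positives; unmatched truths
#' false negatives.
#'
#' @param pred_events,true_events tibbles with `start_s`, `end_s`, sorted
#'   or not (they are sorted internally).
#' @param tol_s matching tolerance in seconds (default 10).
#' @return tibble with `tp`, `fp`, `fn`.
#' @export
match_drink_events <- function(pred_events, true_events, tol_s = 10) {
  p <- arrange(as_tibble(pred_events), .data$start_s)
  tr <- arrange(as_tibble(true_events), .data$start_s)
  matched <- rep(FALSE, nrow(tr))
  tp <- 0L
  for (i in seq_len(nrow(p))) {
    if (nrow(tr) == 0) break
    gap <- pmax(0, pmax(p$start_s[i], tr$start_s) -
                  pmin(p$end_s[i], tr$end_s))
    ok <- which(!matched & gap <= tol_s)
    if (length(ok) > 0) {
      matched[ok[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble(tp = tp, fp = nrow(p) - tp, fn = nrow(tr) - tp)
}

#' Evaluate fused predictions against a ground-truth label track
#'
#' Scores a day the way the recognition pipeline is reported: eating on
#' the 1-minute grid (binary eat vs not-eat, with FP/h in minutes per
#' hour), drinking on the 10 s grid and as tolerance-matched events, and
#' the 3-class problem on the 10 s grid, with predicted minute labels
#' broadcast to their six 10 s units and drink events taking precedence.
#'
#' @param predictions an `"intake_predictions"` from
#'   [apply_restrictions()].
#' @param truth a [label_track()].
#' @param config an [intake_config()].
#' @return an object of class `"intake_eval"`: confusion matrices
#'   (`overall`, `eating`, `drinking`), per-class and weighted metrics,
#'   sensitivity/specificity/FP-per-hour rows for both activities, and the
#'   drink-event match counts.
#' @export
evaluate_predictions <- function(predictions, truth,
                                 config = intake_config()) {
  stopifnot(inherits(predictions, "intake_predictions"),
            inherits(truth, "label_track"))
  t0 <- predictions$t0
  dur <- predictions$duration_s
  hours <- dur / 3600

  ## 10 s grid
  n10 <- ceiling(dur / 10)
  truth10 <- rasterize_labels(truth, t0, 10, n10)
  pred10 <- predictions$units$label[seq_len(n10)]

  ## minute grid (eat binary)
  nmin <- ceiling(dur / 60)
  truth_min <- rasterize_labels(truth, t0, 60, nmin)
  truth_min_eat <- ifelse(truth_min == "eat", "eat", "not_eat")
  pred_min_eat <- ifelse(
    seq_len(nmin) %in% which(vapply(seq_len(nmin), function(j) {
      mid <- t0 + (j - 0.5) * 60
      nrow(predictions$meals) > 0 &&
        any(mid >= predictions$meals$start_s & mid < predictions$meals$end_s)
    }, logical(1))), "eat", "not_eat")

  overall_cm <- confusion_matrix(truth10, pred10)
  eat_cm <- confusion_matrix(truth_min_eat, pred_min_eat,
                             classes = c("eat", "not_eat"))
  truth10_drink <- ifelse(truth10 == "drink", "drink", "not_drink")
  pred10_drink <- ifelse(pred10 == "drink", "drink", "not_drink")
  drink_cm <- confusion_matrix(truth10_drink, pred10_drink,
                               classes = c("drink", "not_drink"))

  true_drinks <- filter(as_tibble(truth), .data$label == "drink") %>%
    select("start_s", "end_s")
  ev <- match_drink_events(predictions$drinks, true_drinks,
                           config$drink_match_tol_s)

  structure(list(
    overall = overall_cm, eating = eat_cm, drinking = drink_cm,
    metrics_overall = prf_metrics(overall_cm),
    metrics_eating = prf_metrics(eat_cm),
    metrics_drinking = prf_metrics(drink_cm),
    eat_rates = sens_spec_fph(truth_min_eat, pred_min_eat, "eat", hours),
    drink_rates = sens_spec_fph(truth10_drink, pred10_drink, "drink", hours),
    drink_events = mutate(ev, fp_per_hour = .data$fp / hours),
    hours = hours
  ), class = "intake_eval")
}

#' @export
print.intake_eval <- function(x, ...) {
  w <- filter(x$metrics_overall, .data$class == "weighted")
  cat(sprintf("<intake_eval> %.2f h scored; weighted F1 = %.3f\n",
              x$hours, w$f1))
  cat("overall 10 s confusion (rows = truth):\n")
  print(x$overall)
  cat(sprintf("eating: sens %.2f spec %.2f FP/h %.2f | drink events: %d TP, %d FP, %d FN\n",
              x$eat_rates$sensitivity, x$eat_rates$specificity,
              x$eat_rates$fp_per_hour, x$drink_events$tp,
              x$drink_events$fp, x$drink_events$fn))
  invisible(x)
}

#' @export
tidy.intake_eval <- function(x, ...) {
  bind_rows(
    mutate(x$metrics_overall, task = "overall"),
    mutate(x$metrics_eating, task = "eating"),
    mutate(x$metrics_drinking, task = "drinking")
  ) %>%
    select("task", "class", "support", "precision", "recall", "f1")
}

#' @export
glance.intake_eval <- function(x, ...) {
  w <- filter(x$metrics_overall, .data$class == "weighted")
  tibble(hours = x$hours,
         weighted_precision = w$precision,
         weighted_recall = w$recall,
         weighted_f1 = w$f1,
         eat_sensitivity = x$eat_rates$sensitivity,
         eat_specificity = x$eat_rates$specificity,
         eat_fp_per_hour = x$eat_rates$fp_per_hour,
         drink_sensitivity = x$drink_rates$sensitivity,
         drink_specificity = x$drink_rates$specificity,
         drink_event_tp = x$drink_events$tp,
         drink_event_fp = x$drink_events$fp,
         drink_event_fn = x$drink_events$fn,
         drink_event_fp_per_hour = x$drink_events$fp_per_hour)
}
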