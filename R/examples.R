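#' Bundled worked-example evaluation tables
#'
#' The package ships, as plain CSV under `inst/extdata`, the published
#' evaluation tables of the reference all-day deployment of this
#' algorithm, used as worked examples for the metric functions:
#'
#' * `"overall"` -- the 3-class confusion matrix of a 16 h free-living
#'   day scored on the 10 s grid (rows = truth, columns = predictions).
#' * `"drinking"` -- the binary drinking confusion matrix of the same day.
#' * `"validation"` -- per-class precision/recall/F1 and supports of the
#'   full 31 h multi-user validation set.
#'
#' @param which which table to load.
#' @return a matrix (confusion tables) or tibble (`"validation"`).
#' @export
#' @examples
#' m <- reference_table("overall")
#' prf_metrics(m)
reference_table <- function(which = c("overall", "drinking", "validation")) {
  which <- match.arg(which)
  file <- switch(which,
    overall = "allday_overall_confusion.csv",
    drinking = "allday_drinking_confusion.csv",
    validation = "validation_class_metrics.csv"
  )
  path <- system.file("extdata", file, package = "wristintake")
  df <- utils::read.csv(path, check.names = FALSE)
  if (which == "validation") return(as_tibble(df))
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  dimnames(m) <- list(truth = rownames(m), pred = colnames(m))
  m
}

#' Weighted F1 from printed per-class F1 values and supports
#'
#' Support-weighted mean of per-class F1 scores, as used to summarize a
#' multi-class evaluation from its printed per-class table.
#'
#' @param f1 per-class F1 values.
#' @param support per-class supports (unit counts).
#' @return the weighted F1.
#' @export
weighted_f1_from_table <- function(f1, support) {
  if (length(f1) != length(support)) abort("f1 and support lengths differ")
  sum(f1 * support) / sum(support)
}
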