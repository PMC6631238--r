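#' Default computational-cost ranking of the feature families
#'
#' Used by [correlation_filter()] to decide which member of a highly
#' correlated pair to drop: the costlier one goes first. Higher rank =
#' more expensive. Pairwise correlations and covariances are the most
#' expensive family, then Haar responses, variances, zero-crossing rates
#' (with the composite manipulation / linear-acceleration features), RMS,
#' and finally plain means.
#'
#' @param names feature names (defaults to the canonical 33).
#' @return named numeric vector of cost ranks.
#' @export
feature_cost_rank <- function(names = feature_names()) {
  rank_of <- function(nm) {
    dplyr::case_when(
      grepl("^corr_", nm) ~ 6,
      grepl("^cov_", nm) ~ 6,
      grepl("^haar_", nm) ~ 5,
      grepl("^(var|std)_", nm) ~ 4,
      grepl("^zcr_", nm) ~ 3,
      nm %in% c("manipulation", "linear_acceleration") ~ 3,
      grepl("^rms", nm) ~ 2,
      grepl("^mean_", nm) ~ 1,
      TRUE ~ 3
    )
  }
  stats::setNames(rank_of(names), names)
}

#' Drop one of every highly correlated feature pair
#'
#' Computes all pairwise Pearson correlations between feature columns and
#' greedily processes pairs in order of decreasing `|r|` (ties broken by
#' name order): whenever both members of a pair with `|r| > r_max` are
#' still alive, the costlier one (per `cost_rank`; cost ties broken by
#' later name order) is dropped. Constant columns have undefined
#' correlation; they are excluded from pairing and never dropped here.
#'
#' @param features a data frame of feature columns (>= 2 rows); extra
#'   non-feature columns such as window bookkeeping are ignored if a
#'   `names` subset is given.
#' @param names which columns to consider (default: all numeric columns
#'   present in [feature_names()], else all numeric columns).
#' @param cost_rank named numeric vector of costs; see
#'   [feature_cost_rank()].
#' @param r_max correlation threshold (default 0.8).
#' @return character vector of kept feature names.
#' @export
correlation_filter <- function(features, names = NULL, cost_rank = NULL,
                               r_max = 0.8) {
  if (is.null(names)) {
    names <- intersect(feature_names(), colnames(features))
    if (length(names) == 0) {
      names <- colnames(features)[vapply(features, is.numeric, logical(1))]
    }
  }
  x <- as.matrix(features[, names, drop = FALSE])
  if (nrow(x) < 2) abort("need >= 2 rows to estimate correlations")
  sds <- apply(x, 2, stats::sd)
  active <- names[sds > 0]
  if (length(active) < 2) return(names)
  r <- stats::cor(x[, active, drop = FALSE])
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pr <- tibble(
    a = active[pairs[, 1]], b = active[pairs[, 2]],
    absr = abs(r[pairs])
  ) %>%
    filter(.data$absr > r_max) %>%
    arrange(dplyr::desc(.data$absr), .data$a, .data$b)
  if (is.null(cost_rank)) cost_rank <- feature_cost_rank(names)
  alive <- stats::setNames(rep(TRUE, length(names)), names)
  for (i in seq_len(nrow(pr))) {
    a <- pr$a[i]; b <- pr$b[i]
    if (!alive[a] || !alive[b]) next
    ca <- cost_rank[a]; cb <- cost_rank[b]
    drop <- if (ca > cb) a else if (cb > ca) b else sort(c(a, b))[2]
    alive[drop] <- FALSE
  }
  names[alive[names]]
}

#' Drop features unimportant to either recognition branch
#'
#' Trains one random forest on eat-vs-rest labels and one on
#' drink-vs-rest labels, normalizes each model's impurity (Gini)
#' importances to sum 1, and drops every feature whose normalized
#' importance falls below `threshold` in at least one of the two models.
#'
#' @param features data frame containing the feature columns.
#' @param eat_labels,drink_labels logical (or two-level) vectors, one per
#'   row of `features`; both classes must be present in each.
#' @param threshold normalized-importance cutoff (default 0.01).
#' @param seed integer seed for the forests.
#' @param names feature columns to consider (default as in
#'   [correlation_filter()]).
#' @param n_trees forest size.
#' @return list with `kept` (character), and the per-model normalized
#'   importances `importance_eat`, `importance_drink` (named, each summing
#'   to 1).
#' @export
importance_filter <- function(features, eat_labels, drink_labels,
                              threshold = 0.01, seed = 1, names = NULL,
                              n_trees = 200) {
  if (is.null(names)) {
    names <- intersect(feature_names(), colnames(features))
    if (length(names) == 0) {
      names <- colnames(features)[vapply(features, is.numeric, logical(1))]
    }
  }
  imp_one <- function(labels, which) {
    y <- factor(ifelse(as.logical(labels), "pos", "rest"),
                levels = c("pos", "rest"))
    if (length(unique(y)) < 2) {
      abort(paste0("single-class ", which, " label vector"))
    }
    df <- as.data.frame(features[, names, drop = FALSE])
    df$.y <- y
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = n_trees,
                          importance = "impurity", seed = seed,
                          num.threads = 1)
    imp <- fit$variable.importance
    imp <- pmax(imp, 0)
    imp / sum(imp)
  }
  ie <- imp_one(eat_labels, "eating")
  id <- imp_one(drink_labels, "drinking")
  kept <- names[ie[names] >= threshold & id[names] >= threshold]
  list(kept = kept, importance_eat = ie, importance_drink = id)
}
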