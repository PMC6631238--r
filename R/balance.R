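#' SMOTE + ENN class balancing
#'
#' Oversamples the minority class with SMOTE (synthetic points interpolated
#' between a minority sample and one of its `k_smote` nearest minority
#' neighbours) up to the majority count, then cleans the combined set with
#' edited nearest neighbours: every sample whose label disagrees with the
#' majority vote of its `k_enn` nearest neighbours is removed. A class is
#' never emptied: if cleaning would remove all samples of a class, that
#' class's removals are skipped. Deterministic under `seed`.
#'
#' @param x data frame or matrix of numeric features.
#' @param y binary label vector (logical, or any two-level vector).
#' @param seed integer seed.
#' @param k_smote number of SMOTE neighbours (default 5); the minority
#'   class must contain at least `k_smote + 1` samples.
#' @param k_enn number of ENN neighbours (default 3).
#' @return list with `x` (tibble) and `y` (same type as input levels),
#'   plus `counts_before` / `counts_after`.
#' @export
balance_classes <- function(x, y, seed = 1, k_smote = 5, k_enn = 3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  lv <- unique(y)
  if (length(lv) != 2) abort("y must contain exactly two classes")
  tab <- table(factor(y, levels = lv))
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < k_smote + 1) {
    abort(sprintf(
      "minority class has %d samples but SMOTE needs k + 1 = %d; use a smaller k_smote",
      n_min, k_smote + 1))
  }
  counts_before <- c(stats::setNames(as.integer(tab), names(tab)))

  withr::with_seed(seed, {
    xs <- x; ys <- as.character(y)
    n_new <- n_maj - n_min
    if (n_new > 0) {
      xmin <- x[ys == minority, , drop = FALSE]
      d <- as.matrix(stats::dist(xmin))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_smote)]))
      base_idx <- rep_len(seq_len(nrow(xmin)), n_new)
      syn <- matrix(0, n_new, ncol(x))
      for (i in seq_len(n_new)) {
        b <- base_idx[i]
        nb <- nn[b, sample.int(k_smote, 1)]
        u <- runif(1)
        syn[i, ] <- xmin[b, ] + u * (xmin[nb, ] - xmin[b, ])
      }
      xs <- rbind(x, syn)
      ys <- c(ys, rep(minority, n_new))
    }
    ## ENN cleaning on the combined set
    dd <- as.matrix(stats::dist(xs))
    diag(dd) <- Inf
    k <- min(k_enn, nrow(xs) - 1)
    remove <- vapply(seq_len(nrow(xs)), function(i) {
      nb <- order(dd[i, ])[seq_len(k)]
      votes <- table(ys[nb])
      names(votes)[which.max(votes)] != ys[i]
    }, logical(1))
    for (cls in c(minority, majority)) {
      if (all(remove[ys == cls])) remove[ys == cls] <- FALSE
    }
    xs <- xs[!remove, , drop = FALSE]
    ys <- ys[!remove]
  })

  if (is.null(colnames(x))) {
    colnames(xs) <- paste0("f", seq_len(ncol(xs)))
  } else {
    colnames(xs) <- colnames(x)
  }
  counts_after <- c(table(factor(ys, levels = names(tab))))
  list(x = as_tibble(xs), y = ys,
       counts_before = counts_before,
       counts_after = stats::setNames(as.integer(counts_after),
                                      names(counts_after)))
}
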