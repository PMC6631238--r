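## Independent reference implementations used as oracles. These are
## deliberately written as straight-line code, separate from the package
## internals.

## --- 33-feature brute force -------------------------------------------------
## mat: n x 6 (ax ay az gx gy gz)
ref_features <- function(mat, fs, g = 9.80665, eps = 1e-6) {
  n <- nrow(mat)
  pvar <- function(x) sum((x - sum(x) / n)^2) / n
  pcov <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / n
  pcor <- function(x, y) {
    if (pvar(x) == 0 || pvar(y) == 0) return(0)
    pcov(x, y) / sqrt(pvar(x) * pvar(y))
  }
  haar <- function(x) {
    h <- floor(n / 2)
    mean(x[1:h]) - mean(x[(h + 1):n])
  }
  zcr <- function(x) {
    s <- x - mean(x)
    cnt <- 0
    for (i in 1:(n - 1)) if (s[i] * s[i + 1] < 0) cnt <- cnt + 1
    cnt / (n / fs)
  }
  amag <- sqrt(mat[, 1]^2 + mat[, 2]^2 + mat[, 3]^2)
  out <- c(
    apply(mat, 2, mean),
    apply(mat, 2, pvar),
    apply(mat, 2, haar),
    pcor(mat[, 1], mat[, 2]), pcor(mat[, 1], mat[, 3]), pcor(mat[, 2], mat[, 3]),
    pcor(mat[, 4], mat[, 5]), pcor(mat[, 4], mat[, 6]), pcor(mat[, 5], mat[, 6]),
    pcov(mat[, 1], mat[, 2]), pcov(mat[, 1], mat[, 3]), pcov(mat[, 2], mat[, 3]),
    zcr(mat[, 4]), zcr(mat[, 5]), zcr(mat[, 6]),
    mean((abs(mat[, 4]) + abs(mat[, 5]) + abs(mat[, 6])) / pmax(amag, eps)),
    mean(abs(amag - g)),
    sqrt(mean(amag^2))
  )
  names(out) <- feature_names()
  out
}

## --- dynamic-window reference scan ------------------------------------------
## Pure-R re-implementation of the descending-run scan over x[from:to]
## (1-based inclusive); returns 1-based inclusive end indices of windows.
ref_dw_scan <- function(x, N, scale, floor_, from = 1, to = length(x)) {
  ends <- integer()
  run_max <- x[from]; run_min <- x[from]; run_min_idx <- from
  pending <- FALSE
  win_start <- from
  for (i in from:to) {
    if (i > from) {
      xi <- x[i]
      if (xi > run_min + floor_) {
        if (pending && run_min_idx >= win_start) {
          ends <- c(ends, run_min_idx)
          win_start <- run_min_idx + 1
        }
        pending <- FALSE
        run_max <- xi; run_min <- xi; run_min_idx <- i
      } else if (xi < run_min) {
        run_min <- xi; run_min_idx <- i
      }
    }
    hist <- i - from
    theta <- floor_
    if (hist >= N) {
      h <- x[(i - N):(i - 1)]
      theta <- max(floor_, scale * stats::mad(h))  # 1.4826 * MAD
    }
    if (run_max - run_min > theta) pending <- TRUE
  }
  if (pending && run_min_idx >= win_start && run_min_idx < to) {
    ends <- c(ends, run_min_idx)
  }
  c(ends, to)
}

ref_dw_windows <- function(x, N = 100, scale = 3, floor_ = 0.1) {
  ends <- ref_dw_scan(x, N, scale, floor_)
  starts <- c(1L, head(ends, -1) + 1L)
  data.frame(start_idx = starts, end_idx = ends)
}

ref_dfw_windows <- function(x, fs, t_s = 10, N = 100, scale = 3, floor_ = 0.1) {
  block <- round(t_s * fs)
  ends <- integer()
  b <- 1L
  while (b <= length(x)) {
    to <- min(length(x), b + block - 1L)
    ends <- c(ends, ref_dw_scan(x, N, scale, floor_, from = b, to = to))
    b <- b + block
  }
  starts <- c(1L, head(ends, -1) + 1L)
  data.frame(start_idx = starts, end_idx = ends)
}

## --- metric counting oracle -------------------------------------------------
## Per-class metrics computed directly from label vectors by counting pairs.
ref_prf_from_vectors <- function(truth, pred, classes) {
  res <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, support = sum(truth == cl),
               precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, res)
}

## Horner polynomial evaluation, highest degree first (for analytic filter
## responses)
polyval <- function(cf, x) {
  out <- 0 + 0i
  for (c_i in cf) out <- out * x + c_i
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## raised-cosine bump of given width (samples), centred at `center`
bump_vec <- function(n, center, width) {
  u <- (seq_len(n) - center) / (width / 2)
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}

## --- tiny fixtures ----------------------------------------------------------
random_stream <- function(n, fs = 50, seed = 1, t0 = 0) {
  withr::with_seed(seed, {
    m <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(m) <- c("ax", "ay", "az", "gx", "gy", "gz")
    sensor_stream(m, fs = fs, t0 = t0)
  })
}

## linearly separable two-class feature table on the 33-feature layout
separable_features <- function(n_pos = 40, n_neg = 80, seed = 1, shift = 6) {
  withr::with_seed(seed, {
    m <- matrix(rnorm((n_pos + n_neg) * 33), n_pos + n_neg, 33)
    m[seq_len(n_pos), 1:5] <- m[seq_len(n_pos), 1:5] + shift
    colnames(m) <- feature_names()
    list(features = tibble::as_tibble(m),
         labels = c(rep("eat", n_pos), rep("other", n_neg)))
  })
}
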