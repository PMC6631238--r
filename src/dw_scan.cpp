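#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Median of a scratch buffer (R semantics: even length averages the two
// central order statistics). Destroys the buffer's order.
static double med_of(std::vector<double>& buf) {
  size_t n = buf.size();
  size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Robust dispersion of the window: 1.4826 * MAD (consistent with the
// standard deviation under Gaussian noise, insensitive to a transient
// occupying less than half the window).
static double robust_sd(const double* w, int N, std::vector<double>& scratch) {
  scratch.assign(w, w + N);
  double m = med_of(scratch);
  for (int j = 0; j < N; ++j) scratch[j] = std::fabs(w[j] - m);
  return 1.4826 * med_of(scratch);
}

// Dynamic-window scan over x[from, to) (0-based, half-open).
//
// State: the current maximal descending run (run max, run min, index of
// the run minimum). A run restarts when the signal rises more than
// `floor_` above its running minimum. When the run's drop (max - min)
// exceeds the dynamic threshold
//   theta(i) = max(floor_, scale * robust sd of the previous N samples)
// the window is flagged pending and closes at the end of the descent: the
// run-minimum sample, once the restart rise occurs (or the range ends,
// provided the boundary is interior). History accrues from `from`; until
// N in-range samples exist, theta = floor_.
//
// Appends 0-based *exclusive* end indices of closed windows to `ends`;
// the final tail window (ending at `to`) is always appended.
static void scan_range(const double* x, int from, int to,
                       int N, double scale, double floor_,
                       std::vector<int>& ends,
                       std::vector<double>& scratch) {
  if (to <= from) return;
  double run_max = x[from], run_min = x[from];
  int run_min_idx = from;
  bool pending = false;
  int win_start = from;

  for (int i = from; i < to; ++i) {
    if (i > from) {
      double xi = x[i];
      if (xi > run_min + floor_) {
        // descent over: close a pending window at the run minimum
        if (pending && run_min_idx + 1 > win_start) {
          ends.push_back(run_min_idx + 1);
          win_start = run_min_idx + 1;
        }
        pending = false;
        run_max = xi; run_min = xi; run_min_idx = i;
      } else if (xi < run_min) {
        run_min = xi; run_min_idx = i;
      }
    }
    double theta = floor_;
    if (i - from >= N) {
      double disp = scale * robust_sd(&x[i - N], N, scratch);
      theta = disp > floor_ ? disp : floor_;
    }
    if (run_max - run_min > theta) pending = true;
  }
  if (pending && run_min_idx + 1 > win_start && run_min_idx + 1 < to) {
    ends.push_back(run_min_idx + 1);
  }
  ends.push_back(to);
}

// block_len <= 0: plain dynamic windows over the whole signal (DW).
// block_len  > 0: forced boundary and full state/history reset every
//                 block_len samples (DFW); each block is scanned
//                 independently, so DFW == per-block DW by construction.
// [[Rcpp::export]]
IntegerVector dw_scan_cpp(NumericVector x, int N, double scale, double floor_,
                          int block_len) {
  int n = x.size();
  std::vector<int> ends;
  std::vector<double> scratch;
  scratch.reserve(N);
  const double* xp = REAL(x);
  if (n == 0) return IntegerVector(0);
  if (block_len <= 0) {
    scan_range(xp, 0, n, N, scale, floor_, ends, scratch);
  } else {
    for (int b = 0; b < n; b += block_len) {
      int to = b + block_len < n ? b + block_len : n;
      scan_range(xp, b, to, N, scale, floor_, ends, scratch);
    }
  }
  return wrap(ends);   // 0-based exclusive end indices, strictly increasing
}
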