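#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diagonal-line statistics of a symmetric recurrence structure.
// Works on the upper triangle only; by symmetry every off-identity line
// appears once per triangle, so counts are doubled. The line of identity
// (main diagonal) is excluded throughout.
//
// rec(i, j) is provided through a callback-free design: callers fill a
// boolean buffer of the upper triangle, indexed by offset d = j - i
// (1..n-1) and position i (0..n-1-d).
struct RqaAccum {
  double rr, det, avg_len, entr;
  bool has_lines;
};

static RqaAccum rqa_scan(const std::vector<unsigned char> &upper,
                         int n, int l_min) {
  // upper is laid out diagonal-major: for d = 1..n-1 the run of (n - d)
  // entries holds rec(i, i + d).
  long long rec_points = 0;     // upper-triangle recurrent points
  long long det_points = 0;     // of those, points on lines of length >= l_min
  std::vector<long long> hist;  // line-length histogram (lines >= l_min)
  hist.assign(n + 1, 0);

  std::size_t off = 0;
  for (int d = 1; d < n; ++d) {
    int len = n - d;
    int run = 0;
    for (int i = 0; i <= len; ++i) {
      bool on = (i < len) && upper[off + i];
      if (on) {
        ++run;
      } else if (run > 0) {
        rec_points += run;
        if (run >= l_min) {
          det_points += run;
          hist[run] += 1;
        }
        run = 0;
      }
    }
    off += len;
  }

  RqaAccum out;
  long long denom = (long long)n * n - n;
  out.rr = denom > 0 ? (2.0 * rec_points) / denom : 0.0;
  out.det = rec_points > 0 ? (double)det_points / rec_points : 0.0;

  long long n_lines = 0;
  for (int l = l_min; l <= n; ++l) n_lines += hist[l];
  out.has_lines = n_lines > 0;
  if (n_lines > 0) {
    double L = 0.0, H = 0.0;
    for (int l = l_min; l <= n; ++l) {
      if (hist[l] == 0) continue;
      double p = (double)hist[l] / n_lines;
      L += p * l;
      H -= p * std::log(p);
    }
    out.avg_len = L;
    out.entr = H;
  } else {
    out.avg_len = NA_REAL;
    out.entr = 0.0;
  }
  return out;
}

// [[Rcpp::export(name = ".rqa_from_binary")]]
NumericVector rqa_from_binary(LogicalMatrix m, int l_min) {
  int n = m.nrow();
  if (m.ncol() != n) stop("recurrence matrix must be square");
  std::vector<unsigned char> upper;
  upper.reserve((std::size_t)n * (n - 1) / 2);
  for (int d = 1; d < n; ++d)
    for (int i = 0; i + d < n; ++i)
      upper.push_back(m(i, i + d) == TRUE ? 1 : 0);
  RqaAccum a = rqa_scan(upper, n, l_min);
  return NumericVector::create(_["rr"] = a.rr, _["det"] = a.det,
                               _["avg_len"] = a.avg_len, _["entr"] = a.entr);
}

// RQA measures over a series of windows of a 3-axis signal.
// acc: n x 3 matrix; win_start/win_end: 1-based inclusive sample bounds per
// window. radius = radius_fraction * max pairwise distance within the window
// (fixed_radius > 0 overrides). Returns one row (rr, det, avg_len, entr) per
// window; windows with < 2 samples give NA rows.
// [[Rcpp::export(name = ".rqa_series")]]
NumericMatrix rqa_series(NumericMatrix acc, IntegerVector win_start,
                         IntegerVector win_end, double radius_fraction,
                         double fixed_radius, int l_min) {
  int nw = win_start.size();
  if (win_end.size() != nw) stop("window bound lengths differ");
  NumericMatrix out(nw, 4);
  std::fill(out.begin(), out.end(), NA_REAL);

  std::vector<double> d2;           // upper-triangle squared distances
  std::vector<unsigned char> upper; // thresholded recurrences

  const double *x = &acc(0, 0);
  const double *y = &acc(0, 1);
  const double *z = &acc(0, 2);
  int nr = acc.nrow();

  for (int w = 0; w < nw; ++w) {
    int a = win_start[w] - 1, b = win_end[w] - 1;
    if (a < 0 || b >= nr || b - a + 1 < 2) continue;
    int n = b - a + 1;
    std::size_t ntri = (std::size_t)n * (n - 1) / 2;
    d2.resize(ntri);
    upper.resize(ntri);

    // diagonal-major layout to match rqa_scan
    double maxd2 = 0.0;
    std::size_t k = 0;
    for (int d = 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i, ++k) {
        double dx = x[a + i] - x[a + i + d];
        double dy = y[a + i] - y[a + i + d];
        double dz = z[a + i] - z[a + i + d];
        double v = dx * dx + dy * dy + dz * dz;
        d2[k] = v;
        if (v > maxd2) maxd2 = v;
      }
    }
    double r2;
    if (fixed_radius > 0) {
      r2 = fixed_radius * fixed_radius;
    } else {
      double r = radius_fraction * std::sqrt(maxd2);
      r2 = r * r;
    }
    for (std::size_t i = 0; i < ntri; ++i) upper[i] = d2[i] <= r2 ? 1 : 0;

    RqaAccum acc_out = rqa_scan(upper, n, l_min);
    out(w, 0) = acc_out.rr;
    out(w, 1) = acc_out.det;
    out(w, 2) = acc_out.avg_len;
    out(w, 3) = acc_out.entr;
  }
  colnames(out) = CharacterVector::create("rr", "det", "avg_len", "entr");
  return out;
}
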