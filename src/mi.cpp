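#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in entropies and pairwise mutual information over discretized
// feature columns. Codes are 0-based bin ids in [0, n_bins). All values
// are in bits. The d x d pair loop is the hot path of the pipeline, hence
// the C++ implementation; everything is exact counting, no approximation.

static inline double xlog2x(double p) {
  return p > 0.0 ? p * std::log2(p) : 0.0;
}

// [[Rcpp::export]]
NumericMatrix mi_matrix_codes(IntegerMatrix codes, int n_bins) {
  const int n = codes.nrow();
  const int d = codes.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (n_bins < 1) stop("n_bins must be positive");

  // marginal counts per column
  std::vector<int> marg(static_cast<size_t>(d) * n_bins, 0);
  for (int j = 0; j < d; ++j) {
    int *m = &marg[static_cast<size_t>(j) * n_bins];
    for (int i = 0; i < n; ++i) {
      int c = codes(i, j);
      if (c < 0 || c >= n_bins) stop("code out of range in column %d", j + 1);
      m[c]++;
    }
  }

  // per-column entropies H(f_j)
  std::vector<double> H(d);
  const double dn = static_cast<double>(n);
  for (int j = 0; j < d; ++j) {
    const int *m = &marg[static_cast<size_t>(j) * n_bins];
    double h = 0.0;
    for (int b = 0; b < n_bins; ++b) h -= xlog2x(m[b] / dn);
    H[j] = h;
  }

  NumericMatrix out(d, d);
  std::vector<int> joint(static_cast<size_t>(n_bins) * n_bins);
  for (int j = 0; j < d; ++j) {
    out(j, j) = H[j];
    const int *cj = &codes(0, j);
    const int *mj = &marg[static_cast<size_t>(j) * n_bins];
    for (int k = j + 1; k < d; ++k) {
      if (H[j] == 0.0 || H[k] == 0.0) {
        // a zero-entropy (constant) column is independent of everything
        out(j, k) = 0.0;
        out(k, j) = 0.0;
        continue;
      }
      const int *ck = &codes(0, k);
      const int *mk = &marg[static_cast<size_t>(k) * n_bins];
      std::fill(joint.begin(), joint.end(), 0);
      for (int i = 0; i < n; ++i) joint[cj[i] * n_bins + ck[i]]++;
      double mi = 0.0;
      for (int a = 0; a < n_bins; ++a) {
        if (mj[a] == 0) continue;
        for (int b = 0; b < n_bins; ++b) {
          int c = joint[a * n_bins + b];
          if (c == 0 || mk[b] == 0) continue;
          double pj = c / dn;
          mi += pj * std::log2(pj * dn * dn / (static_cast<double>(mj[a]) * mk[b]));
        }
      }
      if (mi < 0.0) mi = 0.0; // guard against rounding at independence
      out(j, k) = mi;
      out(k, j) = mi;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mi_label_codes(IntegerMatrix codes, IntegerVector y,
                             int n_bins, int n_classes) {
  const int n = codes.nrow();
  const int d = codes.ncol();
  if (y.size() != n) stop("label length must match rows");
  const double dn = static_cast<double>(n);

  std::vector<int> ymarg(n_classes, 0);
  for (int i = 0; i < n; ++i) {
    if (y[i] < 0 || y[i] >= n_classes) stop("label code out of range");
    ymarg[y[i]]++;
  }

  NumericVector out(d);
  std::vector<int> joint(static_cast<size_t>(n_bins) * n_classes);
  std::vector<int> marg(n_bins);
  for (int j = 0; j < d; ++j) {
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(marg.begin(), marg.end(), 0);
    for (int i = 0; i < n; ++i) {
      int c = codes(i, j);
      if (c < 0 || c >= n_bins) stop("code out of range in column %d", j + 1);
      joint[c * n_classes + y[i]]++;
      marg[c]++;
    }
    double mi = 0.0;
    for (int a = 0; a < n_bins; ++a) {
      if (marg[a] == 0) continue;
      for (int b = 0; b < n_classes; ++b) {
        int c = joint[a * n_classes + b];
        if (c == 0 || ymarg[b] == 0) continue;
        double pj = c / dn;
        mi += pj * std::log2(pj * dn * dn / (static_cast<double>(marg[a]) * ymarg[b]));
      }
    }
    out[j] = mi < 0.0 ? 0.0 : mi;
  }
  return out;
}
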