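#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in Shannon entropy (bits) of the keys accumulated in cnt at the
// positions listed in touched; resets the buffer for reuse.
static double ent_flush(std::vector<int> &cnt, std::vector<int> &touched,
                        double n) {
  double h = 0.0;
  for (size_t i = 0; i < touched.size(); ++i) {
    int k = touched[i];
    double p = cnt[k] / n;
    h -= p * std::log2(p);
    cnt[k] = 0;
  }
  touched.clear();
  return h;
}

static inline void count_key(int key, std::vector<int> &cnt,
                             std::vector<int> &touched) {
  if (cnt[key]++ == 0) touched.push_back(key);
}

// All pairwise symbolic transfer entropies of one data block.
//
// codes:    patterns x channels matrix of symbols in [0, alphabet).
// deltas:   transfer delays (pattern steps).
// src, tgt: 0-based channel indices of the ordered pairs.
//
// For each (pair, delta) the four entropies H(Y,Y'), H(Y), H(X,Y,Y') and
// H(X,Y) are marginals of the empirical triple distribution over the common
// range t = 0 .. n-1-delta, so every estimate is non-negative.
// [[Rcpp::export]]
NumericMatrix ste_matrix_cpp(IntegerMatrix codes, IntegerVector deltas,
                             IntegerVector src, IntegerVector tgt,
                             int alphabet) {
  const int n = codes.nrow();
  const int nch = codes.ncol();
  const int npair = src.size();
  const int ndel = deltas.size();
  const size_t a1 = (size_t)alphabet;
  // reused across calls; ent_flush leaves it all-zero
  static std::vector<int> cnt;
  if (cnt.size() < a1 * a1 * a1) cnt.assign(a1 * a1 * a1, 0);
  std::vector<int> touched;
  touched.reserve(n);

  NumericMatrix out(npair, ndel);
  std::vector<double> h_y(nch), h_yy(nch);

  for (int di = 0; di < ndel; ++di) {
    const int delta = deltas[di];
    if (delta >= n) stop("transfer delay exceeds the block's pattern count");
    const double len = n - delta;
    for (int c = 0; c < nch; ++c) {
      for (int t = 0; t < n - delta; ++t) count_key(codes(t, c), cnt, touched);
      h_y[c] = ent_flush(cnt, touched, len);
      for (int t = 0; t < n - delta; ++t)
        count_key(codes(t, c) * alphabet + codes(t + delta, c), cnt, touched);
      h_yy[c] = ent_flush(cnt, touched, len);
    }
    for (int p = 0; p < npair; ++p) {
      const int cs = src[p], ct = tgt[p];
      for (int t = 0; t < n - delta; ++t)
        count_key(codes(t, cs) * alphabet + codes(t, ct), cnt, touched);
      double h_xy = ent_flush(cnt, touched, len);
      for (int t = 0; t < n - delta; ++t)
        count_key((codes(t, cs) * alphabet + codes(t, ct)) * alphabet +
                      codes(t + delta, ct),
                  cnt, touched);
      double h_xyy = ent_flush(cnt, touched, len);
      double te = h_yy[ct] - h_y[ct] - h_xyy + h_xy;
      out(p, di) = te > 0 ? te : 0;
    }
  }
  return out;
}
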