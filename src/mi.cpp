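// Adaptive-partitioning mutual information on rank-transformed data.
// Ranks are scaled to (0, 1]; the unit square is split recursively into
// four equal-area quadrants while the 4-cell occupancy chi-square exceeds
// `chi_crit` and the parent cell holds at least 4 * min_leaf points.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct MiCtx {
  const double *rx;
  const double *ry;
  int n;
  int min_leaf;
  double chi_crit;
};

double mi_rec(const MiCtx &ctx, std::vector<int> &idx, int lo, int hi,
              double x0, double x1, double y0, double y1) {
  const int nl = hi - lo;
  if (nl == 0) return 0.0;
  const double xm = 0.5 * (x0 + x1), ym = 0.5 * (y0 + y1);

  bool split = false;
  if (nl >= 4 * ctx.min_leaf) {
    int c1 = 0, c2 = 0, c3 = 0, c4 = 0;
    for (int t = lo; t < hi; ++t) {
      const int i = idx[t];
      const bool right = ctx.rx[i] > xm, top = ctx.ry[i] > ym;
      if (right) { if (top) ++c1; else ++c4; }
      else       { if (top) ++c2; else ++c3; }
    }
    const double e = nl / 4.0;
    const double chi = ((c1 - e) * (c1 - e) + (c2 - e) * (c2 - e) +
                        (c3 - e) * (c3 - e) + (c4 - e) * (c4 - e)) / e;
    split = chi > ctx.chi_crit;
  }

  if (!split) {
    const double p = static_cast<double>(nl) / ctx.n;
    const double area = (x1 - x0) * (y1 - y0);
    return p * std::log(p / area);
  }

  // partition idx[lo, hi) into quadrants: left/right by x, then bottom/top by y
  std::vector<int>::iterator b = idx.begin();
  std::vector<int>::iterator mid =
      std::partition(b + lo, b + hi, [&](int i) { return ctx.rx[i] <= xm; });
  std::vector<int>::iterator lmid =
      std::partition(b + lo, mid, [&](int i) { return ctx.ry[i] <= ym; });
  std::vector<int>::iterator rmid =
      std::partition(mid, b + hi, [&](int i) { return ctx.ry[i] <= ym; });
  const int i_lmid = static_cast<int>(lmid - b);
  const int i_mid = static_cast<int>(mid - b);
  const int i_rmid = static_cast<int>(rmid - b);

  return mi_rec(ctx, idx, lo, i_lmid, x0, xm, y0, ym) +      // left-bottom
         mi_rec(ctx, idx, i_lmid, i_mid, x0, xm, ym, y1) +   // left-top
         mi_rec(ctx, idx, i_mid, i_rmid, xm, x1, y0, ym) +   // right-bottom
         mi_rec(ctx, idx, i_rmid, hi, xm, x1, ym, y1);       // right-top
}

double mi_from_scaled(const double *rx, const double *ry, int n,
                      int min_leaf, double chi_crit) {
  MiCtx ctx{rx, ry, n, min_leaf, chi_crit};
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double mi = mi_rec(ctx, idx, 0, n, 0.0, 1.0, 0.0, 1.0);
  return mi > 0.0 ? mi : 0.0;
}

// ranks with ties broken by first occurrence (stable sort), scaled by 1/n
void rank_scaled(const double *x, int n, double *out, std::vector<int> &ord) {
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  for (int r = 0; r < n; ++r) out[ord[r]] = static_cast<double>(r + 1) / n;
}

}  // namespace

// [[Rcpp::export]]
double mi_ap_cpp(NumericVector x, NumericVector y, int min_leaf,
                 double chi_crit) {
  const int n = x.size();
  if (y.size() != n) stop("length mismatch");
  std::vector<double> rx(n), ry(n);
  std::vector<int> scratch;
  rank_scaled(REAL(x), n, rx.data(), scratch);
  rank_scaled(REAL(y), n, ry.data(), scratch);
  return mi_from_scaled(rx.data(), ry.data(), n, min_leaf, chi_crit);
}

// Row-wise ranks (ties by first occurrence), scaled to (0, 1].
// [[Rcpp::export]]
NumericMatrix rank_rows_cpp(NumericMatrix m) {
  const int g = m.nrow(), n = m.ncol();
  NumericMatrix out(g, n);
  std::vector<double> row(n), rr(n);
  std::vector<int> scratch;
  for (int i = 0; i < g; ++i) {
    for (int j = 0; j < n; ++j) row[j] = m(i, j);
    rank_scaled(row.data(), n, rr.data(), scratch);
    for (int j = 0; j < n; ++j) out(i, j) = rr[j];
  }
  return out;
}

// MI for every (regulator row, gene row) pair of a pre-ranked matrix.
// `reg_rows` is 1-based; self pairs are NA.
// [[Rcpp::export]]
NumericMatrix mi_pairs_cpp(NumericMatrix ranks, IntegerVector reg_rows,
                           int min_leaf, double chi_crit) {
  const int g = ranks.nrow(), n = ranks.ncol(), nr = reg_rows.size();
  NumericMatrix out(nr, g);
  // copy rows once into contiguous buffers
  std::vector<double> buf(static_cast<size_t>(g) * n);
  for (int i = 0; i < g; ++i)
    for (int j = 0; j < n; ++j) buf[static_cast<size_t>(i) * n + j] = ranks(i, j);
  for (int r = 0; r < nr; ++r) {
    const int ri = reg_rows[r] - 1;
    if (ri < 0 || ri >= g) stop("regulator row out of range");
    const double *rx = &buf[static_cast<size_t>(ri) * n];
    for (int gi = 0; gi < g; ++gi) {
      if (gi == ri) { out(r, gi) = NA_REAL; continue; }
      const double *ry = &buf[static_cast<size_t>(gi) * n];
      out(r, gi) = mi_from_scaled(rx, ry, n, min_leaf, chi_crit);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Null MI draws: random gene-pair rows with one member independently permuted.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector mi_null_cpp(NumericMatrix ranks, int n_null, int min_leaf,
                          double chi_crit) {
  const int g = ranks.nrow(), n = ranks.ncol();
  if (g < 2) stop("need at least two genes");
  NumericVector out(n_null);
  std::vector<double> rx(n), ry(n);
  for (int d = 0; d < n_null; ++d) {
    int i = static_cast<int>(unif_rand() * g);
    int j = static_cast<int>(unif_rand() * g);
    if (i >= g) i = g - 1;
    if (j >= g) j = g - 1;
    if (j == i) j = (i + 1) % g;
    for (int t = 0; t < n; ++t) { rx[t] = ranks(i, t); ry[t] = ranks(j, t); }
    // Fisher-Yates shuffle of ry
    for (int t = n - 1; t > 0; --t) {
      int k = static_cast<int>(unif_rand() * (t + 1));
      if (k > t) k = t;
      std::swap(ry[t], ry[k]);
    }
    out[d] = mi_from_scaled(rx.data(), ry.data(), n, min_leaf, chi_crit);
    if (d % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
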