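#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Local extrema. Plateaus contribute their midpoint. Endpoints are never
// extrema themselves; boundary handling is done by mirror extension of the
// interior extrema before spline fitting.
// ---------------------------------------------------------------------------
static void find_extrema(const double* x, int n,
                         std::vector<int>& mx, std::vector<int>& mn) {
  mx.clear(); mn.clear();
  if (n < 3) return;
  int i = 1;
  while (i < n - 1) {
    double dl = x[i] - x[i - 1];
    if (x[i] == x[i + 1]) {             // plateau: scan to its end
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1) {
        double dr = x[j + 1] - x[j];
        int mid = (i + j) / 2;
        if (dl > 0 && dr < 0) mx.push_back(mid);
        else if (dl < 0 && dr > 0) mn.push_back(mid);
      }
      i = j + 1;
    } else {
      double dr = x[i + 1] - x[i];
      if (dl > 0 && dr < 0) mx.push_back(i);
      else if (dl < 0 && dr > 0) mn.push_back(i);
      ++i;
    }
  }
}

static int count_zero_crossings(const double* x, int n) {
  int zc = 0;
  double prev = 0.0;
  bool have_prev = false;
  for (int i = 0; i < n; ++i) {
    if (x[i] == 0.0) continue;          // skip exact zeros (touching counts once)
    if (have_prev && ((prev > 0) != (x[i] > 0))) ++zc;
    prev = x[i];
    have_prev = true;
  }
  return zc;
}

// ---------------------------------------------------------------------------
// Natural cubic spline through (t, y), evaluated at integers 0..n-1.
// Knot abscissae must be strictly increasing and bracket [0, n-1].
// ---------------------------------------------------------------------------
static void spline_eval(const std::vector<double>& t, const std::vector<double>& y,
                        int n, std::vector<double>& out) {
  int m = (int) t.size();
  out.assign(n, 0.0);
  if (m == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (m == 2) {                         // linear
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives via tridiagonal solve (natural BC: M0 = Mm-1 = 0)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 6.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate; walk the knot intervals once
  int k = 0;
  for (int i = 0; i < n; ++i) {
    double ti = (double) i;
    while (k < m - 2 && ti > t[k + 1]) ++k;
    double hk = h[k];
    double a = (t[k + 1] - ti) / hk, b = (ti - t[k]) / hk;
    out[i] = a * y[k] + b * y[k + 1] +
      ((a * a * a - a) * M[k] + (b * b * b - b) * M[k + 1]) * (hk * hk) / 6.0;
  }
}

// Mirror up to `nmir` extrema about each end so the spline is anchored
// outside [0, n-1]; standard EMD boundary treatment.
static void mirrored_knots(const std::vector<int>& idx, const double* x, int n,
                           std::vector<double>& t, std::vector<double>& y) {
  int m = (int) idx.size();
  const int nmir = 2;
  t.clear(); y.clear();
  // left mirror (reflect about sample 0), most distant reflection first
  for (int k = std::min(nmir, m); k >= 1; --k) {
    if (idx[k - 1] > 0) { t.push_back(-(double) idx[k - 1]); y.push_back(x[idx[k - 1]]); }
  }
  for (int k = 0; k < m; ++k) { t.push_back((double) idx[k]); y.push_back(x[idx[k]]); }
  for (int k = 1; k <= std::min(nmir, m); ++k) {
    int j = idx[m - k];
    if (j < n - 1) { t.push_back(2.0 * (n - 1) - j); y.push_back(x[j]); }
  }
  // enforce strict monotonicity (duplicates can arise from mirroring extrema
  // that sit exactly at the ends)
  std::vector<double> tt, yy;
  for (size_t k = 0; k < t.size(); ++k) {
    if (tt.empty() || t[k] > tt.back()) { tt.push_back(t[k]); yy.push_back(y[k]); }
  }
  t.swap(tt); y.swap(yy);
}

// Boundary extension for the envelope pair: reflect extrema symmetrically
// about the first/last extremum; when the end sample protrudes beyond the
// nearest opposite extremum, reflect about the end sample and anchor it as an
// extremum instead. Standard treatment for spline envelopes in EMD.
static void extend_pair(const std::vector<int>& mx, const std::vector<int>& mn,
                        const double* x, int n,
                        std::vector<double>& tu, std::vector<double>& yu,
                        std::vector<double>& tl, std::vector<double>& yl) {
  const int nb = 2;
  int nmx = (int) mx.size(), nmn = (int) mn.size();
  tu.clear(); yu.clear(); tl.clear(); yl.clear();
  std::vector<double> ltu, lyu, ltl, lyl, rtu, ryu, rtl, ryl;

  // --- left end ---
  if (mx[0] < mn[0]) {                   // first extremum is a maximum
    if (x[0] > x[mn[0]]) {               // mirror about the first maximum
      for (int k = std::min(nb, nmx - 1); k >= 1; --k)
        { ltu.push_back(2.0 * mx[0] - mx[k]); lyu.push_back(x[mx[k]]); }
      for (int k = std::min(nb, nmn) - 1; k >= 0; --k)
        { ltl.push_back(2.0 * mx[0] - mn[k]); lyl.push_back(x[mn[k]]); }
    } else {                             // end sample protrudes: anchor it
      for (int k = std::min(nb, nmx) - 1; k >= 0; --k)
        { ltu.push_back(-(double) mx[k]); lyu.push_back(x[mx[k]]); }
      for (int k = std::min(nb - 1, nmn) - 1; k >= 0; --k)
        { ltl.push_back(-(double) mn[k]); lyl.push_back(x[mn[k]]); }
      ltl.push_back(0.0); lyl.push_back(x[0]);
    }
  } else {                               // first extremum is a minimum
    if (x[0] < x[mx[0]]) {
      for (int k = std::min(nb, nmn - 1); k >= 1; --k)
        { ltl.push_back(2.0 * mn[0] - mn[k]); lyl.push_back(x[mn[k]]); }
      for (int k = std::min(nb, nmx) - 1; k >= 0; --k)
        { ltu.push_back(2.0 * mn[0] - mx[k]); lyu.push_back(x[mx[k]]); }
    } else {
      for (int k = std::min(nb, nmn) - 1; k >= 0; --k)
        { ltl.push_back(-(double) mn[k]); lyl.push_back(x[mn[k]]); }
      for (int k = std::min(nb - 1, nmx) - 1; k >= 0; --k)
        { ltu.push_back(-(double) mx[k]); lyu.push_back(x[mx[k]]); }
      ltu.push_back(0.0); lyu.push_back(x[0]);
    }
  }
  // --- right end ---
  double e = (double) (n - 1);
  if (mx[nmx - 1] > mn[nmn - 1]) {       // last extremum is a maximum
    if (x[n - 1] > x[mn[nmn - 1]]) {
      for (int k = 1; k <= std::min(nb, nmx - 1); ++k)
        { rtu.push_back(2.0 * mx[nmx - 1] - mx[nmx - 1 - k]); ryu.push_back(x[mx[nmx - 1 - k]]); }
      for (int k = 0; k < std::min(nb, nmn); ++k)
        { rtl.push_back(2.0 * mx[nmx - 1] - mn[nmn - 1 - k]); ryl.push_back(x[mn[nmn - 1 - k]]); }
    } else {
      rtl.push_back(e); ryl.push_back(x[n - 1]);
      for (int k = 0; k < std::min(nb, nmx); ++k)
        { rtu.push_back(2.0 * e - mx[nmx - 1 - k]); ryu.push_back(x[mx[nmx - 1 - k]]); }
      for (int k = 0; k < std::min(nb - 1, nmn); ++k)
        { rtl.push_back(2.0 * e - mn[nmn - 1 - k]); ryl.push_back(x[mn[nmn - 1 - k]]); }
    }
  } else {                               // last extremum is a minimum
    if (x[n - 1] < x[mx[nmx - 1]]) {
      for (int k = 1; k <= std::min(nb, nmn - 1); ++k)
        { rtl.push_back(2.0 * mn[nmn - 1] - mn[nmn - 1 - k]); ryl.push_back(x[mn[nmn - 1 - k]]); }
      for (int k = 0; k < std::min(nb, nmx); ++k)
        { rtu.push_back(2.0 * mn[nmn - 1] - mx[nmx - 1 - k]); ryu.push_back(x[mx[nmx - 1 - k]]); }
    } else {
      rtu.push_back(e); ryu.push_back(x[n - 1]);
      for (int k = 0; k < std::min(nb, nmn); ++k)
        { rtl.push_back(2.0 * e - mn[nmn - 1 - k]); ryl.push_back(x[mn[nmn - 1 - k]]); }
      for (int k = 0; k < std::min(nb - 1, nmx); ++k)
        { rtu.push_back(2.0 * e - mx[nmx - 1 - k]); ryu.push_back(x[mx[nmx - 1 - k]]); }
    }
  }
  // assemble: left extension + interior extrema + right extension
  auto assemble = [&](std::vector<double>& t, std::vector<double>& y,
                      std::vector<double>& lt, std::vector<double>& ly,
                      const std::vector<int>& idx,
                      std::vector<double>& rt, std::vector<double>& ry) {
    for (size_t k = 0; k < lt.size(); ++k) { t.push_back(lt[k]); y.push_back(ly[k]); }
    for (size_t k = 0; k < idx.size(); ++k) { t.push_back((double) idx[k]); y.push_back(x[idx[k]]); }
    for (size_t k = 0; k < rt.size(); ++k) { t.push_back(rt[k]); y.push_back(ry[k]); }
    // guarantee coverage of [0, n-1]
    if (t.front() > 0.0) { t.insert(t.begin(), -1.0); y.insert(y.begin(), y.front()); }
    if (t.back() < e) { t.push_back(e + 1.0); y.push_back(y.back()); }
    // strictly increasing knots
    std::vector<double> tt, yy;
    for (size_t k = 0; k < t.size(); ++k)
      if (tt.empty() || t[k] > tt.back()) { tt.push_back(t[k]); yy.push_back(y[k]); }
    t.swap(tt); y.swap(yy);
  };
  assemble(tu, yu, ltu, lyu, mx, rtu, ryu);
  assemble(tl, yl, ltl, lyl, mn, rtl, ryl);
}

static bool envelope_pair(const double* x, int n,
                          std::vector<double>& upper, std::vector<double>& lower) {
  std::vector<int> mx, mn;
  find_extrema(x, n, mx, mn);
  if ((int) mx.size() < 2 || (int) mn.size() < 2) return false;
  std::vector<double> tu, yu, tl, yl;
  extend_pair(mx, mn, x, n, tu, yu, tl, yl);
  spline_eval(tu, yu, n, upper);
  spline_eval(tl, yl, n, lower);
  return true;
}

// ---------------------------------------------------------------------------
// Sift one IMF. S-number stopping: the candidate is accepted when the IMF
// zero-crossing property holds (extrema and zero-crossing counts differ by at
// most one) and both counts have remained unchanged for `s_number`
// consecutive sifts, with a hard cap of `max_sift` iterations.
// Returns false when the signal has too few extrema to sift.
// ---------------------------------------------------------------------------
static bool sift_one(const std::vector<double>& x, int s_number, int max_sift,
                     std::vector<double>& imf) {
  int n = (int) x.size();
  imf = x;
  std::vector<double> upper, lower;
  int prev_ext = -1, prev_zc = -1, s_count = 0;
  for (int it = 0; it < max_sift; ++it) {
    if (!envelope_pair(imf.data(), n, upper, lower)) {
      if (it == 0) return false;       // not siftable at all
      break;                            // accept current candidate
    }
    for (int i = 0; i < n; ++i) imf[i] -= 0.5 * (upper[i] + lower[i]);
    std::vector<int> mx, mn;
    find_extrema(imf.data(), n, mx, mn);
    int ext = (int) (mx.size() + mn.size());
    int zc = count_zero_crossings(imf.data(), n);
    if (std::abs(ext - zc) <= 1 && ext == prev_ext && zc == prev_zc) {
      if (++s_count >= s_number) break;
    } else {
      s_count = 0;
    }
    prev_ext = ext; prev_zc = zc;
  }
  return true;
}

// [[Rcpp::export(name = ".sift_c")]]
List sift_c(NumericVector x, int s_number = 4, int max_sift = 50) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> imf;
  bool ok = sift_one(xs, s_number, max_sift, imf);
  if (!ok) return List::create(_["siftable"] = false);
  NumericVector out(imf.begin(), imf.end());
  return List::create(_["siftable"] = true, _["imf"] = out);
}

// [[Rcpp::export(name = ".emd_c")]]
List emd_c(NumericVector x, int max_imf, int s_number = 4, int max_sift = 50) {
  int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  std::vector<int> mx, mn;
  for (int k = 0; k < max_imf; ++k) {
    find_extrema(r.data(), n, mx, mn);
    if ((int) (mx.size() + mn.size()) < 4) break;   // monotone-ish: residue
    std::vector<double> imf;
    if (!sift_one(r, s_number, max_sift, imf)) break;
    imfs.push_back(imf);
    for (int i = 0; i < n; ++i) r[i] -= imf[i];
  }
  int K = (int) imfs.size();
  NumericMatrix M(n, K);
  for (int k = 0; k < K; ++k)
    std::copy(imfs[k].begin(), imfs[k].end(), M(_, k).begin());
  NumericVector res(r.begin(), r.end());
  return List::create(_["imfs"] = M, _["residue"] = res);
}

// [[Rcpp::export(name = ".extrema_c")]]
List extrema_c(NumericVector x) {
  std::vector<int> mx, mn;
  find_extrema(REAL(x), x.size(), mx, mn);
  IntegerVector a(mx.size()), b(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) a[i] = mx[i] + 1;
  for (size_t i = 0; i < mn.size(); ++i) b[i] = mn[i] + 1;
  return List::create(_["maxima"] = a, _["minima"] = b,
                      _["zero_crossings"] = count_zero_crossings(REAL(x), x.size()));
}

// Spline through the maxima of |x| (amplitude envelope). Returns a vector of
// length n, or NULL when |x| has fewer than 2 maxima.
// [[Rcpp::export(name = ".envelope_c")]]
SEXP envelope_c(NumericVector x) {
  int n = x.size();
  std::vector<double> ax(n);
  for (int i = 0; i < n; ++i) ax[i] = std::fabs(x[i]);
  std::vector<int> mx, mn;
  find_extrema(ax.data(), n, mx, mn);
  if ((int) mx.size() < 2) return R_NilValue;
  std::vector<double> t, y, env;
  mirrored_knots(mx, ax.data(), n, t, y);
  spline_eval(t, y, n, env);
  return NumericVector(env.begin(), env.end());
}

// ---------------------------------------------------------------------------
// Connected components of supra-threshold cells under a CSR adjacency,
// positive and negative clusters formed separately.
// adj_ptr: 0-based row pointers (length ncell+1); adj_idx: 0-based neighbors.
// ---------------------------------------------------------------------------
static void flood(const IntegerVector& ptr, const IntegerVector& idx,
                  const std::vector<char>& in_set, std::vector<int>& label,
                  int start, int lab, std::vector<int>& stack) {
  stack.clear(); stack.push_back(start); label[start] = lab;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = idx[e];
      if (in_set[u] && label[u] == 0) { label[u] = lab; stack.push_back(u); }
    }
  }
}

// [[Rcpp::export(name = ".cluster_label_c")]]
List cluster_label_c(NumericVector t, double thr,
                     IntegerVector adj_ptr, IntegerVector adj_idx) {
  int n = t.size();
  std::vector<char> pos(n), neg(n);
  for (int i = 0; i < n; ++i) { pos[i] = t[i] > thr; neg[i] = t[i] < -thr; }
  std::vector<int> label(n, 0), stack;
  int lab = 0;
  for (int i = 0; i < n; ++i)
    if (pos[i] && label[i] == 0) flood(adj_ptr, adj_idx, pos, label, i, ++lab, stack);
  for (int i = 0; i < n; ++i)
    if (neg[i] && label[i] == 0) flood(adj_ptr, adj_idx, neg, label, i, ++lab, stack);
  NumericVector mass(lab);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = label[i];
    if (label[i] > 0) mass[label[i] - 1] += t[i];
  }
  return List::create(_["labels"] = out, _["mass"] = mass);
}

// Max |cluster mass| for each column of a t-statistic matrix (cells x perms).
// [[Rcpp::export(name = ".perm_max_mass_c")]]
NumericVector perm_max_mass_c(NumericMatrix T, double thr,
                              IntegerVector adj_ptr, IntegerVector adj_idx) {
  int n = T.nrow(), P = T.ncol();
  NumericVector out(P);
  std::vector<char> pos(n), neg(n);
  std::vector<int> label(n), stack;
  for (int p = 0; p < P; ++p) {
    const double* t = &T(0, p);
    for (int i = 0; i < n; ++i) { pos[i] = t[i] > thr; neg[i] = t[i] < -thr; }
    std::fill(label.begin(), label.end(), 0);
    int lab = 0;
    double best = 0.0;
    for (int sgn = 0; sgn < 2; ++sgn) {
      const std::vector<char>& set = sgn ? neg : pos;
      for (int i = 0; i < n; ++i) {
        if (set[i] && label[i] == 0) {
          flood(adj_ptr, adj_idx, set, label, i, ++lab, stack);
          // recompute mass of this component
          double m = 0.0;
          for (int j = i; j < n; ++j) if (label[j] == lab) m += t[j];
          if (std::fabs(m) > best) best = std::fabs(m);
        }
      }
    }
    out[p] = best;
  }
  return out;
}
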