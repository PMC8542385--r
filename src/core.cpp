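#include <Rcpp.h>
#include <vector>
#include <limits>
#include <queue>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower-envelope algorithm).
// f: input squared distances (INF where no site), d: output.
static void edt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                  std::vector<int> &v, std::vector<double> &z) {
  static const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// 2-D squared EDT over a rectangular window [r0, r1] x [c0, c1]; sites
// outside the window are ignored (callers guarantee the component lies
// inside). `out` is window-local, row-major within the window.
static void edt2d_window(const std::vector<char> &site, int nr,
                         std::vector<double> &out, int r0, int r1, int c0,
                         int c1, std::vector<double> &f,
                         std::vector<double> &d, std::vector<int> &v,
                         std::vector<double> &z) {
  static const double INF = std::numeric_limits<double>::infinity();
  int wr = r1 - r0 + 1, wc = c1 - c0 + 1;
  // pass over columns
  for (int c = 0; c < wc; c++) {
    bool any = false;
    for (int r = 0; r < wr; r++) {
      char s = site[(r0 + r) + (c0 + c) * nr];
      f[r] = s ? 0.0 : INF;
      any = any || s;
    }
    if (!any) {
      for (int r = 0; r < wr; r++) out[r + c * wr] = INF;
      continue;
    }
    edt1d(f, d, wr, v, z);
    for (int r = 0; r < wr; r++) out[r + c * wr] = d[r];
  }
  // pass over rows
  for (int r = 0; r < wr; r++) {
    bool any = false;
    for (int c = 0; c < wc; c++) {
      f[c] = out[r + c * wr];
      any = any || (f[c] < INF);
    }
    if (!any) continue;  // row stays INF
    edt1d(f, d, wc, v, z);
    for (int c = 0; c < wc; c++) out[r + c * wr] = d[c];
  }
}

// Assign every pixel to the nearest labelled component (exact squared
// Euclidean distance to any pixel of the component); ties go to the
// smaller label.  A global all-site EDT bounds each label's reach: label
// l can win pixel p only if the distance from p to l's bounding box is at
// most sqrt(D[p]), so each label's EDT runs on a pruned window.
// [[Rcpp::export]]
List cpp_voronoi_labels(IntegerMatrix labels) {
  static const double INF = std::numeric_limits<double>::infinity();
  int nr = labels.nrow(), nc = labels.ncol(), n = nr * nc;
  int nlab = 0;
  for (int i = 0; i < n; i++) nlab = std::max(nlab, labels[i]);
  if (nlab < 1) stop("no labelled components");
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // global EDT over all sites
  std::vector<char> site(n);
  for (int i = 0; i < n; i++) site[i] = labels[i] > 0;
  std::vector<double> D(n);
  edt2d_window(site, nr, D, 0, nr - 1, 0, nc - 1, f, d, v, z);

  // label bounding boxes
  std::vector<int> bR0(nlab, nr), bR1(nlab, -1), bC0(nlab, nc), bC1(nlab, -1);
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      int l = labels(r, c);
      if (l > 0) {
        int k = l - 1;
        bR0[k] = std::min(bR0[k], r); bR1[k] = std::max(bR1[k], r);
        bC0[k] = std::min(bC0[k], c); bC1[k] = std::max(bC1[k], c);
      }
    }

  // candidate windows: expand each label's bbox by every pixel whose
  // global nearest-site distance reaches the bbox
  std::vector<int> wR0(bR0), wR1(bR1), wC0(bC0), wC1(bC1);
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      double rad2 = D[r + c * nr];
      for (int k = 0; k < nlab; k++) {
        if (bR1[k] < 0) continue;
        double dr = (r < bR0[k]) ? bR0[k] - r : (r > bR1[k] ? r - bR1[k] : 0);
        double dc = (c < bC0[k]) ? bC0[k] - c : (c > bC1[k] ? c - bC1[k] : 0);
        if (dr * dr + dc * dc <= rad2) {
          wR0[k] = std::min(wR0[k], r); wR1[k] = std::max(wR1[k], r);
          wC0[k] = std::min(wC0[k], c); wC1[k] = std::max(wC1[k], c);
        }
      }
    }

  IntegerMatrix assign(nr, nc);
  NumericMatrix best(nr, nc);
  std::fill(best.begin(), best.end(), INF);
  std::vector<double> d2;
  for (int l = 1; l <= nlab; l++) {
    int k = l - 1;
    if (bR1[k] < 0) continue;  // label absent
    // refresh site flags within the window only (the EDT reads only there)
    for (int c = wC0[k]; c <= wC1[k]; c++)
      for (int r = wR0[k]; r <= wR1[k]; r++)
        site[r + c * nr] = (labels[r + c * nr] == l);
    int wr = wR1[k] - wR0[k] + 1, wc = wC1[k] - wC0[k] + 1;
    d2.resize((size_t)wr * wc);
    edt2d_window(site, nr, d2, wR0[k], wR1[k], wC0[k], wC1[k], f, d, v, z);
    for (int c = 0; c < wc; c++)
      for (int r = 0; r < wr; r++) {
        double val = d2[r + c * wr];
        int gi = (wR0[k] + r) + (wC0[k] + c) * nr;
        if (val < best[gi]) {  // strict: smaller label keeps ties
          best[gi] = val;
          assign[gi] = l;
        }
      }
  }
  return List::create(_["assign"] = assign, _["dist2"] = best);
}

// Connected-component labelling of a binary mask, 4- or 8-connectivity,
// labels assigned in raster-scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      next++;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; k++) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
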