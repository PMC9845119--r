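#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012),
// lower envelope of parabolas rooted at f.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared EDT of an nr x nc grid of seed costs (0 at feature pixels, DT_INF
// elsewhere), in place.
static void edt2d(std::vector<double>& g, int nr, int nc) {
  int n = std::max(nr, nc);
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  for (int c = 0; c < nc; c++) {           // along columns
    for (int r = 0; r < nr; r++) f[r] = g[(size_t)r * nc + c];
    edt1d(f, d, v, z, nr);
    for (int r = 0; r < nr; r++) g[(size_t)r * nc + c] = d[r];
  }
  for (int r = 0; r < nr; r++) {           // along rows
    for (int c = 0; c < nc; c++) f[c] = g[(size_t)r * nc + c];
    edt1d(f, d, v, z, nc);
    for (int c = 0; c < nc; c++) g[(size_t)r * nc + c] = d[c];
  }
}

// Exact Euclidean distance (in pixels) from each foreground pixel to the
// nearest background pixel; the image border counts as background, so the
// grid is padded by one zero ring before the transform. Background pixels
// return 0.
// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int pr = nr + 2, pc = nc + 2;
  std::vector<double> g((size_t)pr * pc, 0.0);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (mask(r, c) != 0) g[(size_t)(r + 1) * pc + (c + 1)] = DT_INF;
  edt2d(g, pr, pc);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      out(r, c) = mask(r, c) == 0 ? 0.0 : std::sqrt(g[(size_t)(r + 1) * pc + (c + 1)]);
  return out;
}

// Distance from every pixel to the nearest pixel of `set` (1 = member).
// No border padding: pixels outside the grid are not members. Used for
// crown dilation (buffering). Returns Inf if the set is empty.
// [[Rcpp::export]]
NumericMatrix edt_to_set_cpp(IntegerMatrix set) {
  int nr = set.nrow(), nc = set.ncol();
  std::vector<double> g((size_t)nr * nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      g[(size_t)r * nc + c] = set(r, c) != 0 ? 0.0 : DT_INF;
  edt2d(g, nr, nc);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++) {
      double v = g[(size_t)r * nc + c];
      out(r, c) = v >= DT_INF ? R_PosInf : std::sqrt(v);
    }
  return out;
}

// m x m grey-level maximum filter, window clipped at the grid edge.
// [[Rcpp::export]]
NumericMatrix maxfilter_cpp(NumericMatrix x, int m) {
  if (m < 1 || m % 2 == 0) stop("m must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), h = m / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; r++) {
    int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
    for (int c = 0; c < nc; c++) {
      int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      double best = -DT_INF;
      for (int rr = r0; rr <= r1; rr++)
        for (int cc = c0; cc <= c1; cc++)
          if (x(rr, cc) > best) best = x(rr, cc);
      out(r, c) = best;
    }
  }
  return out;
}

// Connected-component labelling of non-zero pixels, 4- or 8-connectivity.
// Components are numbered in row-major discovery order, so the first pixel
// of component k (scanning rows top to bottom, columns left to right) is the
// smallest row-major pixel of that component.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int j = 0; j < nd; j++) {
          int rr = p.first + dr[j], cc = p.second + dc[j];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) == 0 || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}

// Count background pixels on the Bresenham line from (r0,c0) to (r1,c1),
// both endpoints excluded.
static int bres_bg(const IntegerMatrix& mask, int r0, int c0, int r1, int c1) {
  int dr = std::abs(r1 - r0), dc = std::abs(c1 - c0);
  int sr = r0 < r1 ? 1 : -1, sc = c0 < c1 ? 1 : -1;
  int err = dc - dr;
  int r = r0, c = c0, cnt = 0;
  while (!(r == r1 && c == c1)) {
    int e2 = 2 * err;
    if (e2 > -dr) { err -= dr; c += sc; }
    if (e2 < dc)  { err += dc; r += sr; }
    if (r == r1 && c == c1) break;
    if (mask(r, c) == 0) cnt++;
  }
  return cnt;
}

// Assign every foreground pixel to the centre minimising
//   d(x, c) = ||x - c||_2 + lambda * (# background pixels on the Bresenham
//             line from c to x, endpoints excluded),
// ties going to the smallest centre index. `centres` is a k x 2 matrix of
// 1-based (row, col). Centres are visited in increasing Euclidean distance
// (stable on the original index), and a centre is skipped once its plain
// Euclidean distance exceeds the best penalised distance found so far: the
// penalty is non-negative, so such a centre can neither win nor tie. The
// result is therefore identical to exhaustive evaluation.
// [[Rcpp::export]]
IntegerMatrix relabel_cpp(IntegerMatrix mask, IntegerMatrix centres,
                          double lambda) {
  int nr = mask.nrow(), nc = mask.ncol(), k = centres.nrow();
  if (k < 1) stop("at least one centre is required");
  if (lambda < 0) stop("penalty_weight must be >= 0");
  IntegerMatrix lab(nr, nc);
  std::vector<double> eu(k);
  std::vector<int> ord(k);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (mask(r, c) == 0) continue;
      for (int j = 0; j < k; j++) {
        double drr = r - (centres(j, 0) - 1);
        double dcc = c - (centres(j, 1) - 1);
        eu[j] = std::sqrt(drr * drr + dcc * dcc);
        ord[j] = j;
      }
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return eu[a] < eu[b] || (eu[a] == eu[b] && a < b);
      });
      double bestd = std::numeric_limits<double>::infinity();
      int best = -1;
      for (int t = 0; t < k; t++) {
        int j = ord[t];
        if (eu[j] > bestd) break;
        double d = eu[j];
        if (lambda > 0)
          d += lambda * bres_bg(mask, centres(j, 0) - 1, centres(j, 1) - 1, r, c);
        if (d < bestd || (d == bestd && j < best)) { bestd = d; best = j; }
      }
      lab(r, c) = best + 1;
    }
  }
  return lab;
}
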