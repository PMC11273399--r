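#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
// f: input squared distances, d: output, n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest TRUE pixel.
// Pixels with no TRUE anywhere get Inf.
// [[Rcpp::export]]
NumericMatrix sqdist_to_true(LogicalMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix out(nr, nc);
  const double INF = std::numeric_limits<double>::infinity();
  // pass 1: per column, squared distance along rows
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sites(i, j) ? 0.0 : INF;
    // 1-D transform degenerates with all-Inf input; handle by scan instead
    bool any = false;
    for (int i = 0; i < nr; ++i) if (sites(i, j)) { any = true; break; }
    if (!any) {
      for (int i = 0; i < nr; ++i) out(i, j) = INF;
      continue;
    }
    // forward/backward scan gives exact 1-D distance
    double prev = INF;
    for (int i = 0; i < nr; ++i) {
      if (sites(i, j)) prev = 0.0; else if (prev != INF) prev += 1.0;
      d[i] = prev;
    }
    prev = INF;
    for (int i = nr - 1; i >= 0; --i) {
      if (sites(i, j)) prev = 0.0; else if (prev != INF) prev += 1.0;
      if (prev < d[i]) d[i] = prev;
    }
    for (int i = 0; i < nr; ++i) out(i, j) = d[i] == INF ? INF : d[i] * d[i];
  }
  // pass 2: per row, lower envelope across columns
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; ++i) {
    bool allinf = true;
    for (int j = 0; j < nc; ++j) {
      fr[j] = out(i, j);
      if (fr[j] != INF) allinf = false;
    }
    if (allinf) continue;
    // replace Inf with a large finite sentinel for the envelope
    double big = 1.0 + (double)nr * nr + (double)nc * nc;
    for (int j = 0; j < nc; ++j) if (fr[j] == INF) fr[j] = big * 4.0;
    dt1d(fr, dr, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = dr[j] >= big ? INF : dr[j];
  }
  return out;
}

// Connected-component labels (BFS in raster order, so label 1 has the
// smallest top-left pixel). connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nnb = connectivity == 8 ? 8 : 4;
  const int* drs = connectivity == 8 ? dr8 : dr4;
  const int* dcs = connectivity == 8 ? dc8 : dc4;
  std::queue<std::pair<int, int> > q;
  // raster order: column-major would be R's order; spec's top-left tie break
  // wants row-major scan (topmost then leftmost)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          int ii = p.first + drs[k], jj = p.second + dcs[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Moore-neighbour boundary trace, clockwise, starting at the
// topmost-then-leftmost foreground pixel. Returns an n x 2 matrix of
// 1-based (row, col). Stops on Jacob's criterion (start pixel re-entered
// from the same direction as the first entry).
// [[Rcpp::export]]
IntegerMatrix trace_contour_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // clockwise neighbour ring starting at W: W, NW, N, NE, E, SE, S, SW
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int sr = -1, sc = -1;
  for (int i = 0; i < nr && sr < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (mask(i, j)) { sr = i; sc = j; break; }
  if (sr < 0) stop("mask has no foreground pixels");
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // backtrack direction: from current pixel towards the last background
  // neighbour examined; starts at W of the start pixel (bg or outside,
  // since start is topmost-then-leftmost)
  int cr = sr, cc = sc, bdir = 0;
  int first_dir = -1;
  long guard = 8L * (long)nr * (long)nc + 16;
  while (guard-- > 0) {
    int found = -1, prev = bdir;
    for (int k = 1; k <= 8; ++k) {
      int d = (bdir + k) % 8;
      int ii = cr + dr[d], jj = cc + dc[d];
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && mask(ii, jj)) {
        found = d;
        break;
      }
      prev = d;
    }
    if (found < 0) break; // isolated pixel: contour is the single start pixel
    if (cr == sr && cc == sc) {
      if (first_dir < 0) first_dir = found;
      else if (found == first_dir) break; // full loop completed
    }
    // background neighbour just before the hit, in coords of the new pixel
    int br = cr + dr[prev], bc = cc + dc[prev];
    cr += dr[found];
    cc += dc[found];
    int vr = br - cr, vc = bc - cc;
    for (int d = 0; d < 8; ++d)
      if (dr[d] == vr && dc[d] == vc) { bdir = d; break; }
    rows.push_back(cr);
    cols.push_back(cc);
  }
  // drop the closing revisit of the start pixel, if any
  if (rows.size() > 1 && rows.back() == sr && cols.back() == sc) {
    rows.pop_back();
    cols.pop_back();
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t t = 0; t < rows.size(); ++t) {
    out(t, 0) = rows[t] + 1;
    out(t, 1) = cols[t] + 1;
  }
  return out;
}
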