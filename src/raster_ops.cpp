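#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect an index into [0, n). Mirror-without-repeat ("reflect" padding):
// -1 -> 0, -2 -> 1, n -> n-1, ...
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Copy img into a buffer padded by `pad` on every side with reflected
// ("mirror, no repeat") borders, so neighbourhood kernels need no bounds
// checks in their inner loops.
static std::vector<double> padReflect(const NumericMatrix &img, int pad,
                                      int &nrp) {
  const int nr = img.nrow(), nc = img.ncol();
  nrp = nr + 2 * pad;
  const int ncp = nc + 2 * pad;
  std::vector<double> out((size_t)nrp * ncp);
  for (int c = 0; c < ncp; ++c) {
    const int sc = refl(c - pad, nc);
    double *dst = &out[(size_t)c * nrp];
    for (int r = 0; r < nrp; ++r)
      dst[r] = img(refl(r - pad, nr), sc);
  }
  return out;
}

// Rank (median) filter over an arbitrary neighbourhood given as offsets.
// Offsets are (dRow, dCol) pairs; edges handled by reflection.
// [[Rcpp::export(name = ".cppRankMedian")]]
NumericMatrix cppRankMedian(const NumericMatrix img,
                            const IntegerVector dRow,
                            const IntegerVector dCol) {
  const int nr = img.nrow(), nc = img.ncol(), k = dRow.size();
  int pad = 0;
  for (int j = 0; j < k; ++j)
    pad = std::max(pad, std::max(abs(dRow[j]), abs(dCol[j])));
  int nrp;
  std::vector<double> padBuf = padReflect(img, pad, nrp);
  // linear offsets into the padded buffer
  std::vector<long> off(k);
  for (int j = 0; j < k; ++j)
    off[j] = (long)dCol[j] * nrp + dRow[j];
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  const int mid = k / 2;
  for (int c = 0; c < nc; ++c) {
    const double *base = &padBuf[(size_t)(c + pad) * nrp + pad];
    for (int r = 0; r < nr; ++r) {
      for (int j = 0; j < k; ++j) buf[j] = base[r + off[j]];
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        m = 0.5 * (m + buf[mid - 1]);
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Grayscale erosion (dilate = false) or dilation (dilate = true) with a
// possibly non-flat structuring function. heights[j] is the structuring
// element height at offset j (0 everywhere for a flat element).
// Erosion:  out(p) = min_j img(p + o_j) - h_j
// Dilation: out(p) = max_j img(p - o_j) + h_j
// Reflect padding at the edges. Offset-major loops over a padded buffer
// keep the passes sequential in memory.
// [[Rcpp::export(name = ".cppGrayMorph")]]
NumericMatrix cppGrayMorph(const NumericMatrix img,
                           const IntegerVector dRow,
                           const IntegerVector dCol,
                           const NumericVector heights,
                           const bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), k = dRow.size();
  int pad = 0;
  for (int j = 0; j < k; ++j)
    pad = std::max(pad, std::max(abs(dRow[j]), abs(dCol[j])));
  int nrp;
  std::vector<double> padBuf = padReflect(img, pad, nrp);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), dilate ? R_NegInf : R_PosInf);
  double *po = out.begin();
  for (int j = 0; j < k; ++j) {
    const int dr = dilate ? -dRow[j] : dRow[j];
    const int dc = dilate ? -dCol[j] : dCol[j];
    const double h = dilate ? heights[j] : -heights[j];
    for (int c = 0; c < nc; ++c) {
      const double *ps = &padBuf[(size_t)(c + pad + dc) * nrp + pad + dr];
      double *pd = po + (size_t)c * nr;
      if (dilate) {
        for (int r = 0; r < nr; ++r) {
          const double v = ps[r] + h;
          if (v > pd[r]) pd[r] = v;
        }
      } else {
        for (int r = 0; r < nr; ++r) {
          const double v = ps[r] + h;
          if (v < pd[r]) pd[r] = v;
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask, 4- or 8-connectivity.
// Labels are assigned in raster-scan (row-major, top-left first) order of
// the first pixel encountered, so the result is deterministic.
// [[Rcpp::export(name = ".cppLabel")]]
IntegerMatrix cppLabel(const LogicalMatrix mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int j = 0; j < nn; ++j) {
          int qr = pr + dr[j], qc = pc + dc[j];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && !lab(qr, qc)) {
            lab(qr, qc) = next;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  return lab;
}

// Fill enclosed holes: background is flood-filled from the image border with
// the connectivity complementary to the foreground's (8-conn foreground pairs
// with 4-conn background and vice versa); unreached background becomes
// foreground.
// [[Rcpp::export(name = ".cppFillHoles")]]
LogicalMatrix cppFillHoles(const LogicalMatrix mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int bgConn = (connectivity == 8) ? 4 : 8;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (bgConn == 8) ? dr8 : dr4;
  const int *dc = (bgConn == 8) ? dc8 : dc4;
  const int nn = (bgConn == 8) ? 8 : 4;
  LogicalMatrix seen(nr, nc);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) &&
          !mask(r, c) && !seen(r, c)) {
        seen(r, c) = true;
        stack.push_back(r * nc + c);
        while (!stack.empty()) {
          int p = stack.back();
          stack.pop_back();
          int pr = p / nc, pc = p % nc;
          for (int j = 0; j < nn; ++j) {
            int qr = pr + dr[j], qc = pc + dc[j];
            if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
            if (!mask(qr, qc) && !seen(qr, qc)) {
              seen(qr, qc) = true;
              stack.push_back(qr * nc + qc);
            }
          }
        }
      }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = mask(r, c) || !seen(r, c);
  return out;
}

// Trace the outer boundary of one labelled region through boundary PIXEL
// CENTRES with 8-connected moves (Moore contour, clockwise in screen
// convention). Returns an m x 2 matrix of (x = col, y = row) 0-based
// centre coordinates in traversal order; the polygon closes implicitly.
// Axial steps have length 1 and diagonal steps sqrt(2), which is the
// perimeter estimator used by the particle analysis.
// [[Rcpp::export(name = ".cppContourTrace")]]
IntegerMatrix cppContourTrace(const IntegerMatrix lab, const int label) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  auto inside = [&](int x, int y) {
    return x >= 0 && x < nc && y >= 0 && y < nr && lab(y, x) == label;
  };
  // 8 neighbours in clockwise order (screen convention, y down),
  // starting west
  const int nx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int ny[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  auto dirIndex = [&](int dx, int dy) {
    for (int d = 0; d < 8; ++d)
      if (nx[d] == dx && ny[d] == dy) return d;
    stop("internal error: invalid backtrack offset");
    return -1;
  };
  std::vector<int> vx, vy;
  int px = sc, py = sr;
  int bx = sc - 1, by = sr;   // backtrack: west of start (background)
  vx.push_back(px); vy.push_back(py);
  int firstDir = -1;
  int guard = 8 * (nr + 2) * (nc + 2);
  while (guard-- > 0) {
    const int d0 = dirIndex(bx - px, by - py);
    int found = -1;
    for (int s = 1; s <= 8; ++s) {
      int d = (d0 + s) % 8;
      int qx = px + nx[d], qy = py + ny[d];
      if (inside(qx, qy)) { found = d; break; }
      bx = qx; by = qy;  // last background cell examined
    }
    if (found < 0) break;  // isolated pixel
    // full cycle: about to repeat the first move from the start pixel
    if (firstDir >= 0 && px == sc && py == sr && found == firstDir) break;
    if (firstDir < 0) firstDir = found;
    px += nx[found];
    py += ny[found];
    if (!(px == sc && py == sr)) { vx.push_back(px); vy.push_back(py); }
  }
  if (guard <= 0) stop("contour trace failed to terminate");
  IntegerMatrix out(vx.size(), 2);
  for (size_t i = 0; i < vx.size(); ++i) {
    out(i, 0) = vx[i];
    out(i, 1) = vy[i];
  }
  return out;
}

// Trace the outer crack boundary of one labelled region. The boundary runs
// along pixel edges; returned vertices are pixel-corner coordinates (x, y),
// 0-based, x = column, y = row, traversed clockwise in screen convention
// (y pointing down) with the region kept on the right. Collinear runs are
// merged, so every vertex is a 90-degree corner. The total length of the
// polygon in unit steps equals the number of crack edges E, and the number of
// vertices equals the corner count C used by the traced-perimeter estimator
// P = E - C (2 - sqrt(2)).
// [[Rcpp::export(name = ".cppTraceOutline")]]
IntegerMatrix cppTraceOutline(const IntegerMatrix lab, const int label,
                              const int connectivity) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // inside test in corner space: pixel (x = col, y = row)
  auto inside = [&](int x, int y) {
    return x >= 0 && x < nc && y >= 0 && y < nr && lab(y, x) == label;
  };
  // directions: 0 = +x (R), 1 = +y (D), 2 = -x (L), 3 = -y (U)
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  const int startx = sc, starty = sr;
  // the walk always re-enters the start corner (top-left corner of the
  // topmost-then-leftmost region pixel) moving upward along the pixel's
  // left edge, so (start corner, incoming direction U) is the stop state
  int cx = sc, cy = sr, d = 3;
  bool first = true;
  std::vector<int> vx, vy;
  int guard = 8 * (nr + 2) * (nc + 2);
  while (true) {
    if (!first && cx == startx && cy == starty && d == 3) break;
    first = false;
    // pixels ahead of corner (cx, cy) relative to direction d
    int rax, ray, lax, lay;
    switch (d) {
      case 0: rax = cx;     ray = cy;     lax = cx;     lay = cy - 1; break;
      case 1: rax = cx - 1; ray = cy;     lax = cx;     lay = cy;     break;
      case 2: rax = cx - 1; ray = cy - 1; lax = cx - 1; lay = cy;     break;
      default: rax = cx;    ray = cy - 1; lax = cx - 1; lay = cy - 1; break;
    }
    const bool ra = inside(rax, ray), la = inside(lax, lay);
    int nd;
    if (ra && la) nd = (d + 3) % 4;                               // turn left
    else if (ra) nd = d;                                          // straight
    // checkerboard pinch: diagonal pixels meet at this corner; with
    // 8-connectivity they are one region (wrap around, turn left), with
    // 4-connectivity they are not traversed together (turn right)
    else if (la) nd = (connectivity == 8) ? (d + 3) % 4 : (d + 1) % 4;
    else nd = (d + 1) % 4;                                        // turn right
    if (nd != d) { vx.push_back(cx); vy.push_back(cy); }
    d = nd;
    cx += dx[d];
    cy += dy[d];
    if (--guard < 0) stop("boundary trace failed to terminate");
  }
  IntegerMatrix out(vx.size(), 2);
  for (size_t i = 0; i < vx.size(); ++i) {
    out(i, 0) = vx[i];
    out(i, 1) = vy[i];
  }
  return out;
}
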