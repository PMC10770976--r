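#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected component labelling of a logical matrix.
// Returns an integer matrix: 0 background, 1..k component ids.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& bin) {
  int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!bin(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (bin(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Crack-boundary tracing: follows the polygon of pixel EDGES separating the
// region from background, so vertices sit at half-integer coordinates
// (pixel corners). Input: logical matrix holding ONE connected region.
// Output: n x 2 matrix of (x = col - 0.5 offsets, y likewise) corner
// coordinates, starting at the top-left corner of the topmost-then-leftmost
// region pixel, walked with the region on the right (positive shoelace area
// in x-right/y-down coordinates). Turn preference left-straight-right keeps
// 8-connected regions on a single loop.
// [[Rcpp::export(name = ".cpp_trace_boundary")]]
NumericMatrix cpp_trace_boundary(const LogicalMatrix& bin) {
  int H = bin.nrow(), W = bin.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (bin(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) return NumericMatrix(0, 2);

  // corner (i, j) = point (x = j - 0.5, y = i - 0.5); fg() is safe lookup
  #define FG(r, c) ((r) >= 0 && (r) < H && (c) >= 0 && (c) < W && bin((r), (c)))
  // directions on the corner grid: 0=E, 1=S, 2=W, 3=N
  const int di[4] = {0, 1, 0, -1};
  const int dj[4] = {1, 0, -1, 0};
  // edge from corner (i,j) in direction d is valid iff the region lies on
  // the right of the walk and background on the left
  struct Valid {
    const LogicalMatrix& b; int H, W;
    bool fg(int r, int c) const {
      return r >= 0 && r < H && c >= 0 && c < W && b(r, c);
    }
    bool operator()(int i, int j, int d) const {
      switch (d) {
        case 0: return  fg(i, j)     && !fg(i - 1, j);     // E: below fg
        case 1: return  fg(i, j - 1) && !fg(i, j);         // S: west fg
        case 2: return  fg(i - 1, j - 1) && !fg(i, j - 1); // W: above fg
        default: return fg(i - 1, j) && !fg(i - 1, j - 1); // N: east fg
      }
    }
  } valid = {bin, H, W};
  #undef FG

  std::vector<double> xs, ys;
  int si = sr, sj = sc; // start corner = top-left corner of start pixel
  int ci = si, cj = sj, d = 0; // initial edge runs east along the pixel top
  long guard = 8L * (H + 1) * (W + 1) + 16;
  while (guard-- > 0) {
    xs.push_back(cj - 0.5); ys.push_back(ci - 0.5);
    ci += di[d]; cj += dj[d];
    // choose the next edge: prefer left turn, then straight, then right
    int nd = -1;
    const int turns[3] = {3, 0, 1}; // offsets mod 4: left, straight, right
    for (int k = 0; k < 3; ++k) {
      int cand = (d + turns[k]) % 4;
      if (valid(ci, cj, cand)) { nd = cand; break; }
    }
    if (nd < 0) break; // dead end: cannot happen on a closed crack boundary
    d = nd;
    if (ci == si && cj == sj && d == 0) break; // about to repeat first edge
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Even-odd point-in-polygon test; points exactly on the boundary count inside.
// px, py: query points; vx, vy: polygon vertices (implicitly closed).
// [[Rcpp::export(name = ".cpp_points_in_polygon")]]
LogicalVector cpp_points_in_polygon(const NumericVector& px, const NumericVector& py,
                                    const NumericVector& vx, const NumericVector& vy) {
  int n = vx.size(), m = px.size();
  LogicalVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = px[q], y = py[q];
    bool inside = false, onb = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = vx[i], yi = vy[i], xj = vx[j], yj = vy[j];
      double ex = xi - xj, ey = yi - yj;
      double len2 = ex * ex + ey * ey;
      double cross = (x - xj) * ey - (y - yj) * ex;
      if (len2 == 0.0) {
        if (x == xj && y == yj) { onb = true; break; }
        continue;
      }
      if (cross * cross <= 1e-18 * len2) { // on the supporting line
        double t = ((x - xj) * ex + (y - yj) * ey) / len2;
        if (t >= -1e-12 && t <= 1.0 + 1e-12) { onb = true; break; }
      }
      if ((yi > y) != (yj > y)) {
        double xint = xj + (y - yj) * ex / ey;
        if (x < xint) inside = !inside;
      }
    }
    out[q] = onb || inside;
  }
  return out;
}

// im2col for a (H, W, C) array (R column-major), zero padding p, stride s,
// square kernel k. Output: (Ho*Wo) x (k*k*C), row = ho + Ho*wo,
// col = kh + k*kw + k*k*c.
// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(const NumericVector& arr, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = &arr[ (R_xlen_t)H * wi + (R_xlen_t)H * W * c ];
          double* dst = &out[ (R_xlen_t)(Ho * Wo) * col + (R_xlen_t)Ho * wo ];
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            if (hi >= 0 && hi < H) dst[ho] = src[hi];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into a (H, W, C) array.
// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(const NumericMatrix& cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector arr((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = &arr[ (R_xlen_t)H * wi + (R_xlen_t)H * W * c ];
          const double* src = &cols[ (R_xlen_t)(Ho * Wo) * col + (R_xlen_t)Ho * wo ];
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            if (hi >= 0 && hi < H) dst[hi] += src[ho];
          }
        }
      }
    }
  }
  arr.attr("dim") = IntegerVector::create(H, W, C);
  return arr;
}
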