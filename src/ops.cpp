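#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays, dim c(H, W, C), column-major: idx(y,x,c) = y + H*(x + W*c).
static inline int idx3(int y, int x, int c, int H, int W) { return y + H * (x + (long)W * c); }

// 2-D convolution (cross-correlation), odd kernel, zero padding, stride 1.
// w has dim c(K, K, Cin, Cout); optional fused ReLU. Implemented as one
// shifted plane accumulation per (kernel tap, ic, oc) so the inner loop is
// contiguous in memory.
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         bool relu) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], Cin = dx[2];
  int K = dw[0], Cout = dw[3];
  int p = K / 2;
  NumericVector out(H * (long)W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *xp = REAL(x), *wp = REAL(w);
  double *op = REAL(out);
  size_t plane = (size_t)H * W;
  for (int oc = 0; oc < Cout; ++oc) {
    double b = bias[oc];
    double *o0 = op + plane * oc;
    for (size_t t = 0; t < plane; ++t) o0[t] = b;
    for (int ic = 0; ic < Cin; ++ic) {
      const double *x0 = xp + plane * ic;
      for (int bk = 0; bk < K; ++bk) {
        int dj = bk - p;
        int j0 = dj < 0 ? -dj : 0, j1 = dj > 0 ? W - dj : W;
        for (int a = 0; a < K; ++a) {
          int di = a - p;
          int i0 = di < 0 ? -di : 0, i1 = di > 0 ? H - di : H;
          double wv = wp[a + K * (bk + K * (ic + (long)Cin * oc))];
          if (wv == 0) continue;
          for (int j = j0; j < j1; ++j) {
            const double *xc = x0 + (size_t)H * (j + dj) + di;
            double *ocol = o0 + (size_t)H * j;
            for (int i = i0; i < i1; ++i) ocol[i] += wv * xc[i];
          }
        }
      }
    }
    if (relu)
      for (size_t t = 0; t < plane; ++t) if (o0[t] < 0) o0[t] = 0;
  }
  return out;
}

// Backward pass for conv2d_fwd. `y` is the (post-ReLU if relu) forward output,
// used to gate dy through the ReLU. Returns dx, dw, db.
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                NumericVector y, bool relu) {
  IntegerVector dxd = x.attr("dim");
  IntegerVector dwd = w.attr("dim");
  int H = dxd[0], W = dxd[1], Cin = dxd[2];
  int K = dwd[0], Cout = dwd[3];
  int p = K / 2;
  std::vector<double> g(dy.size());  // relu-gated dy
  for (R_xlen_t t = 0; t < dy.size(); ++t)
    g[t] = (relu && y[t] <= 0) ? 0.0 : dy[t];
  NumericVector dx(x.size());
  dx.attr("dim") = dxd;
  NumericVector dw(w.size());
  dw.attr("dim") = dwd;
  NumericVector db(Cout);
  const double *xp = REAL(x), *wp = REAL(w);
  double *dxp = REAL(dx), *dwp = REAL(dw);
  size_t plane = (size_t)H * W;
  for (int oc = 0; oc < Cout; ++oc) {
    const double *g0 = g.data() + plane * oc;
    double accb = 0;
    for (size_t t = 0; t < plane; ++t) accb += g0[t];
    db[oc] = accb;
    for (int ic = 0; ic < Cin; ++ic) {
      const double *x0 = xp + plane * ic;
      double *dx0 = dxp + plane * ic;
      for (int bk = 0; bk < K; ++bk) {
        int dj = bk - p;
        int j0 = dj < 0 ? -dj : 0, j1 = dj > 0 ? W - dj : W;
        for (int a = 0; a < K; ++a) {
          int di = a - p;
          int i0 = di < 0 ? -di : 0, i1 = di > 0 ? H - di : H;
          long wi = a + K * (bk + K * (ic + (long)Cin * oc));
          double wv = wp[wi], wacc = 0;
          for (int j = j0; j < j1; ++j) {
            const double *gc = g0 + (size_t)H * j;
            const double *xc = x0 + (size_t)H * (j + dj) + di;
            double *dxc = dx0 + (size_t)H * (j + dj) + di;
            for (int i = i0; i < i1; ++i) {
              wacc += xc[i] * gc[i];
              dxc[i] += wv * gc[i];
            }
          }
          dwp[wi] = wacc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled map and the
// linear argmax index (0-based, into the input array) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * (long)Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector arg(out.size());
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int best = idx3(2 * i, 2 * j, c, H, W);
        double bv = x[best];
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b) {
            int t = idx3(2 * i + a, 2 * j + b, c, H, W);
            if (x[t] > bv) { bv = x[t]; best = t; }
          }
        int o = i + Ho * (j + (long)Wo * c);
        out[o] = bv;
        arg[o] = best;
      }
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector arg, IntegerVector in_dim) {
  NumericVector dx(in_dim[0] * (long)in_dim[1] * in_dim[2]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[arg[t]] += dy[t];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Ho * (long)Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        out[idx3(i, j, c, Ho, Wo)] = x[idx3(i / 2, j / 2, c, H, W)];
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx(H * (long)W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx[idx3(i / 2, j / 2, c, H, W)] += dy[idx3(i, j, c, Ho, Wo)];
  return dx;
}

// Grayscale dilation with a discrete disk {(du,dv): du^2+dv^2 <= r^2};
// neighbourhoods are truncated at the image border.
// [[Rcpp::export]]
NumericMatrix dilate_disk_cpp(NumericMatrix x, int radius) {
  int H = x.nrow(), W = x.ncol();
  std::vector<int> du, dv;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { du.push_back(a); dv.push_back(b); }
  NumericMatrix out(H, W);
  int n = du.size();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = R_NegInf;
      for (int t = 0; t < n; ++t) {
        int ii = i + du[t], jj = j + dv[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (x(ii, jj) > m) m = x(ii, jj);
      }
      out(i, j) = m;
    }
  return out;
}

// Plateau-aware regional maxima, 8-connectivity: a connected plateau of equal
// value is a regional maximum iff every strictly-neighbouring pixel is lower.
// [[Rcpp::export]]
LogicalMatrix regional_maxima_cpp(NumericMatrix x) {
  int H = x.nrow(), W = x.ncol();
  LogicalMatrix out(H, W);
  std::vector<char> visited(H * (size_t)W, 0);
  std::vector<int> stack, plateau;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      int s = i0 + H * j0;
      if (visited[s]) continue;
      double v = x(i0, j0);
      bool is_max = true;
      stack.clear(); plateau.clear();
      stack.push_back(s); visited[s] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        plateau.push_back(cur);
        int ci = cur % H, cj = cur / H;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            if (a == 0 && b == 0) continue;
            int ni = ci + a, nj = cj + b;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            double nv = x(ni, nj);
            if (nv > v) is_max = false;
            else if (nv == v) {
              int t = ni + H * nj;
              if (!visited[t]) { visited[t] = 1; stack.push_back(t); }
            }
          }
      }
      if (is_max)
        for (size_t t = 0; t < plateau.size(); ++t)
          out[plateau[t]] = true;
    }
  return out;
}

// 8-connected component labelling of a boolean mask; labels 1..K are assigned
// in column-major scan order of each component's first-visited pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + H * j0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int ci = cur % H, cj = cur / H;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b) {
            if (a == 0 && b == 0) continue;
            int ni = ci + a, nj = cj + b;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + H * nj);
            }
          }
      }
    }
  return lab;
}
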