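// Hot-path primitives for the CNN backend and image resampling.
// Feature maps are flat vectors in [H, W, B, C] column-major order.

#include <Rcpp.h>
using namespace Rcpp;

// im2col for a same-padded 3x3, stride-1 convolution: output has one row per
// spatial position and batch element (h fastest, then w, then b) and one
// column per (offset, channel) pair, offsets column-major over the 3x3
// window, channels fastest within an offset block.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int H, int W, int B, int C) {
  const int HW = H * W, HWB = HW * B;
  NumericMatrix M(HWB, 9 * C);
  const double* x = X.begin();
  double* m = M.begin();
  for (int j = 0; j < 3; ++j) {
    for (int i = 0; i < 3; ++i) {
      const int o = j * 3 + i;
      for (int c = 0; c < C; ++c) {
        double* col = m + (size_t)(o * C + c) * HWB;
        const double* src = x + (size_t)c * HWB * 1;  // channel plane start
        for (int b = 0; b < B; ++b) {
          const double* plane = src + (size_t)b * HW;
          double* dst = col + (size_t)b * HW;
          for (int w = 0; w < W; ++w) {
            const int ww = w + j - 1;
            double* d = dst + (size_t)w * H;
            if (ww < 0 || ww >= W) {
              for (int h = 0; h < H; ++h) d[h] = 0.0;
              continue;
            }
            const double* s = plane + (size_t)ww * H + (i - 1);
            const int h0 = (i - 1 < 0) ? 1 : 0;        // pad top
            const int h1 = (i - 1 > 0) ? H - 1 : H;    // pad bottom
            if (h0) d[0] = 0.0;
            for (int h = h0; h < h1; ++h) d[h] = s[h];
            if (h1 < H) d[H - 1] = 0.0;
          }
        }
      }
    }
  }
  return M;
}

// 2x2 max pooling, stride 2; returns the pooled map and the argmax code
// (0..3, column-major within the window, first element winning ties).
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector X, int H, int W, int B, int C) {
  const int H2 = H / 2, W2 = W / 2;
  const size_t nout = (size_t)H2 * W2 * B * C;
  NumericVector out(nout);
  IntegerVector arg(nout);
  const double* x = X.begin();
  double* o = out.begin();
  int* a = arg.begin();
  const size_t HW = (size_t)H * W;
  size_t q = 0;
  for (size_t bc = 0; bc < (size_t)B * C; ++bc) {
    const double* plane = x + bc * HW;
    for (int w = 0; w < W2; ++w) {
      const double* c0 = plane + (size_t)(2 * w) * H;
      const double* c1 = plane + (size_t)(2 * w + 1) * H;
      for (int h = 0; h < H2; ++h, ++q) {
        double v = c0[2 * h]; int k = 0;
        if (c0[2 * h + 1] > v) { v = c0[2 * h + 1]; k = 1; }
        if (c1[2 * h] > v) { v = c1[2 * h]; k = 2; }
        if (c1[2 * h + 1] > v) { v = c1[2 * h + 1]; k = 3; }
        o[q] = v; a[q] = k;
      }
    }
  }
  return List::create(_["A"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dY, IntegerVector arg,
                           int H, int W, int B, int C) {
  const int H2 = H / 2, W2 = W / 2;
  NumericVector dX((size_t)H * W * B * C);
  const double* g = dY.begin();
  const int* a = arg.begin();
  double* d = dX.begin();
  const size_t HW = (size_t)H * W;
  size_t q = 0;
  for (size_t bc = 0; bc < (size_t)B * C; ++bc) {
    double* plane = d + bc * HW;
    for (int w = 0; w < W2; ++w) {
      double* c0 = plane + (size_t)(2 * w) * H;
      double* c1 = plane + (size_t)(2 * w + 1) * H;
      for (int h = 0; h < H2; ++h, ++q) {
        switch (a[q]) {
        case 0: c0[2 * h] += g[q]; break;
        case 1: c0[2 * h + 1] += g[q]; break;
        case 2: c1[2 * h] += g[q]; break;
        default: c1[2 * h + 1] += g[q]; break;
        }
      }
    }
  }
  return dX;
}

// Bilinear sampling of a matrix at fractional 1-based (row, col) positions;
// positions outside the image contribute 0.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector r,
                           NumericVector c) {
  const int H = img.nrow(), W = img.ncol();
  const size_t n = r.size();
  NumericVector out(n);
  const double* im = img.begin();
  for (size_t k = 0; k < n; ++k) {
    const double rr = r[k] - 1.0, cc = c[k] - 1.0;  // 0-based
    const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
    const double fr = rr - r0, fc = cc - c0;
    double acc = 0.0;
    for (int dj = 0; dj <= 1; ++dj) {
      const int cj = c0 + dj;
      if (cj < 0 || cj >= W) continue;
      const double wc = dj ? fc : 1.0 - fc;
      for (int di = 0; di <= 1; ++di) {
        const int ri = r0 + di;
        if (ri < 0 || ri >= H) continue;
        const double wr = di ? fr : 1.0 - fr;
        acc += wr * wc * im[(size_t)cj * H + ri];
      }
    }
    out[k] = acc;
  }
  return out;
}

// Batch-norm forward (training): per-column mean/sd normalization of Z,
// scale-shift by gamma/beta, ReLU. Returns the activation, the normalized
// matrix and the column statistics needed for backprop and running averages.
// [[Rcpp::export]]
List cpp_bn_relu_train(NumericMatrix Z, NumericVector gamma,
                       NumericVector beta, double eps) {
  const int n = Z.nrow(), C = Z.ncol();
  NumericMatrix A(n, C), zh(n, C);
  LogicalMatrix relu(n, C);
  NumericVector mu(C), sd(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* z = &Z(0, c);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += z[i];
    const double m = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { const double d = z[i] - m; v += d * d; }
    v /= n;
    const double isd = 1.0 / std::sqrt(v + eps);
    double* zo = &zh(0, c);
    double* a = &A(0, c);
    int* rl = &relu(0, c);
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double q = (z[i] - m) * isd;
      zo[i] = q;
      const double y = g * q + b;
      const bool pos = y > 0;
      a[i] = pos ? y : 0.0;
      rl[i] = pos;
    }
    mu[c] = m; var[c] = v; sd[c] = 1.0 / isd;
  }
  return List::create(_["A"] = A, _["zh"] = zh, _["relu"] = relu,
                      _["mu"] = mu, _["var"] = var, _["sd"] = sd);
}

// Batch-norm forward (inference) with running statistics, fused with ReLU.
// [[Rcpp::export]]
NumericMatrix cpp_bn_relu_eval(NumericMatrix Z, NumericVector gamma,
                               NumericVector beta, NumericVector mu,
                               NumericVector var, double eps) {
  const int n = Z.nrow(), C = Z.ncol();
  NumericMatrix A(n, C);
  for (int c = 0; c < C; ++c) {
    const double* z = &Z(0, c);
    double* a = &A(0, c);
    const double isd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mu[c];
    for (int i = 0; i < n; ++i) {
      const double y = g * (z[i] - m) * isd + b;
      a[i] = y > 0 ? y : 0.0;
    }
  }
  return A;
}

// Batch-norm + ReLU backward: dA is the gradient at the activation; returns
// the gradient with respect to Z plus the gamma/beta gradients.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericMatrix dA, LogicalMatrix relu, NumericMatrix zh,
                     NumericVector sd, NumericVector gamma) {
  const int n = dA.nrow(), C = dA.ncol();
  NumericMatrix dZ(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* da = &dA(0, c);
    const int* rl = &relu(0, c);
    const double* q = &zh(0, c);
    double* dz = &dZ(0, c);
    double sum_dy = 0.0, sum_dyq = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dy = rl[i] ? da[i] : 0.0;
      dz[i] = dy;                      // reuse as scratch for dy
      sum_dy += dy;
      sum_dyq += dy * q[i];
    }
    dgamma[c] = sum_dyq;
    dbeta[c] = sum_dy;
    const double g_isd = gamma[c] / sd[c];
    const double mdy = sum_dy / n, mdyq = sum_dyq / n;
    for (int i = 0; i < n; ++i)
      dz[i] = g_isd * (dz[i] - mdy - q[i] * mdyq);
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Largest 6-connected component of a 3D logical mask; returns the mask with
// all smaller components removed (ensures the single-component invariant
// of a lesion tracing even under per-slice jitter).
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, int nx, int ny,
                                    int nz) {
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  const int* m = LOGICAL(mask);
  int next_label = 0;
  size_t best_size = 0; int best_label = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || label[s]) continue;
    ++next_label;
    size_t size = 0;
    stack.push_back(s);
    label[s] = next_label;
    while (!stack.empty()) {
      const size_t q = stack.back(); stack.pop_back();
      ++size;
      const int x = q % nx, y = (q / nx) % ny, z = q / ((size_t)nx * ny);
      const int ddx[6] = {1, -1, 0, 0, 0, 0};
      const int ddy[6] = {0, 0, 1, -1, 0, 0};
      const int ddz[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        const int x2 = x + ddx[d], y2 = y + ddy[d], z2 = z + ddz[d];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        const size_t q2 = (size_t)z2 * nx * ny + (size_t)y2 * nx + x2;
        if (m[q2] && !label[q2]) { label[q2] = next_label; stack.push_back(q2); }
      }
    }
    if (size > best_size) { best_size = size; best_label = next_label; }
  }
  LogicalVector out(n);
  int* o = LOGICAL(out);
  for (size_t s = 0; s < n; ++s) o[s] = (label[s] == best_label && m[s]);
  return out;
}
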