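#include <Rcpp.h>
using namespace Rcpp;

// Feature-map memory layout (R column-major), channel-last:
//   2D: (H, W, N, C)      3D: (Z, Y, X, N, C)
// Convolutions are stride-1 and shape-preserving; the low-side pad is
// floor((k-1)/2) so even kernel extents get the extra zero at the
// high-index side. im2col rows are ordered (h, w, n) / (z, y, x, n) and
// columns (kh, kw, c) / (kz, ky, kx, c), matching a flattened weight array
// of shape (k..., IC, OC).

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, IntegerVector dims,
                           int kh, int kw, int pt, int pl) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t R = (R_xlen_t)H * W * N;
  NumericMatrix out(R, kh * kw * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh) {
          const int k = dh + kh * (dw + kw * c);
          double* col = &out(0, k);
          for (int ow = 0; ow < W; ++ow) {
            const int w = ow - pl + dw;
            if (w < 0 || w >= W) continue;
            const double* xc = xs + (R_xlen_t)H * w;
            double* oc = col + (R_xlen_t)H * ow + (R_xlen_t)H * W * n;
            for (int oh = 0; oh < H; ++oh) {
              const int h = oh - pt + dh;
              if (h < 0 || h >= H) continue;
              oc[oh] = xc[h];
            }
          }
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix cols, IntegerVector dims,
                           int kh, int kw, int pt, int pl) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double* xs = dp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh) {
          const int k = dh + kh * (dw + kw * c);
          const double* col = &cols(0, k);
          for (int ow = 0; ow < W; ++ow) {
            const int w = ow - pl + dw;
            if (w < 0 || w >= W) continue;
            double* xc = xs + (R_xlen_t)H * w;
            const double* oc = col + (R_xlen_t)H * ow + (R_xlen_t)H * W * n;
            for (int oh = 0; oh < H; ++oh) {
              const int h = oh - pt + dh;
              if (h < 0 || h >= H) continue;
              xc[h] += oc[oh];
            }
          }
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, IntegerVector dims,
                           int kz, int ky, int kx,
                           int pz, int py, int px) {
  const int Z = dims[0], Y = dims[1], X = dims[2], N = dims[3], C = dims[4];
  const R_xlen_t R = (R_xlen_t)Z * Y * X * N;
  NumericMatrix out(R, kz * ky * kx * C);
  const double* xp = x.begin();
  const R_xlen_t vol = (R_xlen_t)Z * Y * X;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + vol * (n + (R_xlen_t)N * c);
      for (int dx_ = 0; dx_ < kx; ++dx_)
        for (int dy = 0; dy < ky; ++dy)
          for (int dz = 0; dz < kz; ++dz) {
            const int k = dz + kz * (dy + ky * (dx_ + kx * c));
            double* col = &out(0, k);
            for (int ox = 0; ox < X; ++ox) {
              const int xx = ox - px + dx_;
              if (xx < 0 || xx >= X) continue;
              for (int oy = 0; oy < Y; ++oy) {
                const int yy = oy - py + dy;
                if (yy < 0 || yy >= Y) continue;
                const double* xc = xs + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
                double* oc = col + (R_xlen_t)Z * (oy + (R_xlen_t)Y * ox) + vol * n;
                for (int oz = 0; oz < Z; ++oz) {
                  const int zz = oz - pz + dz;
                  if (zz < 0 || zz >= Z) continue;
                  oc[oz] = xc[zz];
                }
              }
            }
          }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix cols, IntegerVector dims,
                           int kz, int ky, int kx,
                           int pz, int py, int px) {
  const int Z = dims[0], Y = dims[1], X = dims[2], N = dims[3], C = dims[4];
  const R_xlen_t vol = (R_xlen_t)Z * Y * X;
  NumericVector dxv(vol * C * N);
  double* dp = dxv.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double* xs = dp + vol * (n + (R_xlen_t)N * c);
      for (int dx_ = 0; dx_ < kx; ++dx_)
        for (int dy = 0; dy < ky; ++dy)
          for (int dz = 0; dz < kz; ++dz) {
            const int k = dz + kz * (dy + ky * (dx_ + kx * c));
            const double* col = &cols(0, k);
            for (int ox = 0; ox < X; ++ox) {
              const int xx = ox - px + dx_;
              if (xx < 0 || xx >= X) continue;
              for (int oy = 0; oy < Y; ++oy) {
                const int yy = oy - py + dy;
                if (yy < 0 || yy >= Y) continue;
                double* xc = xs + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
                const double* oc = col + (R_xlen_t)Z * (oy + (R_xlen_t)Y * ox) + vol * n;
                for (int oz = 0; oz < Z; ++oz) {
                  const int zz = oz - pz + dz;
                  if (zz < 0 || zz >= Z) continue;
                  xc[zz] += oc[oz];
                }
              }
            }
          }
    }
  return dxv;
}

// Pooling and upsampling treat everything after the spatial axes as one
// combined trailing dimension, so callers pass dims = (spatial..., N*C, 1).

// [[Rcpp::export]]
List maxpool2d_cpp(NumericVector x, IntegerVector dims, int ph, int pw) {
  const int H = dims[0], W = dims[1];
  const R_xlen_t T = (R_xlen_t)dims[2] * dims[3];
  const int OH = H / ph, OW = W / pw;
  NumericVector y((R_xlen_t)OH * OW * T);
  IntegerVector idx((R_xlen_t)OH * OW * T);
  const double* xp = x.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    const R_xlen_t base = (R_xlen_t)H * W * t;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        double best = R_NegInf;
        R_xlen_t bi = -1;
        for (int dw = 0; dw < pw; ++dw)
          for (int dh = 0; dh < ph; ++dh) {
            const int h = oh * ph + dh, w = ow * pw + dw;
            const R_xlen_t i = base + h + (R_xlen_t)H * w;
            if (xp[i] > best) { best = xp[i]; bi = i; }
          }
        const R_xlen_t o = oh + (R_xlen_t)OH * ow + (R_xlen_t)OH * OW * t;
        y[o] = best;
        idx[o] = (int)(bi + 1);  // 1-based into x
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
List maxpool3d_cpp(NumericVector x, IntegerVector dims, int pz, int py, int px) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t T = (R_xlen_t)dims[3] * dims[4];
  const int OZ = Z / pz, OY = Y / py, OX = X / px;
  const R_xlen_t ovol = (R_xlen_t)OZ * OY * OX;
  NumericVector y(ovol * T);
  IntegerVector idx(ovol * T);
  const double* xp = x.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    const R_xlen_t base = (R_xlen_t)Z * Y * X * t;
    for (int ox = 0; ox < OX; ++ox)
      for (int oy = 0; oy < OY; ++oy)
        for (int oz = 0; oz < OZ; ++oz) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int dx_ = 0; dx_ < px; ++dx_)
            for (int dy = 0; dy < py; ++dy)
              for (int dz = 0; dz < pz; ++dz) {
                const int z = oz * pz + dz, yy = oy * py + dy, xx = ox * px + dx_;
                const R_xlen_t i = base + z + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          const R_xlen_t o = oz + (R_xlen_t)OZ * (oy + (R_xlen_t)OY * ox) + ovol * t;
          y[o] = best;
          idx[o] = (int)(bi + 1);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Transposed convolution with kernel = stride (blocks do not overlap).
// x: (H, W, N, IC), w: (kh, kw, IC, OC) -> y: (H*kh, W*kw, N, OC)
// [[Rcpp::export]]
NumericVector convtrans2d_fw_cpp(NumericVector x, IntegerVector dims,
                                 NumericVector w, IntegerVector wdims,
                                 NumericVector b) {
  const int H = dims[0], W = dims[1], N = dims[2], IC = dims[3];
  const int kh = wdims[0], kw = wdims[1], OC = wdims[3];
  const int OH = H * kh, OW = W * kw;
  NumericVector y((R_xlen_t)OH * OW * N * OC);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int oc = 0; oc < OC; ++oc)
    for (int n = 0; n < N; ++n) {
      double* ys = yp + (R_xlen_t)OH * OW * (n + (R_xlen_t)N * oc);
      const double bv = b[oc];
      for (R_xlen_t i = 0; i < (R_xlen_t)OH * OW; ++i) ys[i] = bv;
      for (int ic = 0; ic < IC; ++ic) {
        const double* xs = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * ic);
        for (int dw = 0; dw < kw; ++dw)
          for (int dh = 0; dh < kh; ++dh) {
            const double wv = wp[dh + kh * (dw + kw * (ic + IC * oc))];
            if (wv == 0) continue;
            for (int j = 0; j < W; ++j) {
              const double* xc = xs + (R_xlen_t)H * j;
              double* yc = ys + (R_xlen_t)OH * (j * kw + dw) + dh;
              for (int i = 0; i < H; ++i)
                yc[(R_xlen_t)i * kh] += wv * xc[i];
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List convtrans2d_bw_cpp(NumericVector x, IntegerVector dims,
                        NumericVector w, IntegerVector wdims,
                        NumericVector dy) {
  const int H = dims[0], W = dims[1], N = dims[2], IC = dims[3];
  const int kh = wdims[0], kw = wdims[1], OC = wdims[3];
  const int OH = H * kh, OW = W * kw;
  NumericVector dxv((R_xlen_t)H * W * N * IC);
  NumericVector dw(w.size());
  NumericVector db(OC);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (int oc = 0; oc < OC; ++oc)
    for (int n = 0; n < N; ++n) {
      const double* dys = dyp + (R_xlen_t)OH * OW * (n + (R_xlen_t)N * oc);
      double acc = 0;
      for (R_xlen_t i = 0; i < (R_xlen_t)OH * OW; ++i) acc += dys[i];
      db[oc] += acc;
      for (int ic = 0; ic < IC; ++ic) {
        const double* xs = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * ic);
        double* dxs = dxv.begin() + (R_xlen_t)H * W * (n + (R_xlen_t)N * ic);
        for (int dw_ = 0; dw_ < kw; ++dw_)
          for (int dh = 0; dh < kh; ++dh) {
            const int wi = dh + kh * (dw_ + kw * (ic + IC * oc));
            const double wv = wp[wi];
            double wacc = 0;
            for (int j = 0; j < W; ++j) {
              const double* xc = xs + (R_xlen_t)H * j;
              double* dxc = dxs + (R_xlen_t)H * j;
              const double* dyc = dys + (R_xlen_t)OH * (j * kw + dw_) + dh;
              for (int i = 0; i < H; ++i) {
                const double g = dyc[(R_xlen_t)i * kh];
                wacc += xc[i] * g;
                dxc[i] += wv * g;
              }
            }
            dw[wi] += wacc;
          }
      }
    }
  return List::create(_["dx"] = dxv, _["dw"] = dw, _["db"] = db);
}

// Nearest-neighbour upsampling by integer factors per axis; trailing
// dimensions combined as for pooling.
// [[Rcpp::export]]
NumericVector upsample3d_cpp(NumericVector x, IntegerVector dims,
                             int fz, int fy, int fx) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t T = (R_xlen_t)dims[3] * dims[4];
  const int OZ = Z * fz, OY = Y * fy, OX = X * fx;
  NumericVector y((R_xlen_t)OZ * OY * OX * T);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    const double* xs = xp + (R_xlen_t)Z * Y * X * t;
    double* ys = yp + (R_xlen_t)OZ * OY * OX * t;
    for (int ox = 0; ox < OX; ++ox)
      for (int oy = 0; oy < OY; ++oy) {
        const double* xc = xs + (R_xlen_t)Z * ((oy / fy) + (R_xlen_t)Y * (ox / fx));
        double* yc = ys + (R_xlen_t)OZ * (oy + (R_xlen_t)OY * ox);
        for (int oz = 0; oz < OZ; ++oz)
          yc[oz] = xc[oz / fz];
      }
  }
  return y;
}

// Gradient of nearest upsampling: sum over each factor block.
// [[Rcpp::export]]
NumericVector sumpool3d_cpp(NumericVector dy, IntegerVector odims,
                            int fz, int fy, int fx) {
  const int OZ = odims[0], OY = odims[1], OX = odims[2];
  const R_xlen_t T = (R_xlen_t)odims[3] * odims[4];
  const int Z = OZ / fz, Y = OY / fy, X = OX / fx;
  NumericVector dxv((R_xlen_t)Z * Y * X * T);
  const double* dp = dy.begin();
  double* xp = dxv.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    const double* ds = dp + (R_xlen_t)OZ * OY * OX * t;
    double* xs = xp + (R_xlen_t)Z * Y * X * t;
    for (int ox = 0; ox < OX; ++ox)
      for (int oy = 0; oy < OY; ++oy) {
        const double* dc = ds + (R_xlen_t)OZ * (oy + (R_xlen_t)OY * ox);
        double* xc = xs + (R_xlen_t)Z * ((oy / fy) + (R_xlen_t)Y * (ox / fx));
        for (int oz = 0; oz < OZ; ++oz)
          xc[oz / fz] += dc[oz];
      }
  }
  return dxv;
}

// ---- elementwise helpers (hot paths of the training loop) ----

// In-place per-output-channel bias add on the (rows x OC) matmul result.
// [[Rcpp::export]]
void add_bias_cpp(NumericMatrix ymat, NumericVector b) {
  const R_xlen_t R = ymat.nrow();
  const int OC = ymat.ncol();
  for (int c = 0; c < OC; ++c) {
    double* col = &ymat(0, c);
    const double bv = b[c];
    for (R_xlen_t i = 0; i < R; ++i) col[i] += bv;
  }
}

// One-pass per-channel mean and mean of squares of an (M x C) matrix.
// [[Rcpp::export]]
List bn_stats_cpp(NumericMatrix xm) {
  const R_xlen_t M = xm.nrow();
  const int C = xm.ncol();
  NumericVector mu(C), m2(C);
  for (int c = 0; c < C; ++c) {
    const double* col = &xm(0, c);
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < M; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    mu[c] = s / M;
    m2[c] = s2 / M;
  }
  return List::create(_["mu"] = mu, _["m2"] = m2);
}

// y = gamma * (x - mu) * invstd + beta, also returning xhat for backward.
// [[Rcpp::export]]
List bn_apply_cpp(NumericMatrix xm, NumericVector mu, NumericVector invstd,
                  NumericVector gamma, NumericVector beta) {
  const R_xlen_t M = xm.nrow();
  const int C = xm.ncol();
  NumericMatrix y(M, C), xhat(M, C);
  for (int c = 0; c < C; ++c) {
    const double* col = &xm(0, c);
    double* yc = &y(0, c);
    double* hc = &xhat(0, c);
    const double m = mu[c], s = invstd[c], g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < M; ++i) {
      const double h = (col[i] - m) * s;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Batch-norm backward (training statistics):
//   dx = gamma*invstd * (dy - dbeta/M - xhat*dgamma/M)
// [[Rcpp::export]]
List bn_bw_cpp(NumericMatrix dy, NumericMatrix xhat, NumericVector gamma,
               NumericVector invstd, bool train) {
  const R_xlen_t M = dy.nrow();
  const int C = dy.ncol();
  NumericMatrix dx(M, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c);
    const double* hc = &xhat(0, c);
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < M; ++i) { sg += dyc[i] * hc[i]; sb += dyc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double gi = gamma[c] * invstd[c];
    double* dxc = &dx(0, c);
    if (train) {
      const double a = sb / M, b = sg / M;
      for (R_xlen_t i = 0; i < M; ++i)
        dxc[i] = gi * (dyc[i] - a - hc[i] * b);
    } else {
      for (R_xlen_t i = 0; i < M; ++i) dxc[i] = gi * dyc[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// Returns a new gradient with entries zeroed where the activation was 0.
// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dp = dy.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}
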