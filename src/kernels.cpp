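// Low-level numerical kernels for the 2D->3D GAN engine.
//
// Convolutions are im2col + GEMM. The GEMMs run in single precision
// (roughly twice the dgemm throughput on one CPU; the training loop keeps
// master weights and losses in double, so this only perturbs gradients at
// the 1e-7 relative level). 3D convolutions process the output z axis in
// slabs so the im2col buffer stays bounded even for full-scale
// 128x128x256 volumes.
//
// Array layouts follow R column-major order:
//   2D activations: (W, H, C, N)      weights: (kw, kh, Cin, Cout)
//   3D activations: (X, Y, Z, C, N)   weights: (kx, ky, kz, Cin, Cout)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const arma::uword MAX_SLAB_ELEMS = 6000000; // ~24 MB float buffer

static NumericVector alloc_nd(std::vector<int> d) {
  double n = 1; for (int v : d) n *= v;
  NumericVector out((R_xlen_t)n);
  out.attr("dim") = IntegerVector(d.begin(), d.end());
  return out;
}
static IntegerVector alloc_id(std::vector<int> d) {
  double n = 1; for (int v : d) n *= v;
  IntegerVector out((R_xlen_t)n);
  out.attr("dim") = IntegerVector(d.begin(), d.end());
  return out;
}

static arma::fmat to_f(const double* p, size_t rows, size_t cols) {
  arma::fmat m(rows, cols);
  float* dst = m.memptr();
  for (size_t i = 0; i < rows * cols; ++i) dst[i] = (float)p[i];
  return m;
}

// ---------------------------------------------------------------- conv2d

static void im2col2d(const double* x, int W, int H, int C,
                     int kw, int kh, int s, int pl, int pt,
                     int OW, int OH, arma::fmat& A) {
  // A: (OW*OH) x (kw*kh*C)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)W * H * c;
    for (int kj = 0; kj < kh; ++kj) {
      for (int ki = 0; ki < kw; ++ki) {
        int col = ki + kw * (kj + kh * c);
        float* Acol = A.colptr(col);
        for (int ov = 0; ov < OH; ++ov) {
          int iy = ov * s - pt + kj;
          if (iy < 0 || iy >= H) {
            for (int ou = 0; ou < OW; ++ou) Acol[ou + OW * ov] = 0.0f;
            continue;
          }
          const double* xrow = xc + (size_t)W * iy;
          for (int ou = 0; ou < OW; ++ou) {
            int ix = ou * s - pl + ki;
            Acol[ou + OW * ov] = (ix >= 0 && ix < W) ? (float)xrow[ix] : 0.0f;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pl, int pr, int pt, int pb) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int kw = wd[0], kh = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fw: channel mismatch");
  int OW = (W + pl + pr - kw) / stride + 1;
  int OH = (H + pt + pb - kh) / stride + 1;
  NumericVector y = alloc_nd({OW, OH, Cout, N});
  arma::fmat Wm = to_f(w.begin(), (size_t)kw * kh * Cin, Cout);
  arma::fmat A(OW * OH, (size_t)kw * kh * Cin);
  for (int n = 0; n < N; ++n) {
    im2col2d(x.begin() + (size_t)W * H * C * n, W, H, C, kw, kh, stride,
             pl, pt, OW, OH, A);
    arma::fmat Y = A * Wm;
    double* yn = y.begin() + (size_t)OW * OH * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Y.colptr(co);
      double bc = b[co];
      double* dst = yn + (size_t)OW * OH * co;
      for (int i = 0; i < OW * OH; ++i) dst[i] = src[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pl, int pt, bool need_dx, bool need_dw) {
  // pl, pt: left/top pads (right/bottom implied by dy dims)
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int kw = wd[0], kh = wd[1], Cin = wd[2], Cout = wd[3];
  int OW = yd[0], OH = yd[1];
  arma::fmat Wm = to_f(w.begin(), (size_t)kw * kh * Cin, Cout);
  NumericVector dx = alloc_nd({W, H, C, need_dx ? N : 0});
  NumericVector dw = alloc_nd({kw, kh, Cin, Cout});
  NumericVector db(Cout);
  arma::fmat dWm(need_dw ? (size_t)kw * kh * Cin : 0, need_dw ? Cout : 0,
                 arma::fill::zeros);
  arma::fmat A;
  if (need_dw) A.set_size(OW * OH, (size_t)kw * kh * Cin);
  for (int n = 0; n < N; ++n) {
    arma::fmat dY = to_f(dy.begin() + (size_t)OW * OH * Cout * n,
                         (size_t)OW * OH, Cout);
    if (need_dw) {
      im2col2d(x.begin() + (size_t)W * H * C * n, W, H, C, kw, kh, stride,
               pl, pt, OW, OH, A);
      dWm += A.t() * dY;
      for (int co = 0; co < Cout; ++co)
        db[co] += arma::accu(dY.col(co));
    }
    if (need_dx) {
      arma::fmat dA = dY * Wm.t(); // (OW*OH) x (kw*kh*Cin)
      double* dxn = dx.begin() + (size_t)W * H * C * n;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + (size_t)W * H * c;
        for (int kj = 0; kj < kh; ++kj) {
          for (int ki = 0; ki < kw; ++ki) {
            int col = ki + kw * (kj + kh * c);
            const float* dAcol = dA.colptr(col);
            for (int ov = 0; ov < OH; ++ov) {
              int iy = ov * stride - pt + kj;
              if (iy < 0 || iy >= H) continue;
              double* dxrow = dxc + (size_t)W * iy;
              for (int ou = 0; ou < OW; ++ou) {
                int ix = ou * stride - pl + ki;
                if (ix >= 0 && ix < W) dxrow[ix] += dAcol[ou + OW * ov];
              }
            }
          }
        }
      }
    }
  }
  if (need_dw) {
    const float* src = dWm.memptr();
    for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = src[i];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------- conv3d

static void im2col3d_slab(const double* x, int X, int Y, int Z, int C,
                          int kx, int ky, int kz, int s,
                          int px, int py, int pz,
                          int OX, int OY, int oz0, int nz, arma::fmat& A) {
  // rows: OX*OY*nz output positions for output z in [oz0, oz0+nz)
  int rowsXY = OX * OY;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)X * Y * Z * c;
    for (int kk = 0; kk < kz; ++kk) {
      for (int kj = 0; kj < ky; ++kj) {
        for (int ki = 0; ki < kx; ++ki) {
          int col = ki + kx * (kj + ky * (kk + kz * c));
          float* Acol = A.colptr(col);
          for (int zo = 0; zo < nz; ++zo) {
            int iz = (oz0 + zo) * s - pz + kk;
            float* Az = Acol + (size_t)rowsXY * zo;
            if (iz < 0 || iz >= Z) {
              std::fill(Az, Az + rowsXY, 0.0f);
              continue;
            }
            const double* xz = xc + (size_t)X * Y * iz;
            for (int oy = 0; oy < OY; ++oy) {
              int iy = oy * s - py + kj;
              float* Arow = Az + (size_t)OX * oy;
              if (iy < 0 || iy >= Y) {
                std::fill(Arow, Arow + OX, 0.0f);
                continue;
              }
              const double* xrow = xz + (size_t)X * iy;
              for (int ox = 0; ox < OX; ++ox) {
                int ix = ox * s - px + ki;
                Arow[ox] = (ix >= 0 && ix < X) ? (float)xrow[ix] : 0.0f;
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int px0, int px1, int py0, int py1,
                        int pz0, int pz1) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  int kx = wd[0], ky = wd[1], kz = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d_fw: channel mismatch");
  int OX = (X + px0 + px1 - kx) / stride + 1;
  int OY = (Y + py0 + py1 - ky) / stride + 1;
  int OZ = (Z + pz0 + pz1 - kz) / stride + 1;
  int px = px0, py = py0, pz = pz0;
  NumericVector y = alloc_nd({OX, OY, OZ, Cout, N});
  arma::fmat Wm = to_f(w.begin(), (size_t)kx * ky * kz * Cin, Cout);
  arma::uword cols = (arma::uword)kx * ky * kz * Cin;
  int slab = std::max(1, (int)(MAX_SLAB_ELEMS / (cols * OX * OY + 1)));
  arma::fmat A;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)X * Y * Z * C * n;
    double* yn = y.begin() + (size_t)OX * OY * OZ * Cout * n;
    for (int oz0 = 0; oz0 < OZ; oz0 += slab) {
      int nz = std::min(slab, OZ - oz0);
      A.set_size((size_t)OX * OY * nz, cols);
      im2col3d_slab(xn, X, Y, Z, C, kx, ky, kz, stride, px, py, pz,
                    OX, OY, oz0, nz, A);
      arma::fmat Yb = A * Wm; // (OX*OY*nz) x Cout
      for (int co = 0; co < Cout; ++co) {
        double* dst = yn + (size_t)OX * OY * OZ * co + (size_t)OX * OY * oz0;
        const float* src = Yb.colptr(co);
        double bc = b[co];
        for (size_t i = 0; i < (size_t)OX * OY * nz; ++i) dst[i] = src[i] + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int px, int py, int pz, bool need_dx,
               bool need_dw) {
  // px, py, pz: leading (low-index) pads; trailing pads implied by dy dims
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  int kx = wd[0], ky = wd[1], kz = wd[2], Cin = wd[3], Cout = wd[4];
  int OX = yd[0], OY = yd[1], OZ = yd[2];
  arma::fmat Wm = to_f(w.begin(), (size_t)kx * ky * kz * Cin, Cout);
  NumericVector dx = alloc_nd({X, Y, Z, C, need_dx ? N : 0});
  NumericVector dw = alloc_nd({kx, ky, kz, Cin, Cout});
  NumericVector db(Cout);
  arma::fmat dWm(need_dw ? (size_t)kx * ky * kz * Cin : 0,
                 need_dw ? Cout : 0, arma::fill::zeros);
  arma::uword cols = (arma::uword)kx * ky * kz * Cin;
  int slab = std::max(1, (int)(MAX_SLAB_ELEMS / (cols * OX * OY + 1)));
  arma::fmat A, dYb;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)X * Y * Z * C * n;
    const double* dyn = dy.begin() + (size_t)OX * OY * OZ * Cout * n;
    double* dxn = need_dx ? dx.begin() + (size_t)X * Y * Z * C * n : nullptr;
    for (int oz0 = 0; oz0 < OZ; oz0 += slab) {
      int nz = std::min(slab, OZ - oz0);
      size_t rows = (size_t)OX * OY * nz;
      dYb.set_size(rows, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* src = dyn + (size_t)OX * OY * OZ * co + (size_t)OX * OY * oz0;
        float* dst = dYb.colptr(co);
        for (size_t i = 0; i < rows; ++i) dst[i] = (float)src[i];
      }
      if (need_dw) {
        A.set_size(rows, cols);
        im2col3d_slab(xn, X, Y, Z, C, kx, ky, kz, stride, px, py, pz,
                      OX, OY, oz0, nz, A);
        dWm += A.t() * dYb;
        for (int co = 0; co < Cout; ++co)
          db[co] += arma::accu(dYb.col(co));
      }
      if (need_dx) {
        arma::fmat dA = dYb * Wm.t();
        int rowsXY = OX * OY;
        for (int c = 0; c < C; ++c) {
          double* dxc = dxn + (size_t)X * Y * Z * c;
          for (int kk = 0; kk < kz; ++kk) {
            for (int kj = 0; kj < ky; ++kj) {
              for (int ki = 0; ki < kx; ++ki) {
                int col = ki + kx * (kj + ky * (kk + kz * c));
                const float* dAcol = dA.colptr(col);
                for (int zo = 0; zo < nz; ++zo) {
                  int iz = (oz0 + zo) * stride - pz + kk;
                  if (iz < 0 || iz >= Z) continue;
                  double* dxz = dxc + (size_t)X * Y * iz;
                  const float* dAz = dAcol + (size_t)rowsXY * zo;
                  for (int oy = 0; oy < OY; ++oy) {
                    int iy = oy * stride - py + kj;
                    if (iy < 0 || iy >= Y) continue;
                    double* dxrow = dxz + (size_t)X * iy;
                    const float* dArow = dAz + (size_t)OX * oy;
                    for (int ox = 0; ox < OX; ++ox) {
                      int ix = ox * stride - px + ki;
                      if (ix >= 0 && ix < X) dxrow[ix] += dArow[ox];
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  if (need_dw) {
    const float* src = dWm.memptr();
    for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = src[i];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------------------- maxpool2d

// [[Rcpp::export(name = ".maxpool2d_fw")]]
List maxpool2d_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int OW = W / 2, OH = H / 2;
  NumericVector y = alloc_nd({OW, OH, C, N});
  IntegerVector idx = alloc_id({OW, OH, C, N}); // 1-based linear index into x
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + (size_t)W * H * p;
    double* yp = y.begin() + (size_t)OW * OH * p;
    int* ip = idx.begin() + (size_t)OW * OH * p;
    for (int ov = 0; ov < OH; ++ov) {
      for (int ou = 0; ou < OW; ++ou) {
        int best = 2 * ou + W * (2 * ov);
        double bv = xp[best];
        int cand[3] = {2 * ou + 1 + W * (2 * ov), 2 * ou + W * (2 * ov + 1),
                       2 * ou + 1 + W * (2 * ov + 1)};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        yp[ou + OW * ov] = bv;
        ip[ou + OW * ov] = (int)((size_t)W * H * p + best) + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2d_bw")]]
NumericVector maxpool2d_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx = alloc_nd({xdim[0], xdim[1], xdim[2], xdim[3]});
  int n = dy.size();
  for (int i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// --------------------------------------------------------- leaky ReLU

// [[Rcpp::export(name = ".lrelu_fw")]]
NumericVector lrelu_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export(name = ".lrelu_bw")]]
NumericVector lrelu_bw(NumericVector dy, NumericVector x, double slope) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dx;
}
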