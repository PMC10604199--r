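#include <Rcpp.h>
using namespace Rcpp;

// 3D feature maps are stored as R arrays with dims (X, Y, Z, C), column-major.
// Convolutions are lowered to GEMM: vol2col unrolls every receptive field into
// a column of a (kx*ky*kz*C) x (ox*oy*oz) matrix, the matrix product against
// the (Cout x kx*ky*kz*C) weight matrix is done in R via BLAS, and col2vol
// scatters the column-space gradient back onto the input grid.

// [[Rcpp::export]]
NumericMatrix vol2col(const NumericVector& x, const IntegerVector& xdim,
                      const IntegerVector& k, const IntegerVector& pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = X + 2 * px - kx + 1;
  const int oy = Y + 2 * py - ky + 1;
  const int oz = Z + 2 * pz - kz + 1;
  if (ox < 1 || oy < 1 || oz < 1)
    stop("kernel larger than padded input");
  const int nrow = kx * ky * kz * C;
  const int ncol = ox * oy * oz;
  NumericMatrix out(nrow, ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int iz = 0; iz < oz; ++iz) {
    for (int iy = 0; iy < oy; ++iy) {
      for (int ix = 0; ix < ox; ++ix) {
        const R_xlen_t col = (R_xlen_t)ix + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz);
        double* dst = op + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int dz = 0; dz < kz; ++dz) {
            const int sz = iz - pz + dz;
            for (int dy = 0; dy < ky; ++dy) {
              const int sy = iy - py + dy;
              for (int dx = 0; dx < kx; ++dx) {
                const int sx = ix - px + dx;
                double v = 0.0;
                if (sx >= 0 && sx < X && sy >= 0 && sy < Y && sz >= 0 && sz < Z)
                  v = xp[(R_xlen_t)sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * (sz + (R_xlen_t)Z * c))];
                *dst++ = v;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2vol(const NumericMatrix& dcol, const IntegerVector& xdim,
                      const IntegerVector& k, const IntegerVector& pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = X + 2 * px - kx + 1;
  const int oy = Y + 2 * py - ky + 1;
  const int oz = Z + 2 * pz - kz + 1;
  const int nrow = kx * ky * kz * C;
  if (dcol.nrow() != nrow || dcol.ncol() != (R_xlen_t)ox * oy * oz)
    stop("dcol dimensions inconsistent with xdim/k/pad");
  NumericVector dx_out((R_xlen_t)X * Y * Z * C);
  double* xp = dx_out.begin();
  const double* dp = dcol.begin();
  for (int iz = 0; iz < oz; ++iz) {
    for (int iy = 0; iy < oy; ++iy) {
      for (int ix = 0; ix < ox; ++ix) {
        const R_xlen_t col = (R_xlen_t)ix + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz);
        const double* src = dp + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int dz = 0; dz < kz; ++dz) {
            const int sz = iz - pz + dz;
            for (int dy = 0; dy < ky; ++dy) {
              const int sy = iy - py + dy;
              for (int dxk = 0; dxk < kx; ++dxk) {
                const int sx = ix - px + dxk;
                const double v = *src++;
                if (sx >= 0 && sx < X && sy >= 0 && sy < Y && sz >= 0 && sz < Z)
                  xp[(R_xlen_t)sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * (sz + (R_xlen_t)Z * c))] += v;
              }
            }
          }
        }
      }
    }
  }
  dx_out.attr("dim") = xdim;
  return dx_out;
}

// Max pooling with ceil-mode output (windows clipped at the border), stride =
// pool size. Returns the pooled map and 0-based argmax indices for backprop.
// [[Rcpp::export]]
List maxpool3d_fw(const NumericVector& x, const IntegerVector& xdim,
                  const IntegerVector& pool) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int pxs = pool[0], pys = pool[1], pzs = pool[2];
  const int ox = (X + pxs - 1) / pxs;
  const int oy = (Y + pys - 1) / pys;
  const int oz = (Z + pzs - 1) / pzs;
  NumericVector out((R_xlen_t)ox * oy * oz * C);
  IntegerVector arg((R_xlen_t)ox * oy * oz * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c) {
    for (int iz = 0; iz < oz; ++iz) {
      for (int iy = 0; iy < oy; ++iy) {
        for (int ix = 0; ix < ox; ++ix, ++oi) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          const int zmax = std::min(Z, (iz + 1) * pzs);
          const int ymax = std::min(Y, (iy + 1) * pys);
          const int xmax = std::min(X, (ix + 1) * pxs);
          for (int sz = iz * pzs; sz < zmax; ++sz)
            for (int sy = iy * pys; sy < ymax; ++sy)
              for (int sx = ix * pxs; sx < xmax; ++sx) {
                const R_xlen_t li = (R_xlen_t)sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * (sz + (R_xlen_t)Z * c));
                if (xp[li] > best) { best = xp[li]; besti = li; }
              }
          op[oi] = best;
          ap[oi] = (int)besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(const NumericVector& dy, const IntegerVector& argmax,
                           const IntegerVector& xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double* dp = dy.begin();
  const int* ap = argmax.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) xp[ap[i]] += dp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Average pooling, ceil-mode: border windows are clipped and divided by their
// actual voxel count.
// [[Rcpp::export]]
NumericVector avgpool3d_fw(const NumericVector& x, const IntegerVector& xdim,
                           const IntegerVector& pool) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int pxs = pool[0], pys = pool[1], pzs = pool[2];
  const int ox = (X + pxs - 1) / pxs;
  const int oy = (Y + pys - 1) / pys;
  const int oz = (Z + pzs - 1) / pzs;
  NumericVector out((R_xlen_t)ox * oy * oz * C);
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix, ++oi) {
          const int zmax = std::min(Z, (iz + 1) * pzs);
          const int ymax = std::min(Y, (iy + 1) * pys);
          const int xmax = std::min(X, (ix + 1) * pxs);
          double s = 0.0; int cnt = 0;
          for (int sz = iz * pzs; sz < zmax; ++sz)
            for (int sy = iy * pys; sy < ymax; ++sy)
              for (int sx = ix * pxs; sx < xmax; ++sx, ++cnt)
                s += xp[(R_xlen_t)sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * (sz + (R_xlen_t)Z * c))];
          op[oi] = s / cnt;
        }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bw(const NumericVector& dy, const IntegerVector& xdim,
                           const IntegerVector& pool) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int pxs = pool[0], pys = pool[1], pzs = pool[2];
  const int ox = (X + pxs - 1) / pxs;
  const int oy = (Y + pys - 1) / pys;
  const int oz = (Z + pzs - 1) / pzs;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix, ++oi) {
          const int zmax = std::min(Z, (iz + 1) * pzs);
          const int ymax = std::min(Y, (iy + 1) * pys);
          const int xmax = std::min(X, (ix + 1) * pxs);
          const int cnt = (zmax - iz * pzs) * (ymax - iy * pys) * (xmax - ix * pxs);
          const double g = dp[oi] / cnt;
          for (int sz = iz * pzs; sz < zmax; ++sz)
            for (int sy = iy * pys; sy < ymax; ++sy)
              for (int sx = ix * pxs; sx < xmax; ++sx)
                xp[(R_xlen_t)sx + (R_xlen_t)X * (sy + (R_xlen_t)Y * (sz + (R_xlen_t)Z * c))] += g;
        }
  dx.attr("dim") = xdim;
  return dx;
}
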