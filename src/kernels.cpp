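// Compiled tensor kernels for the volumetric networks.
//
// Feature maps are R arrays with dim = c(C, X, Y, Z): channels fastest so a
// map is, in memory, a C x (X*Y*Z) column-major matrix whose columns are
// voxels.  Convolution weights have dim = c(Cout, Cin/groups, kx, ky, kz).
// All spatial conventions are 0-based half-open; padding is zero-padding.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outsz(int X, int k, int s, int d, int p) {
  return (X + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Valid output range [lo, hi] along one axis for kernel-tap offset `off`
// (= tap index * dilation - pad): input index ix = ox*s + off must lie in
// [0, X).
static inline void valid_range(int X, int OX, int s, int off, int &lo, int &hi) {
  lo = 0;
  if (off < 0) lo = (-off + s - 1) / s;
  hi = OX - 1;
  int top = X - 1 - off;
  if (top < 0) { lo = 1; hi = 0; return; }
  int h2 = top / s;
  if (h2 < hi) hi = h2;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector dil,
                             IntegerVector pad, int groups) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0], Cg = wd[1], kx = wd[2], ky = wd[3], kz = wd[4];
  int sx = stride[0], sy = stride[1], sz = stride[2];
  int dx = dil[0], dy = dil[1], dz = dil[2];
  int px = pad[0], py = pad[1], pz = pad[2];
  if (groups == 1 && Cg != C) stop("conv3d: channel mismatch");
  if (groups != 1 && !(groups == C && Cg == 1 && Cout == C))
    stop("conv3d: only groups==1 or depthwise supported");

  int OX = outsz(X, kx, sx, dx, px);
  int OY = outsz(Y, ky, sy, dy, py);
  int OZ = outsz(Z, kz, sz, dz, pz);
  if (OX < 1 || OY < 1 || OZ < 1) stop("conv3d: output would be empty");
  R_xlen_t Nout = (R_xlen_t)OX * OY * OZ;
  NumericVector y((R_xlen_t)Cout * Nout);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w), *bp = REAL(b);

  for (R_xlen_t n = 0; n < Nout; n++) {
    double *yy = yp + (R_xlen_t)Cout * n;
    for (int c = 0; c < Cout; c++) yy[c] = bp[c];
  }

  bool depthwise = (groups == C && groups > 1);
  bool pointwise = (kx == 1 && ky == 1 && kz == 1 && groups == 1 &&
                    sx == 1 && sy == 1 && sz == 1 &&
                    px == 0 && py == 0 && pz == 0);

  if (pointwise) {
    arma::mat Xm(const_cast<double *>(xp), C, (size_t)X * Y * Z, false, true);
    arma::mat Wm(const_cast<double *>(wp), Cout, C, false, true);
    arma::mat Ym(yp, Cout, (size_t)Nout, false, true);
    Ym += Wm * Xm;
  } else if (depthwise) {
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, sz, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, sy, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, sx, offx, xlo, xhi);
          const double *wo = wp + (R_xlen_t)C * (i + kx * (j + (R_xlen_t)ky * k));
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz * sz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy * sy + offy;
              R_xlen_t orow = (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
              R_xlen_t irow = (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              for (int ox = xlo; ox <= xhi; ox++) {
                int ix = ox * sx + offx;
                double *yy = yp + (R_xlen_t)C * (orow + ox);
                const double *xx = xp + (R_xlen_t)C * (irow + ix);
                for (int c = 0; c < C; c++) yy[c] += wo[c] * xx[c];
              }
            }
          }
        }
      }
    }
  } else if (sx == 1 && sy == 1 && sz == 1) {
    // stride-1 dense conv: per kernel tap, gather the shifted input box with
    // contiguous-run copies, one GEMM, then scatter-add into the output box
    int runx_max = OX;
    arma::mat Xs(C, (size_t)OX * OY * OZ);
    arma::mat Wo(Cout, C);
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, 1, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, 1, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, 1, offx, xlo, xhi);
          if (zlo > zhi || ylo > yhi || xlo > xhi) continue;
          int runx = xhi - xlo + 1;
          size_t m = 0;
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy + offy;
              const double *src = xp + (R_xlen_t)C * ((xlo + offx) + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
              std::memcpy(Xs.colptr(m), src, sizeof(double) * (size_t)C * runx);
              m += runx;
            }
          }
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              Wo(co, ci) = wp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))];
          arma::mat Ys = Wo * Xs.cols(0, m - 1);
          size_t t = 0;
          for (int oz = zlo; oz <= zhi; oz++)
            for (int oy = ylo; oy <= yhi; oy++) {
              double *dst = yp + (R_xlen_t)Cout * (xlo + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz));
              const double *srcy = Ys.colptr(t);
              for (R_xlen_t q = 0; q < (R_xlen_t)Cout * runx; q++) dst[q] += srcy[q];
              t += runx;
            }
        }
      }
    }
    (void)runx_max;
  } else {
    arma::mat Xm(const_cast<double *>(xp), C, (size_t)X * Y * Z, false, true);
    arma::mat Ym(yp, Cout, (size_t)Nout, false, true);
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, sz, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, sy, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, sx, offx, xlo, xhi);
          if (zlo > zhi || ylo > yhi || xlo > xhi) continue;
          size_t m = (size_t)(zhi - zlo + 1) * (yhi - ylo + 1) * (xhi - xlo + 1);
          arma::uvec oidx(m), iidx(m);
          size_t t = 0;
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz * sz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy * sy + offy;
              for (int ox = xlo; ox <= xhi; ox++, t++) {
                oidx[t] = (arma::uword)(ox + (size_t)OX * (oy + (size_t)OY * oz));
                iidx[t] = (arma::uword)((ox * sx + offx) + (size_t)X * (iy + (size_t)Y * iz));
              }
            }
          }
          arma::mat Wo(Cout, C);
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              Wo(co, ci) = wp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))];
          Ym.cols(oidx) += Wo * Xm.cols(iidx);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, OX, OY, OZ);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, IntegerVector dil,
                    IntegerVector pad, int groups) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0], Cg = wd[1], kx = wd[2], ky = wd[3], kz = wd[4];
  IntegerVector gd = gy.attr("dim");
  int OX = gd[1], OY = gd[2], OZ = gd[3];
  int sx = stride[0], sy = stride[1], sz = stride[2];
  int dx = dil[0], dy = dil[1], dz = dil[2];
  int px = pad[0], py = pad[1], pz = pad[2];

  NumericVector gx((R_xlen_t)C * X * Y * Z);
  NumericVector gw(w.length());
  NumericVector gb(Cout);
  double *gxp = REAL(gx), *gwp = REAL(gw), *gbp = REAL(gb);
  const double *xp = REAL(x), *wp = REAL(w), *gyp = REAL(gy);
  R_xlen_t Nout = (R_xlen_t)OX * OY * OZ;

  for (R_xlen_t n = 0; n < Nout; n++) {
    const double *gg = gyp + (R_xlen_t)Cout * n;
    for (int c = 0; c < Cout; c++) gbp[c] += gg[c];
  }

  bool depthwise = (groups == C && groups > 1);
  bool pointwise = (kx == 1 && ky == 1 && kz == 1 && groups == 1 &&
                    sx == 1 && sy == 1 && sz == 1 &&
                    px == 0 && py == 0 && pz == 0);

  if (pointwise) {
    arma::mat Xm(const_cast<double *>(xp), C, (size_t)X * Y * Z, false, true);
    arma::mat Wm(const_cast<double *>(wp), Cout, C, false, true);
    arma::mat Gy(const_cast<double *>(gyp), Cout, (size_t)Nout, false, true);
    arma::mat Gx(gxp, C, (size_t)X * Y * Z, false, true);
    arma::mat Gw(gwp, Cout, C, false, true);
    Gx = Wm.t() * Gy;
    Gw = Gy * Xm.t();
  } else if (depthwise) {
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, sz, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, sy, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, sx, offx, xlo, xhi);
          const double *wo = wp + (R_xlen_t)C * (i + kx * (j + (R_xlen_t)ky * k));
          double *gwo = gwp + (R_xlen_t)C * (i + kx * (j + (R_xlen_t)ky * k));
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz * sz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy * sy + offy;
              R_xlen_t orow = (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
              R_xlen_t irow = (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              for (int ox = xlo; ox <= xhi; ox++) {
                int ix = ox * sx + offx;
                const double *gg = gyp + (R_xlen_t)C * (orow + ox);
                const double *xx = xp + (R_xlen_t)C * (irow + ix);
                double *gxx = gxp + (R_xlen_t)C * (irow + ix);
                for (int c = 0; c < C; c++) {
                  gxx[c] += wo[c] * gg[c];
                  gwo[c] += xx[c] * gg[c];
                }
              }
            }
          }
        }
      }
    }
  } else if (sx == 1 && sy == 1 && sz == 1) {
    // stride-1 dense conv backward with contiguous-run copies + GEMMs
    arma::mat Xs(C, (size_t)OX * OY * OZ);
    arma::mat Gs(Cout, (size_t)OX * OY * OZ);
    arma::mat Wo(Cout, C);
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, 1, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, 1, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, 1, offx, xlo, xhi);
          if (zlo > zhi || ylo > yhi || xlo > xhi) continue;
          int runx = xhi - xlo + 1;
          size_t m = 0;
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy + offy;
              const double *srcx = xp + (R_xlen_t)C * ((xlo + offx) + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
              std::memcpy(Xs.colptr(m), srcx, sizeof(double) * (size_t)C * runx);
              const double *srcg = gyp + (R_xlen_t)Cout * (xlo + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz));
              std::memcpy(Gs.colptr(m), srcg, sizeof(double) * (size_t)Cout * runx);
              m += runx;
            }
          }
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              Wo(co, ci) = wp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))];
          arma::mat Gyb = Gs.cols(0, m - 1);
          arma::mat Xsb = Xs.cols(0, m - 1);
          arma::mat Gxb = Wo.t() * Gyb;      // C x m, aligned to input box
          arma::mat Gwo = Gyb * Xsb.t();     // Cout x C
          size_t t = 0;
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy + offy;
              double *dst = gxp + (R_xlen_t)C * ((xlo + offx) + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
              const double *srcb = Gxb.colptr(t);
              for (R_xlen_t q = 0; q < (R_xlen_t)C * runx; q++) dst[q] += srcb[q];
              t += runx;
            }
          }
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              gwp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))] += Gwo(co, ci);
        }
      }
    }
  } else {
    arma::mat Xm(const_cast<double *>(xp), C, (size_t)X * Y * Z, false, true);
    arma::mat Gy(const_cast<double *>(gyp), Cout, (size_t)Nout, false, true);
    arma::mat Gx(gxp, C, (size_t)X * Y * Z, false, true);
    for (int k = 0; k < kz; k++) {
      int offz = k * dz - pz; int zlo, zhi; valid_range(Z, OZ, sz, offz, zlo, zhi);
      for (int j = 0; j < ky; j++) {
        int offy = j * dy - py; int ylo, yhi; valid_range(Y, OY, sy, offy, ylo, yhi);
        for (int i = 0; i < kx; i++) {
          int offx = i * dx - px; int xlo, xhi; valid_range(X, OX, sx, offx, xlo, xhi);
          if (zlo > zhi || ylo > yhi || xlo > xhi) continue;
          size_t m = (size_t)(zhi - zlo + 1) * (yhi - ylo + 1) * (xhi - xlo + 1);
          arma::uvec oidx(m), iidx(m);
          size_t t = 0;
          for (int oz = zlo; oz <= zhi; oz++) {
            int iz = oz * sz + offz;
            for (int oy = ylo; oy <= yhi; oy++) {
              int iy = oy * sy + offy;
              for (int ox = xlo; ox <= xhi; ox++, t++) {
                oidx[t] = (arma::uword)(ox + (size_t)OX * (oy + (size_t)OY * oz));
                iidx[t] = (arma::uword)((ox * sx + offx) + (size_t)X * (iy + (size_t)Y * iz));
              }
            }
          }
          arma::mat Wo(Cout, C);
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              Wo(co, ci) = wp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))];
          arma::mat Gys = Gy.cols(oidx);
          arma::mat Xs = Xm.cols(iidx);
          Gx.cols(iidx) += Wo.t() * Gys;
          arma::mat Gwo = Gys * Xs.t();
          for (int ci = 0; ci < C; ci++)
            for (int co = 0; co < Cout; co++)
              gwp[co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cg * (i + kx * (j + (R_xlen_t)ky * k)))] += Gwo(co, ci);
        }
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Per-axis half-pixel trilinear resize coefficients.
static void axis_coef(int X, int OX, std::vector<int> &i0, std::vector<int> &i1,
                      std::vector<double> &w1) {
  i0.resize(OX); i1.resize(OX); w1.resize(OX);
  for (int o = 0; o < OX; o++) {
    double src = (o + 0.5) * (double)X / OX - 0.5;
    if (src < 0) src = 0;
    if (src > X - 1) src = X - 1;
    int a = (int)std::floor(src);
    if (a > X - 1) a = X - 1;
    i0[o] = a;
    i1[o] = (a + 1 < X) ? a + 1 : a;
    w1[o] = src - a;
  }
}

// [[Rcpp::export]]
NumericVector resize3d_fwd_cpp(NumericVector x, IntegerVector odim) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  int OX = odim[0], OY = odim[1], OZ = odim[2];
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  axis_coef(X, OX, x0, x1, wx);
  axis_coef(Y, OY, y0, y1, wy);
  axis_coef(Z, OZ, z0, z1, wz);
  NumericVector y((R_xlen_t)C * OX * OY * OZ);
  double *yp = REAL(y);
  const double *xp = REAL(x);
  for (int oz = 0; oz < OZ; oz++) {
    for (int oy = 0; oy < OY; oy++) {
      for (int ox = 0; ox < OX; ox++) {
        double *yy = yp + (R_xlen_t)C * (ox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz));
        for (int c = 0; c < C; c++) yy[c] = 0.0;
        for (int cz = 0; cz < 2; cz++) {
          int iz = cz ? z1[oz] : z0[oz];
          double az = cz ? wz[oz] : 1 - wz[oz];
          if (az == 0) continue;
          for (int cy = 0; cy < 2; cy++) {
            int iy = cy ? y1[oy] : y0[oy];
            double ay = cy ? wy[oy] : 1 - wy[oy];
            if (ay == 0) continue;
            for (int cx = 0; cx < 2; cx++) {
              int ix = cx ? x1[ox] : x0[ox];
              double a = az * ay * (cx ? wx[ox] : 1 - wx[ox]);
              if (a == 0) continue;
              const double *xx = xp + (R_xlen_t)C * (ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
              for (int c = 0; c < C; c++) yy[c] += a * xx[c];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  return y;
}

// [[Rcpp::export]]
NumericVector resize3d_bwd_cpp(NumericVector gy, IntegerVector idim) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], OX = gd[1], OY = gd[2], OZ = gd[3];
  int X = idim[0], Y = idim[1], Z = idim[2];
  std::vector<int> x0, x1, y0, y1, z0, z1;
  std::vector<double> wx, wy, wz;
  axis_coef(X, OX, x0, x1, wx);
  axis_coef(Y, OY, y0, y1, wy);
  axis_coef(Z, OZ, z0, z1, wz);
  NumericVector gx((R_xlen_t)C * X * Y * Z);
  double *gxp = REAL(gx);
  const double *gyp = REAL(gy);
  for (int oz = 0; oz < OZ; oz++) {
    for (int oy = 0; oy < OY; oy++) {
      for (int ox = 0; ox < OX; ox++) {
        const double *gg = gyp + (R_xlen_t)C * (ox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz));
        for (int cz = 0; cz < 2; cz++) {
          int iz = cz ? z1[oz] : z0[oz];
          double az = cz ? wz[oz] : 1 - wz[oz];
          if (az == 0) continue;
          for (int cy = 0; cy < 2; cy++) {
            int iy = cy ? y1[oy] : y0[oy];
            double ay = cy ? wy[oy] : 1 - wy[oy];
            if (ay == 0) continue;
            for (int cx = 0; cx < 2; cx++) {
              int ix = cx ? x1[ox] : x0[ox];
              double a = az * ay * (cx ? wx[ox] : 1 - wx[ox]);
              if (a == 0) continue;
              double *gxx = gxp + (R_xlen_t)C * (ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz));
              for (int c = 0; c < C; c++) gxx[c] += a * gg[c];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return gx;
}

// Sample a (X,Y,Z) scalar grid at arbitrary continuous voxel coordinates
// (0-based).  mode 0 = trilinear with `fill` outside, 1 = nearest neighbor.
// [[Rcpp::export]]
NumericVector sample3d_cpp(NumericVector x, NumericMatrix pts, double fill,
                           int mode) {
  IntegerVector xd = x.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2];
  int N = pts.ncol();
  NumericVector out(N);
  const double *xp = REAL(x);
  for (int n = 0; n < N; n++) {
    double u = pts(0, n), v = pts(1, n), w = pts(2, n);
    if (mode == 1) {
      int ix = (int)std::lround(u), iy = (int)std::lround(v), iz = (int)std::lround(w);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= X || iy >= Y || iz >= Z)
        out[n] = fill;
      else
        out[n] = xp[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
      continue;
    }
    if (u < -1 || v < -1 || w < -1 || u > X || v > Y || w > Z) { out[n] = fill; continue; }
    int x0 = (int)std::floor(u), y0 = (int)std::floor(v), z0 = (int)std::floor(w);
    double fx = u - x0, fy = v - y0, fz = w - z0;
    double acc = 0;
    for (int cz = 0; cz < 2; cz++) {
      int iz = z0 + cz; double az = cz ? fz : 1 - fz;
      if (az == 0) continue;
      for (int cy = 0; cy < 2; cy++) {
        int iy = y0 + cy; double ay = cy ? fy : 1 - fy;
        if (ay == 0) continue;
        for (int cx = 0; cx < 2; cx++) {
          int ix = x0 + cx; double a = az * ay * (cx ? fx : 1 - fx);
          if (a == 0) continue;
          double val = fill;
          if (ix >= 0 && iy >= 0 && iz >= 0 && ix < X && iy < Y && iz < Z)
            val = xp[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
          acc += a * val;
        }
      }
    }
    out[n] = acc;
  }
  return out;
}

static const double DT_INF = 1e100;

// One-dimensional lower envelope of parabolas (squared-distance transform)
// with grid spacing `w`.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = 0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

// Exact Euclidean distance (optionally anisotropic spacing) from every voxel
// to the nearest TRUE voxel.  All-FALSE input gives Inf everywhere.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector sites, NumericVector spacing) {
  IntegerVector xd = sites.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2];
  R_xlen_t N = (R_xlen_t)X * Y * Z;
  std::vector<double> d((size_t)N);
  for (R_xlen_t n = 0; n < N; n++) d[n] = sites[n] ? 0.0 : DT_INF;

  std::vector<double> f, g;
  // along x
  f.resize(X); g.resize(X);
  for (int z = 0; z < Z; z++)
    for (int y = 0; y < Y; y++) {
      R_xlen_t base = (R_xlen_t)X * (y + (R_xlen_t)Y * z);
      for (int i = 0; i < X; i++) f[i] = d[base + i];
      dt1d(f, g, X, spacing[0]);
      for (int i = 0; i < X; i++) d[base + i] = g[i];
    }
  // along y
  f.resize(Y); g.resize(Y);
  for (int z = 0; z < Z; z++)
    for (int x = 0; x < X; x++) {
      R_xlen_t base = x + (R_xlen_t)X * Y * z;
      for (int i = 0; i < Y; i++) f[i] = d[base + (R_xlen_t)X * i];
      dt1d(f, g, Y, spacing[1]);
      for (int i = 0; i < Y; i++) d[base + (R_xlen_t)X * i] = g[i];
    }
  // along z
  f.resize(Z); g.resize(Z);
  for (int y = 0; y < Y; y++)
    for (int x = 0; x < X; x++) {
      R_xlen_t base = x + (R_xlen_t)X * y;
      for (int i = 0; i < Z; i++) f[i] = d[base + (R_xlen_t)X * Y * i];
      dt1d(f, g, Z, spacing[2]);
      for (int i = 0; i < Z; i++) d[base + (R_xlen_t)X * Y * i] = g[i];
    }

  NumericVector out(N);
  for (R_xlen_t n = 0; n < N; n++)
    out[n] = d[n] >= DT_INF ? R_PosInf : std::sqrt(d[n]);
  out.attr("dim") = xd;
  return out;
}

// Connected-component labelling of a logical grid, 26- or 6-connectivity.
// Components are numbered 1..n in scan (discovery) order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int connectivity) {
  IntegerVector xd = mask.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2];
  R_xlen_t N = (R_xlen_t)X * Y * Z;
  IntegerVector lab(N);
  std::vector<R_xlen_t> stack;
  std::vector<int> noff;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        noff.push_back(dx); noff.push_back(dy); noff.push_back(dz);
      }
  int cur = 0;
  for (R_xlen_t n = 0; n < N; n++) {
    if (!mask[n] || lab[n]) continue;
    cur++;
    lab[n] = cur;
    stack.push_back(n);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int px = (int)(p % X), py = (int)((p / X) % Y), pz = (int)(p / ((R_xlen_t)X * Y));
      for (size_t q = 0; q < noff.size(); q += 3) {
        int nx = px + noff[q], ny = py + noff[q + 1], nz = pz + noff[q + 2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
        R_xlen_t m = nx + (R_xlen_t)X * (ny + (R_xlen_t)Y * nz);
        if (mask[m] && !lab[m]) {
          lab[m] = cur;
          stack.push_back(m);
        }
      }
    }
  }
  lab.attr("dim") = xd;
  return lab;
}

// Fused elementwise activations returning value and derivative in one pass.
// type: 0 = GELU (exact, erf-based), 1 = SiLU, 2 = sigmoid.
// [[Rcpp::export]]
List act_cpp(NumericVector x, int type) {
  R_xlen_t n = x.length();
  NumericVector y(n), d(n);
  const double *xp = REAL(x);
  double *yp = REAL(y), *dp = REAL(d);
  const double inv_sqrt2 = 0.7071067811865476;
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < n; i++) {
    double v = xp[i];
    if (type == 0) {
      double cdf = 0.5 * (1.0 + std::erf(v * inv_sqrt2));
      yp[i] = v * cdf;
      dp[i] = cdf + v * inv_sqrt2pi * std::exp(-0.5 * v * v);
    } else if (type == 1) {
      double s = 1.0 / (1.0 + std::exp(-v));
      yp[i] = v * s;
      dp[i] = s * (1.0 + v * (1.0 - s));
    } else {
      double s = 1.0 / (1.0 + std::exp(-v));
      yp[i] = s;
      dp[i] = s * (1.0 - s);
    }
  }
  if (!Rf_isNull(x.attr("dim"))) {
    y.attr("dim") = x.attr("dim");
    d.attr("dim") = x.attr("dim");
  }
  return List::create(_["y"] = y, _["d"] = d);
}

// Group normalization over a (C, X, Y, Z) map: statistics are pooled over
// each channel group and all voxels.  Returns y, the normalized xhat
// (needed by the backward pass) and the per-group standard deviations.
// [[Rcpp::export]]
List gn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                int G, double eps) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0];
  R_xlen_t N = 1;
  for (int a = 1; a < xd.size(); a++) N *= xd[a];
  int gsize = C / G;
  NumericVector y((R_xlen_t)C * N), xhat((R_xlen_t)C * N), sg(G);
  const double *xp = REAL(x), *gp = REAL(gamma), *bp = REAL(beta);
  double *yp = REAL(y), *hp = REAL(xhat), *sp = REAL(sg);
  std::vector<double> sum(G, 0.0), sumsq(G, 0.0);
  for (R_xlen_t n = 0; n < N; n++) {
    const double *col = xp + (R_xlen_t)C * n;
    for (int c = 0; c < C; c++) {
      int g = c / gsize;
      if (g >= G) g = G - 1;
      sum[g] += col[c];
      sumsq[g] += col[c] * col[c];
    }
  }
  std::vector<double> mu(G), inv(G);
  for (int g = 0; g < G; g++) {
    double cnt = (double)gsize * N;
    if (g == G - 1) cnt = (double)(C - gsize * (G - 1)) * N;
    mu[g] = sum[g] / cnt;
    double var = sumsq[g] / cnt - mu[g] * mu[g];
    if (var < 0) var = 0;
    sp[g] = std::sqrt(var + eps);
    inv[g] = 1.0 / sp[g];
  }
  for (R_xlen_t n = 0; n < N; n++) {
    const double *col = xp + (R_xlen_t)C * n;
    double *yc = yp + (R_xlen_t)C * n;
    double *hc = hp + (R_xlen_t)C * n;
    for (int c = 0; c < C; c++) {
      int g = c / gsize;
      if (g >= G) g = G - 1;
      double h = (col[c] - mu[g]) * inv[g];
      hc[c] = h;
      yc[c] = h * gp[c] + bp[c];
    }
  }
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sg"] = sg);
}

// [[Rcpp::export]]
List gn_bwd_cpp(NumericVector gy, NumericVector xhat, NumericVector gamma,
                NumericVector sg, int G) {
  IntegerVector xd = gy.attr("dim");
  int C = xd[0];
  R_xlen_t N = 1;
  for (int a = 1; a < xd.size(); a++) N *= xd[a];
  int gsize = C / G;
  NumericVector gx((R_xlen_t)C * N), ggamma(C), gbeta(C);
  const double *gp = REAL(gy), *hp = REAL(xhat), *gam = REAL(gamma),
               *sp = REAL(sg);
  double *gxp = REAL(gx), *ggp = REAL(ggamma), *gbp = REAL(gbeta);
  std::vector<double> smg(G, 0.0), smgx(G, 0.0), cnt(G, 0.0);
  for (R_xlen_t n = 0; n < N; n++) {
    const double *gc = gp + (R_xlen_t)C * n;
    const double *hc = hp + (R_xlen_t)C * n;
    for (int c = 0; c < C; c++) {
      int g = c / gsize;
      if (g >= G) g = G - 1;
      double gh = gc[c] * gam[c];
      smg[g] += gh;
      smgx[g] += gh * hc[c];
      ggp[c] += gc[c] * hc[c];
      gbp[c] += gc[c];
    }
  }
  for (int g = 0; g < G; g++) {
    double n_elem = (double)gsize * N;
    if (g == G - 1) n_elem = (double)(C - gsize * (G - 1)) * N;
    cnt[g] = n_elem;
  }
  for (R_xlen_t n = 0; n < N; n++) {
    const double *gc = gp + (R_xlen_t)C * n;
    const double *hc = hp + (R_xlen_t)C * n;
    double *gxc = gxp + (R_xlen_t)C * n;
    for (int c = 0; c < C; c++) {
      int g = c / gsize;
      if (g >= G) g = G - 1;
      double gh = gc[c] * gam[c];
      gxc[c] = (gh - smg[g] / cnt[g] - hc[c] * smgx[g] / cnt[g]) / sp[g];
    }
  }
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
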