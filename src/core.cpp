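// Numerical core: cubic B-spline interpolation with prefiltering, image
// warping with a finite-difference Jacobian determinant, the coil-weighted
// sampled Fourier forward model and its exact adjoint, the gradient of the
// k-space data term with respect to dense motion fields, and isotropic TV.
//
// Conventions (match the R layer):
//   * images are nx x ny complex matrices, first dimension = x, second = y
//   * coordinates are 0-based and voxel-centered
//   * displacements are pull-back: value at r is sampled at r + D(r), voxels
//   * spline coefficients are zero outside the grid
//   * the Fourier transform is unitary (1/sqrt(nx*ny))
#include <RcppArmadillo.h>  // ARMA_USE_FFTW3 comes from Makevars
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TWOPI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// cubic B-spline kernel
// ---------------------------------------------------------------------------
static inline double bspl3(double t) {
  double s = std::fabs(t);
  if (s < 1.0) return (4.0 - 6.0 * s * s + 3.0 * s * s * s) / 6.0;
  if (s < 2.0) { double u = 2.0 - s; return u * u * u / 6.0; }
  return 0.0;
}

static inline double dbspl3(double t) {
  double s = std::fabs(t), g;
  if (s < 1.0) g = s * (-12.0 + 9.0 * s) / 6.0;
  else if (s < 2.0) { double u = 2.0 - s; g = -0.5 * u * u; }
  else return 0.0;
  return (t < 0.0) ? -g : g;
}

// ---------------------------------------------------------------------------
// prefilter: solve B c = q where B is the symmetric tridiagonal matrix with
// stencil (1/6, 4/6, 1/6) and zero-outside boundary, applied separably.
// B is symmetric, so the prefilter equals its own transpose.
// ---------------------------------------------------------------------------
static void tridiag_cols(cx_mat& X) {
  const uword n = X.n_rows;
  vec cp(n);
  // Thomas algorithm, constant diagonals a=1/6, b=4/6, c=1/6
  const double a = 1.0 / 6.0, b = 4.0 / 6.0;
  cp[0] = a / b;
  for (uword i = 1; i < n; ++i) cp[i] = a / (b - a * cp[i - 1]);
  for (uword j = 0; j < X.n_cols; ++j) {
    cx_double* x = X.colptr(j);
    x[0] /= b;
    for (uword i = 1; i < n; ++i)
      x[i] = (x[i] - a * x[i - 1]) / (b - a * cp[i - 1]);
    for (uword i = n - 1; i-- > 0;)
      x[i] -= cp[i] * x[i + 1];
  }
}

// [[Rcpp::export]]
arma::cx_mat cpp_prefilter(const arma::cx_mat& q) {
  cx_mat c = q;
  tridiag_cols(c);      // along x
  c = c.st();
  tridiag_cols(c);      // along y
  return c.st();
}

// ---------------------------------------------------------------------------
// Jacobian determinant of r -> r + D(r) via forward differences
// (replicated edge: derivative 0 on the far boundary)
// ---------------------------------------------------------------------------
static void fd_jacobian(const mat& Dx, const mat& Dy,
                        mat& a, mat& b, mat& c, mat& d, mat& det) {
  const uword nx = Dx.n_rows, ny = Dx.n_cols;
  a.zeros(nx, ny); b.zeros(nx, ny); c.zeros(nx, ny); d.zeros(nx, ny);
  for (uword j = 0; j < ny; ++j)
    for (uword i = 0; i + 1 < nx; ++i) {
      a(i, j) = Dx(i + 1, j) - Dx(i, j);
      c(i, j) = Dy(i + 1, j) - Dy(i, j);
    }
  for (uword j = 0; j + 1 < ny; ++j)
    for (uword i = 0; i < nx; ++i) {
      b(i, j) = Dx(i, j + 1) - Dx(i, j);
      d(i, j) = Dy(i, j + 1) - Dy(i, j);
    }
  det = (1.0 + a) % (1.0 + d) - b % c;
}

// ---------------------------------------------------------------------------
// interpolation of prefiltered coefficients at displaced positions;
// optionally also the derivatives with respect to the two coordinates
// ---------------------------------------------------------------------------
static void interp_eval(const cx_mat& coef, const mat& Dx, const mat& Dy,
                        cx_mat& u, cx_mat* ux, cx_mat* uy) {
  const int nx = (int)coef.n_rows, ny = (int)coef.n_cols;
  u.set_size(nx, ny);
  if (ux) { ux->set_size(nx, ny); uy->set_size(nx, ny); }
  double wx[4], wy[4], dwx[4], dwy[4];
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double px = i + Dx(i, j), py = j + Dy(i, j);
      if (!std::isfinite(px) || !std::isfinite(py))
        Rcpp::stop("non-finite displacement");
      int ix = (int)std::floor(px), iy = (int)std::floor(py);
      for (int k = 0; k < 4; ++k) {
        double tx = px - (ix - 1 + k), ty = py - (iy - 1 + k);
        wx[k] = bspl3(tx); wy[k] = bspl3(ty);
        if (ux) { dwx[k] = dbspl3(tx); dwy[k] = dbspl3(ty); }
      }
      cx_double v(0, 0), vx(0, 0), vy(0, 0);
      for (int l = 0; l < 4; ++l) {
        int cy = iy - 1 + l;
        if (cy < 0 || cy >= ny) continue;
        cx_double rowv(0, 0), rowdx(0, 0);
        for (int k = 0; k < 4; ++k) {
          int cx_ = ix - 1 + k;
          if (cx_ < 0 || cx_ >= nx) continue;
          cx_double cc = coef(cx_, cy);
          rowv += cc * wx[k];
          if (ux) rowdx += cc * dwx[k];
        }
        v += rowv * wy[l];
        if (ux) { vx += rowdx * wy[l]; vy += rowv * dwy[l]; }
      }
      u(i, j) = v;
      if (ux) { (*ux)(i, j) = vx; (*uy)(i, j) = vy; }
    }
  }
}

// scatter transpose of the interpolation (same real weights), input already
// multiplied by any diagonal factors
static void interp_scatter(cx_mat& acc, const cx_mat& v,
                           const mat& Dx, const mat& Dy) {
  const int nx = (int)acc.n_rows, ny = (int)acc.n_cols;
  double wx[4], wy[4];
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double px = i + Dx(i, j), py = j + Dy(i, j);
      int ix = (int)std::floor(px), iy = (int)std::floor(py);
      for (int k = 0; k < 4; ++k) {
        wx[k] = bspl3(px - (ix - 1 + k));
        wy[k] = bspl3(py - (iy - 1 + k));
      }
      cx_double val = v(i, j);
      for (int l = 0; l < 4; ++l) {
        int cy = iy - 1 + l;
        if (cy < 0 || cy >= ny || wy[l] == 0.0) continue;
        cx_double vl = val * wy[l];
        for (int k = 0; k < 4; ++k) {
          int cx_ = ix - 1 + k;
          if (cx_ < 0 || cx_ >= nx) continue;
          acc(cx_, cy) += vl * wx[k];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cx_mat cpp_warp(const arma::cx_mat& q, const arma::mat& Dx,
                      const arma::mat& Dy) {
  cx_mat coef = cpp_prefilter(q), u;
  mat a, b, c, d, det;
  fd_jacobian(Dx, Dy, a, b, c, d, det);
  interp_eval(coef, Dx, Dy, u, nullptr, nullptr);
  return conv_to<cx_mat>::from(det) % u;
}

// [[Rcpp::export]]
arma::cx_mat cpp_warp_adjoint(const arma::cx_mat& g, const arma::mat& Dx,
                              const arma::mat& Dy) {
  mat a, b, c, d, det;
  fd_jacobian(Dx, Dy, a, b, c, d, det);
  cx_mat v = conv_to<cx_mat>::from(det) % g;
  cx_mat acc(g.n_rows, g.n_cols, fill::zeros);
  interp_scatter(acc, v, Dx, Dy);
  return cpp_prefilter(acc);   // prefilter is symmetric
}

// [[Rcpp::export]]
arma::mat cpp_jacobian_det(const arma::mat& Dx, const arma::mat& Dy) {
  mat a, b, c, d, det;
  fd_jacobian(Dx, Dy, a, b, c, d, det);
  return det;
}

// ---------------------------------------------------------------------------
// sampled Fourier transform per frame.
//  lines == true : samp = 0-based ky line indices; output ordered
//                  (kx fastest) line by line; partial DFT along y.
//  lines == false: samp = 0-based linear indices into the nx x ny k-grid.
// ---------------------------------------------------------------------------
static cx_mat dft_cols_matrix(int ny, const Rcpp::IntegerVector& ky) {
  cx_mat W(ny, ky.size());
  for (int l = 0; l < ky.size(); ++l)
    for (int y = 0; y < ny; ++y) {
      double ph = -TWOPI * (double)ky[l] * (double)y / (double)ny;
      W(y, l) = cx_double(std::cos(ph), std::sin(ph));
    }
  return W;
}

// scratch buffers reused across frames/coils within one batched call;
// W must be refreshed per frame (the sampled lines change)
struct SampWork {
  cx_mat G;       // coil-weighted image
  cx_mat W;       // ny x nlines partial-DFT matrix (lines scheme)
  cx_mat A, S;    // intermediates
  void setFrame(int ny, const Rcpp::IntegerVector& samp, bool lines) {
    if (lines) W = dft_cols_matrix(ny, samp);
  }
};

// forward through coils + sampling for one frame image h.
// lines scheme evaluates the small partial DFT along y first, then the
// x-FFT on the reduced nx x nlines block (order is interchangeable).
static void frame_forward(cx_mat& out, const cx_mat& h, const cx_cube& coils,
                          const Rcpp::IntegerVector& samp, bool lines,
                          double scale, SampWork& wk) {
  const int nx = (int)h.n_rows, ny = (int)h.n_cols;
  const uword C = coils.n_slices;
  uword nsamp = lines ? (uword)nx * (uword)samp.size() : (uword)samp.size();
  out.set_size(nsamp, C);
  for (uword c = 0; c < C; ++c) {
    wk.G = coils.slice(c) % h;
    if (lines) {
      wk.A = wk.G * wk.W;                 // nx x nlines partial DFT (y)
      wk.S = fft(wk.A);                   // DFT along x
      std::transform(wk.S.begin(), wk.S.end(), out.colptr(c),
                     [scale](cx_double v) { return v * scale; });
    } else {
      wk.S = fft2(wk.G);
      cx_double* o = out.colptr(c);
      for (int s = 0; s < samp.size(); ++s) o[s] = wk.S[samp[s]] * scale;
    }
  }
}

// image-domain backprojection of per-coil samples (adjoint up to, but not
// including, the warp)
static void frame_backproject(cx_mat& g, const cx_mat& r, int nx, int ny,
                              const cx_cube& coils,
                              const Rcpp::IntegerVector& samp, bool lines,
                              double scale, SampWork& wk) {
  const uword C = coils.n_slices;
  g.zeros(nx, ny);
  for (uword c = 0; c < C; ++c) {
    if (lines) {
      const uword nl = (uword)samp.size();
      cx_mat S(const_cast<cx_double*>(r.colptr(c)), (uword)nx, nl, false,
               true);
      // adjoint of unnormalized DFT along x = nx * ifft
      wk.A = (double)nx * scale * ifft(S);
      wk.G = wk.A * wk.W.t();             // W^H on the right
    } else {
      cx_mat Z(nx, ny, fill::zeros);
      const cx_double* v = r.colptr(c);
      for (int s = 0; s < samp.size(); ++s) Z[samp[s]] += v[s];
      wk.G = (double)(nx * ny) * scale * ifft2(Z);
    }
    g += conj(coils.slice(c)) % wk.G;
  }
}

// ---------------------------------------------------------------------------
// batched operators over frames
// ---------------------------------------------------------------------------

// wrap an R numeric vector as an arma cube without copying
static cube cube_view(Rcpp::NumericVector v, int nx, int ny, int M) {
  if ((long long)v.size() != (long long)nx * ny * M)
    Rcpp::stop("displacement array has the wrong size");
  return cube(v.begin(), nx, ny, M, false, true);
}

// [[Rcpp::export]]
Rcpp::List cpp_forward_all(const arma::cx_mat& Q, int nx, int ny,
                           const arma::cx_cube& coils,
                           Rcpp::NumericVector Dx, Rcpp::NumericVector Dy,
                           Rcpp::List samp, bool lines, bool warp) {
  const int M = (int)Q.n_cols;
  const double scale = 1.0 / std::sqrt((double)(nx * ny));
  cube dxc = cube_view(Dx, nx, ny, warp ? M : 0),
       dyc = cube_view(Dy, nx, ny, warp ? M : 0);
  Rcpp::List out(M);
  SampWork wk;
  cx_mat s;
  for (int t = 0; t < M; ++t) {
    Rcpp::IntegerVector st = samp[t];
    wk.setFrame(ny, st, lines);
    cx_mat q(const_cast<cx_double*>(Q.colptr(t)), nx, ny, false, true);
    cx_mat h = warp ? cpp_warp(q, dxc.slice(t), dyc.slice(t)) : cx_mat(q);
    frame_forward(s, h, coils, st, lines, scale, wk);
    out[t] = Rcpp::wrap(s);
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_mat cpp_adjoint_all(Rcpp::List data, int nx, int ny,
                             const arma::cx_cube& coils,
                             Rcpp::NumericVector Dx, Rcpp::NumericVector Dy,
                             Rcpp::List samp, bool lines, bool warp) {
  const int M = data.size();
  const double scale = 1.0 / std::sqrt((double)(nx * ny));
  cube dxc = cube_view(Dx, nx, ny, warp ? M : 0),
       dyc = cube_view(Dy, nx, ny, warp ? M : 0);
  cx_mat out((uword)(nx * ny), (uword)M);
  SampWork wk;
  cx_mat g;
  for (int t = 0; t < M; ++t) {
    Rcpp::IntegerVector st = samp[t];
    wk.setFrame(ny, st, lines);
    cx_mat r = Rcpp::as<cx_mat>(data[t]);
    frame_backproject(g, r, nx, ny, coils, st, lines, scale, wk);
    if (warp) g = cpp_warp_adjoint(g, dxc.slice(t), dyc.slice(t));
    out.col(t) = vectorise(g);
  }
  return out;
}

// data term sum_t ||F q_t - s_t||^2 and its gradient F^H r with respect to
// Q (for the L+S step; D fixed)
// [[Rcpp::export]]
Rcpp::List cpp_lps_resid_grad(const arma::cx_mat& Q, int nx, int ny,
                              const arma::cx_cube& coils,
                              Rcpp::NumericVector Dx, Rcpp::NumericVector Dy,
                              Rcpp::List samp, Rcpp::List data, bool lines,
                              bool warp, bool want_grad) {
  const int M = (int)Q.n_cols;
  const double scale = 1.0 / std::sqrt((double)(nx * ny));
  cube dxc = cube_view(Dx, nx, ny, warp ? M : 0),
       dyc = cube_view(Dy, nx, ny, warp ? M : 0);
  cx_mat G;
  if (want_grad) G.set_size((uword)(nx * ny), (uword)M);
  double value = 0.0;
  SampWork wk;
  cx_mat r, g;
  for (int t = 0; t < M; ++t) {
    Rcpp::IntegerVector st = samp[t];
    wk.setFrame(ny, st, lines);
    cx_mat q(const_cast<cx_double*>(Q.colptr(t)), nx, ny, false, true);
    cx_mat h = warp ? cpp_warp(q, dxc.slice(t), dyc.slice(t)) : cx_mat(q);
    frame_forward(r, h, coils, st, lines, scale, wk);
    r -= Rcpp::as<cx_mat>(data[t]);
    value += accu(square(abs(r)));
    if (!want_grad) continue;
    frame_backproject(g, r, nx, ny, coils, st, lines, scale, wk);
    if (warp) g = cpp_warp_adjoint(g, dxc.slice(t), dyc.slice(t));
    G.col(t) = vectorise(g);
  }
  if (!want_grad) return Rcpp::List::create(Rcpp::Named("value") = value);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("grad") = G);
}

// data term sum_t ||F(q_t | D_t) - s_t||^2 and its gradient with respect to
// the dense displacement fields. Qcoef holds prefiltered spline coefficients
// of each frame of Q (fixed during the motion step).
// [[Rcpp::export]]
Rcpp::List cpp_motion_obj_grad(const arma::cx_mat& Qcoef, int nx, int ny,
                               const arma::cx_cube& coils,
                               Rcpp::NumericVector Dx, Rcpp::NumericVector Dy,
                               Rcpp::List samp, Rcpp::List data, bool lines,
                               bool want_grad) {
  const int M = (int)Qcoef.n_cols;
  const double scale = 1.0 / std::sqrt((double)(nx * ny));
  cube dxc = cube_view(Dx, nx, ny, M), dyc = cube_view(Dy, nx, ny, M);
  double value = 0.0;
  Rcpp::NumericVector GxR, GyR;
  cube Gx, Gy;
  if (want_grad) {
    GxR = Rcpp::NumericVector((R_xlen_t)nx * ny * M);
    GyR = Rcpp::NumericVector((R_xlen_t)nx * ny * M);
    Gx = cube(GxR.begin(), nx, ny, M, false, true);
    Gy = cube(GyR.begin(), nx, ny, M, false, true);
  }
  SampWork wk;
  cx_mat u, ux, uy, r, g;
  mat a, b, c, d, det;
  for (int t = 0; t < M; ++t) {
    Rcpp::IntegerVector st = samp[t];
    wk.setFrame(ny, st, lines);
    cx_mat coef(const_cast<cx_double*>(Qcoef.colptr(t)), nx, ny, false, true);
    const mat& dx = dxc.slice(t);
    const mat& dy = dyc.slice(t);
    fd_jacobian(dx, dy, a, b, c, d, det);
    interp_eval(coef, dx, dy, u, want_grad ? &ux : nullptr,
                want_grad ? &uy : nullptr);
    cx_mat h = conv_to<cx_mat>::from(det) % u;
    frame_forward(r, h, coils, st, lines, scale, wk);
    r -= Rcpp::as<cx_mat>(data[t]);
    value += accu(square(abs(r)));
    if (!want_grad) continue;
    frame_backproject(g, r, nx, ny, coils, st, lines, scale, wk);
    mat gx(Gx.slice_memptr(t), nx, ny, false, true);
    mat gy(Gy.slice_memptr(t), nx, ny, false, true);
    // interpolation part: 2 Re[conj(g) det u_{x,y}]
    mat w(nx, ny);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        cx_double cg = std::conj(g(i, j));
        gx(i, j) = 2.0 * det(i, j) * (cg * ux(i, j)).real();
        gy(i, j) = 2.0 * det(i, j) * (cg * uy(i, j)).real();
        w(i, j) = 2.0 * (cg * u(i, j)).real();
      }
    // determinant part: det = (1+a)(1+d) - b c with forward differences
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double wa = w(i, j) * (1.0 + d(i, j));   // d det / d a
        gx(i + 1, j) += wa; gx(i, j) -= wa;
        double wc = -w(i, j) * b(i, j);          // d det / d c
        gy(i + 1, j) += wc; gy(i, j) -= wc;
      }
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double wb = -w(i, j) * c(i, j);          // d det / d b
        gx(i, j + 1) += wb; gx(i, j) -= wb;
        double wd = w(i, j) * (1.0 + a(i, j));   // d det / d d
        gy(i, j + 1) += wd; gy(i, j) -= wd;
      }
  }
  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = value);
  GxR.attr("dim") = Rcpp::IntegerVector::create(nx, ny, M);
  GyR.attr("dim") = Rcpp::IntegerVector::create(nx, ny, M);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gx") = GxR,
                            Rcpp::Named("gy") = GyR);
}

// ---------------------------------------------------------------------------
// isotropic total variation of the displacement fields: per frame
//   sum_i sqrt(|grad Dx|_i^2 + |grad Dy|_i^2)
// with forward differences and zero-flux boundary, summed over frames.
// The gradient treats zero-norm pixels by their zero subgradient.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_tv(Rcpp::NumericVector Dx, Rcpp::NumericVector Dy,
                  int nx, int ny, int M, bool want_grad) {
  cube dxc = cube_view(Dx, nx, ny, M), dyc = cube_view(Dy, nx, ny, M);
  double value = 0.0;
  cube Gx, Gy;
  Rcpp::NumericVector GxR, GyR;
  if (want_grad) {
    GxR = Rcpp::NumericVector((R_xlen_t)nx * ny * M);
    GyR = Rcpp::NumericVector((R_xlen_t)nx * ny * M);
    Gx = cube(GxR.begin(), nx, ny, M, false, true);
    Gy = cube(GyR.begin(), nx, ny, M, false, true);
  }
  for (int t = 0; t < M; ++t) {
    const mat dx(const_cast<double*>(dxc.slice_memptr(t)), nx, ny, false,
                 true);
    const mat dy(const_cast<double*>(dyc.slice_memptr(t)), nx, ny, false,
                 true);
    double* gxp = want_grad ? Gx.slice_memptr(t) : nullptr;
    double* gyp = want_grad ? Gy.slice_memptr(t) : nullptr;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double ax = (i + 1 < nx) ? dx(i + 1, j) - dx(i, j) : 0.0;
        double bx = (j + 1 < ny) ? dx(i, j + 1) - dx(i, j) : 0.0;
        double ay = (i + 1 < nx) ? dy(i + 1, j) - dy(i, j) : 0.0;
        double by = (j + 1 < ny) ? dy(i, j + 1) - dy(i, j) : 0.0;
        double n = std::sqrt(ax * ax + bx * bx + ay * ay + by * by);
        value += n;
        if (!want_grad || n == 0.0) continue;
        double inv = 1.0 / n;
        const int p = i + nx * j;
        if (i + 1 < nx) {
          gxp[p + 1] += ax * inv; gxp[p] -= ax * inv;
          gyp[p + 1] += ay * inv; gyp[p] -= ay * inv;
        }
        if (j + 1 < ny) {
          gxp[p + nx] += bx * inv; gxp[p] -= bx * inv;
          gyp[p + nx] += by * inv; gyp[p] -= by * inv;
        }
      }
  }
  if (!want_grad) return Rcpp::List::create(Rcpp::Named("value") = value);
  GxR.attr("dim") = Rcpp::IntegerVector::create(nx, ny, M);
  GyR.attr("dim") = Rcpp::IntegerVector::create(nx, ny, M);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gx") = GxR,
                            Rcpp::Named("gy") = GyR);
}

// ---------------------------------------------------------------------------
// unitary DFT along the frame (column) axis of a voxels x frames matrix
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::cx_mat cpp_temporal_fft(const arma::cx_mat& X, bool inverse) {
  const double s = 1.0 / std::sqrt((double)X.n_cols);
  // FFT acts along columns; transpose so frames run down a column
  cx_mat Y = X.st();
  Y = inverse ? cx_mat(ifft(Y) * (double)Y.n_rows) : fft(Y);
  return Y.st() * s;
}
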