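// 3D convolution primitives for the context-encoder networks.
//
// Feature maps are stored as arma::cube with dimensions (channels, voxels,
// batch); the voxel axis flattens a (d1, d2, d3) grid with the first grid
// axis fastest (R array order). Convolution weights are (C_out, C_in*k^3)
// with inner ordering c_in fastest, then kx, ky, kz; transposed-convolution
// weights are (C_in, C_out*k^3) laid out as the weights of the adjoint
// convolution (large grid -> small grid), so tconv_forward is exactly the
// data-backward pass of that convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int conv_out_dim(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Gather sliding windows: x (C_in x V_in) -> cols (C_in*k^3 x V_out).
// cols must be zero-initialised; out-of-range taps stay zero (zero padding).
static void vol2col(const mat& x, int d1, int d2, int d3,
                    int k, int s, int p, mat& cols,
                    int o1, int o2, int o3) {
  const int cin = x.n_rows;
  for (int oz = 0; oz < o3; ++oz) {
    const int iz0 = oz * s - p;
    for (int oy = 0; oy < o2; ++oy) {
      const int iy0 = oy * s - p;
      for (int ox = 0; ox < o1; ++ox) {
        const int ix0 = ox * s - p;
        double* cptr = cols.colptr(ox + (size_t)o1 * (oy + (size_t)o2 * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = iz0 + kz;
          if (iz < 0 || iz >= d3) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= d2) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ix0 + kx;
              if (ix < 0 || ix >= d1) continue;
              const double* src = x.colptr(ix + (size_t)d1 * (iy + (size_t)d2 * iz));
              double* dst = cptr + (size_t)cin * (kx + (size_t)k * (ky + (size_t)k * kz));
              std::memcpy(dst, src, cin * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Scatter-add inverse of vol2col: cols (C_in*k^3 x V_out) += into x (C_in x V_in).
static void col2vol(const mat& cols, int d1, int d2, int d3,
                    int k, int s, int p, mat& x,
                    int o1, int o2, int o3) {
  const int cin = x.n_rows;
  for (int oz = 0; oz < o3; ++oz) {
    const int iz0 = oz * s - p;
    for (int oy = 0; oy < o2; ++oy) {
      const int iy0 = oy * s - p;
      for (int ox = 0; ox < o1; ++ox) {
        const int ix0 = ox * s - p;
        const double* cptr = cols.colptr(ox + (size_t)o1 * (oy + (size_t)o2 * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = iz0 + kz;
          if (iz < 0 || iz >= d3) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= d2) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ix0 + kx;
              if (ix < 0 || ix >= d1) continue;
              double* dst = x.colptr(ix + (size_t)d1 * (iy + (size_t)d2 * iz));
              const double* src = cptr + (size_t)cin * (kx + (size_t)k * (ky + (size_t)k * kz));
              for (int c = 0; c < cin; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv3d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b,
                          int d1, int d2, int d3, int k, int s, int p) {
  const int o1 = conv_out_dim(d1, k, s, p);
  const int o2 = conv_out_dim(d2, k, s, p);
  const int o3 = conv_out_dim(d3, k, s, p);
  const size_t vout = (size_t)o1 * o2 * o3;
  const int n = x.n_slices;
  cube y(W.n_rows, vout, n);
  mat cols(W.n_cols, vout);
  for (int i = 0; i < n; ++i) {
    cols.zeros();
    vol2col(x.slice(i), d1, d2, d3, k, s, p, cols, o1, o2, o3);
    y.slice(i) = W * cols;
    y.slice(i).each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy,
                          int d1, int d2, int d3, int k, int s, int p,
                          bool need_gx, bool need_gw) {
  const int o1 = conv_out_dim(d1, k, s, p);
  const int o2 = conv_out_dim(d2, k, s, p);
  const int o3 = conv_out_dim(d3, k, s, p);
  const size_t vout = (size_t)o1 * o2 * o3;
  const int n = x.n_slices;
  cube gx;
  if (need_gx) gx.zeros(x.n_rows, x.n_cols, n);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(W.n_rows, fill::zeros);
  mat cols(W.n_cols, vout);
  for (int i = 0; i < n; ++i) {
    const mat& g = gy.slice(i);
    gb += sum(g, 1);
    if (need_gw) {
      cols.zeros();
      vol2col(x.slice(i), d1, d2, d3, k, s, p, cols, o1, o2, o3);
      gW += g * cols.t();
    }
    if (need_gx) {
      mat gcols = W.t() * g;
      mat gxi(x.n_rows, x.n_cols, fill::zeros);
      col2vol(gcols, d1, d2, d3, k, s, p, gxi, o1, o2, o3);
      gx.slice(i) = gxi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Transposed convolution small grid (ds) -> large grid (dl); W is
// (C_in, C_out*k^3), the adjoint convolution's weight matrix.
// [[Rcpp::export]]
arma::cube cpp_tconv3d_fwd(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b,
                           int dl1, int dl2, int dl3, int k, int s, int p) {
  const int o1 = conv_out_dim(dl1, k, s, p);
  const int o2 = conv_out_dim(dl2, k, s, p);
  const int o3 = conv_out_dim(dl3, k, s, p);
  const size_t vl = (size_t)dl1 * dl2 * dl3;
  const int cout = W.n_cols / (k * k * k);
  const int n = x.n_slices;
  cube y(cout, vl, n);
  for (int i = 0; i < n; ++i) {
    mat gcols = W.t() * x.slice(i);  // (C_out*k^3) x Vs
    mat yi(cout, vl, fill::zeros);
    col2vol(gcols, dl1, dl2, dl3, k, s, p, yi, o1, o2, o3);
    yi.each_col() += b;
    y.slice(i) = yi;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_tconv3d_bwd(const arma::cube& x, const arma::mat& W,
                           const arma::cube& gy,
                           int dl1, int dl2, int dl3, int k, int s, int p,
                           bool need_gx, bool need_gw) {
  const int o1 = conv_out_dim(dl1, k, s, p);
  const int o2 = conv_out_dim(dl2, k, s, p);
  const int o3 = conv_out_dim(dl3, k, s, p);
  const size_t vout = (size_t)o1 * o2 * o3;
  const int n = x.n_slices;
  const int kk = k * k * k;
  const int cout = W.n_cols / kk;
  cube gx;
  if (need_gx) gx.zeros(x.n_rows, x.n_cols, n);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(cout, fill::zeros);
  mat cols((size_t)cout * kk, vout);
  for (int i = 0; i < n; ++i) {
    const mat& g = gy.slice(i);  // C_out x Vl
    gb += sum(g, 1);
    cols.zeros();
    vol2col(g, dl1, dl2, dl3, k, s, p, cols, o1, o2, o3);
    if (need_gx) gx.slice(i) = W * cols;
    if (need_gw) gW += x.slice(i) * cols.t();
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Separable Gaussian smoothing with zero padding; kernel normalised to sum 1.
// [[Rcpp::export]]
arma::vec cpp_gauss_smooth3(const arma::vec& v, int d1, int d2, int d3,
                            double sigma) {
  if (sigma <= 0) return v;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec ker(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    ker(i + r) = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  ker /= accu(ker);
  vec a = v, b(v.n_elem);
  const int dims[3] = {d1, d2, d3};
  const int strides[3] = {1, d1, d1 * d2};
  for (int ax = 0; ax < 3; ++ax) {
    const int dd = dims[ax];
    const int st = strides[ax];
    b.zeros();
    for (int z = 0; z < d3; ++z)
      for (int y = 0; y < d2; ++y)
        for (int x = 0; x < d1; ++x) {
          const int idx[3] = {x, y, z};
          const size_t lin = x + (size_t)d1 * (y + (size_t)d2 * z);
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            const int q = idx[ax] + t;
            if (q < 0 || q >= dd) continue;
            acc += ker(t + r) * a(lin + (size_t)(q - idx[ax]) * st);
          }
          b(lin) = acc;
        }
    a = b;
  }
  return a;
}
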