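// Low-level numerical kernels: blocked im2col 3D convolution (forward and
// weight gradient) and trilinear resampling.  Activations are stored as
// N x C matrices over a flattened x-fastest voxel grid; `idx` holds, for
// each voxel, the 1-based linear indices of its 27 neighbours (0 = outside
// the grid, i.e. zero padding).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Forward 3^3 convolution.  W is (27*Cin) x Cout with row layout
// k + 27*(c_in - 1) for neighbour offset k; b is length Cout.
// [[Rcpp::export]]
arma::mat conv3d_fwd_cpp(const arma::mat& X, const IntegerMatrix& idx,
                         const arma::mat& W, const arma::rowvec& b) {
  const int N = idx.nrow(), K = idx.ncol(), C = X.n_cols;
  const int Cout = W.n_cols;
  arma::mat Y(N, Cout, arma::fill::zeros);
  arma::mat Xk(N, C);
  arma::mat Wk(C, Cout);
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double* xc = X.colptr(c);
      double* out = Xk.colptr(c);
      for (int i = 0; i < N; ++i) {
        const int j = ik[i];
        out[i] = (j > 0) ? xc[j - 1] : 0.0;
      }
    }
    for (int c = 0; c < C; ++c) Wk.row(c) = W.row(k + K * c);
    Y += Xk * Wk;
  }
  Y.each_row() += b;
  return Y;
}

// Gradient of the convolution with respect to W: dW = im2col(X)^T * dY,
// accumulated per neighbour offset so the im2col matrix is never formed.
// [[Rcpp::export]]
arma::mat conv3d_gw_cpp(const arma::mat& X, const IntegerMatrix& idx,
                        const arma::mat& dY) {
  const int N = idx.nrow(), K = idx.ncol(), C = X.n_cols;
  const int Cout = dY.n_cols;
  arma::mat dW(K * C, Cout, arma::fill::zeros);
  arma::mat Xk(N, C);
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double* xc = X.colptr(c);
      double* out = Xk.colptr(c);
      for (int i = 0; i < N; ++i) {
        const int j = ik[i];
        out[i] = (j > 0) ? xc[j - 1] : 0.0;
      }
    }
    arma::mat g = Xk.t() * dY;  // C x Cout
    for (int c = 0; c < C; ++c) dW.row(k + K * c) = g.row(c);
  }
  return dW;
}

// Trilinear interpolation of a 3D volume at arbitrary (1-based, voxel
// coordinate) sample points; points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector trilerp_cpp(const NumericVector& vol, const IntegerVector& dim,
                          const NumericMatrix& pts, double fill) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 1.0 || x > d1 || y < 1.0 || y > d2 || z < 1.0 || z > d3) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == d1) x0--;
    if (y0 == d2) y0--;
    if (z0 == d3) z0--;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const long long base = (long long)(x0 - 1) +
      (long long)d1 * ((long long)(y0 - 1) + (long long)d2 * (long long)(z0 - 1));
    const long long sx = 1, sy = d1, sz = (long long)d1 * d2;
    const double c000 = v[base],            c100 = v[base + sx];
    const double c010 = v[base + sy],       c110 = v[base + sx + sy];
    const double c001 = v[base + sz],       c101 = v[base + sx + sz];
    const double c011 = v[base + sy + sz],  c111 = v[base + sx + sy + sz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
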