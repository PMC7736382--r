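// Valid 3x3x3 convolution kernels for the multi-resolution patch network.
// Layout conventions (match R's column-major arrays):
//   activations: dim (nx, ny, nz, C), x fastest
//   weights:     matrix (27*Cin) x Cout, row index = dx + 3*dy + 9*dz + 27*cin
// im2col builds an N x (27*Cin) matrix (N = output voxels) so that
//   out = col * W  and  gradW = col' * gout,  gradCol = gout * W'.
// Arithmetic runs in single precision (the usual choice for network
// training); inputs and outputs are R doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dv = x.attr("dim");
  if (dv.size() != 4) stop("expected a 4-d array (x, y, z, channel)");
  for (int i = 0; i < 4; ++i) d[i] = dv[i];
}

static void im2col3(const float* x, int nx, int ny, int nz, int nc,
                    arma::fmat& col) {
  const int ox = nx - 2, oy = ny - 2, oz = nz - 2;
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    const float* base = x + (size_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; ++dz)
      for (int dy = 0; dy < 3; ++dy)
        for (int dx = 0; dx < 3; ++dx, ++k) {
          float* dst = col.colptr(k);
          for (int z = 0; z < oz; ++z) {
            const float* plane = base + (size_t)(z + dz) * nx * ny;
            for (int y = 0; y < oy; ++y) {
              std::memcpy(dst, plane + (size_t)(y + dy) * nx + dx,
                          (size_t)ox * sizeof(float));
              dst += ox;
            }
          }
        }
  }
}

static arma::fvec to_float(const double* p, size_t n) {
  arma::fvec v(n);
  for (size_t i = 0; i < n; ++i) v[i] = (float)p[i];
  return v;
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, const arma::mat& w,
                                 const arma::vec& b) {
  int d[4];
  dims4(x, d);
  const int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  if (nx < 3 || ny < 3 || nz < 3) stop("input smaller than kernel");
  const int cout = (int)w.n_cols;
  if ((int)w.n_rows != 27 * nc) stop("weight rows != 27 * in-channels");
  const int ox = nx - 2, oy = ny - 2, oz = nz - 2;
  const size_t N = (size_t)ox * oy * oz;

  arma::fvec xf = to_float(x.begin(), x.size());
  arma::fmat col(N, 27 * nc);
  im2col3(xf.memptr(), nx, ny, nz, nc, col);
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());

  arma::fmat outf = col * wf;
  outf.each_row() += bf;

  NumericVector out((R_xlen_t)N * cout);
  const float* src = outf.memptr();
  double* dst = out.begin();
  for (size_t i = 0, nn = N * (size_t)cout; i < nn; ++i) dst[i] = src[i];
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, const arma::mat& w,
                         NumericVector gout) {
  int d[4], dg[4];
  dims4(x, d);
  dims4(gout, dg);
  const int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  const int ox = dg[0], oy = dg[1], oz = dg[2], cout = dg[3];
  if (ox != nx - 2 || oy != ny - 2 || oz != nz - 2)
    stop("gradient dims do not match valid-convolution output");
  if ((int)w.n_rows != 27 * nc || (int)w.n_cols != cout)
    stop("weight dims inconsistent");
  const size_t N = (size_t)ox * oy * oz;

  arma::fvec xf = to_float(x.begin(), x.size());
  arma::fmat col(N, 27 * nc);
  im2col3(xf.memptr(), nx, ny, nz, nc, col);
  arma::fvec gf = to_float(gout.begin(), gout.size());
  arma::fmat goutm(gf.memptr(), N, cout, false, true);
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);

  arma::fmat gw = col.t() * goutm;                // (27*Cin) x Cout
  arma::fvec gb = arma::sum(goutm, 0).t();
  arma::fmat gcol = goutm * wf.t();               // N x (27*Cin)

  NumericVector gx((R_xlen_t)nx * ny * nz * nc);  // zero-initialised
  std::vector<float> gxa((size_t)nx * ny * nz * nc, 0.0f);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    float* base = gxa.data() + (size_t)c * nx * ny * nz;
    for (int dz = 0; dz < 3; ++dz)
      for (int dy = 0; dy < 3; ++dy)
        for (int dx = 0; dx < 3; ++dx, ++k) {
          const float* src = gcol.colptr(k);
          for (int z = 0; z < oz; ++z) {
            float* plane = base + (size_t)(z + dz) * nx * ny;
            for (int y = 0; y < oy; ++y) {
              float* dst = plane + (size_t)(y + dy) * nx + dx;
              for (int xx = 0; xx < ox; ++xx) dst[xx] += *src++;
            }
          }
        }
  }
  double* gxp = gx.begin();
  for (size_t i = 0; i < gxa.size(); ++i) gxp[i] = gxa[i];
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return List::create(_["gx"] = gx,
                      _["gw"] = arma::conv_to<arma::mat>::from(gw),
                      _["gb"] = arma::conv_to<arma::vec>::from(gb));
}
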