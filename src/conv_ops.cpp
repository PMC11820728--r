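// Low-level tensor kernels for the package's CNN engine.
// Tensors are H x W x C arma::cubes (R arrays with dim c(H, W, C)).
// Convolution is im2col + one BLAS gemm; backward recomputes the column
// matrix rather than caching it, trading FLOPs for memory on 1-CPU hosts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_dim(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Column layout: row index q = c*k*k + kj*k + ki (ki = kernel row offset,
// kj = kernel col offset); column index = oj*Ho + oi. Weight matrices are
// (C_out x C_in*k*k) with matching column order.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, pad, dil);
  const int Wo = out_dim(W, k, stride, pad, dil);
  mat cols(C * k * k, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj * dil;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            cols(q, oj * Ho + oi) = x(ii, ij, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int k, int stride, int pad, int dil) {
  const int Ho = out_dim(H, k, stride, pad, dil);
  const int Wo = out_dim(W, k, stride, pad, dil);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj * dil;
          if (ij < 0 || ij >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            x(ii, ij, c) += cols(q, oj * Ho + oi);
          }
        }
      }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::vec& b, int k, int stride, int pad, int dil) {
  const int Ho = out_dim(x.n_rows, k, stride, pad, dil);
  const int Wo = out_dim(x.n_cols, k, stride, pad, dil);
  const int Cout = Wm.n_rows;
  mat cols = cpp_im2col(x, k, stride, pad, dil);
  mat y = cols.t() * Wm.t();            // (Ho*Wo) x Cout
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::cube& dy, int k, int stride, int pad, int dil) {
  const int HoWo = dy.n_rows * dy.n_cols;
  const int Cout = dy.n_slices;
  mat dym(const_cast<double*>(dy.memptr()), HoWo, Cout, false, true);
  mat cols = cpp_im2col(x, k, stride, pad, dil);
  mat dW = dym.t() * cols.t();          // Cout x (Cin*k*k)
  vec db = sum(dym, 0).t();
  mat dcols = (dym * Wm).t();           // (Cin*k*k) x (Ho*Wo)
  cube dx = cpp_col2im(dcols, x.n_rows, x.n_cols, x.n_slices, k, stride, pad, dil);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_upsample_nearest(const arma::cube& x, int f) {
  cube y(x.n_rows * f, x.n_cols * f, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c)
    for (unsigned j = 0; j < y.n_cols; ++j)
      for (unsigned i = 0; i < y.n_rows; ++i)
        y(i, j, c) = x(i / f, j / f, c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_nearest_bwd(const arma::cube& dy, int f) {
  cube dx(dy.n_rows / f, dy.n_cols / f, dy.n_slices, fill::zeros);
  for (unsigned c = 0; c < dy.n_slices; ++c)
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i)
        dx(i / f, j / f, c) += dy(i, j, c);
  return dx;
}

// Bilinear resize with the half-pixel-center convention:
// input coord = (out coord + 0.5) * in_size / out_size - 0.5, clamped.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(Ho, Wo, C);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int j = 0; j < Wo; ++j) {
    double xin = (j + 0.5) * sx - 0.5;
    if (xin < 0) xin = 0; if (xin > W - 1) xin = W - 1;
    const int x0 = (int)std::floor(xin), x1 = std::min(x0 + 1, W - 1);
    const double fx = xin - x0;
    for (int i = 0; i < Ho; ++i) {
      double yin = (i + 0.5) * sy - 0.5;
      if (yin < 0) yin = 0; if (yin > H - 1) yin = H - 1;
      const int y0 = (int)std::floor(yin), y1 = std::min(y0 + 1, H - 1);
      const double fy = yin - y0;
      for (int c = 0; c < C; ++c) {
        y(i, j, c) = (1 - fy) * ((1 - fx) * x(y0, x0, c) + fx * x(y0, x1, c)) +
                     fy       * ((1 - fx) * x(y1, x0, c) + fx * x(y1, x1, c));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_bwd(const arma::cube& dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int j = 0; j < Wo; ++j) {
    double xin = (j + 0.5) * sx - 0.5;
    if (xin < 0) xin = 0; if (xin > W - 1) xin = W - 1;
    const int x0 = (int)std::floor(xin), x1 = std::min(x0 + 1, W - 1);
    const double fx = xin - x0;
    for (int i = 0; i < Ho; ++i) {
      double yin = (i + 0.5) * sy - 0.5;
      if (yin < 0) yin = 0; if (yin > H - 1) yin = H - 1;
      const int y0 = (int)std::floor(yin), y1 = std::min(y0 + 1, H - 1);
      const double fy = yin - y0;
      for (int c = 0; c < C; ++c) {
        const double g = dy(i, j, c);
        dx(y0, x0, c) += (1 - fy) * (1 - fx) * g;
        dx(y0, x1, c) += (1 - fy) * fx * g;
        dx(y1, x0, c) += fy * (1 - fx) * g;
        dx(y1, x1, c) += fy * fx * g;
      }
    }
  }
  return dx;
}

// Affine resampling. For each output pixel (x_out = column, y_out = row),
// both 0-based pixel-center coordinates, the source location is
//   x_in = m[0]*x_out + m[1]*y_out + m[4]
//   y_in = m[2]*x_out + m[3]*y_out + m[5]
// m = c(a11, a12, a21, a22, tx, ty). nearest = TRUE uses nearest-neighbour
// sampling (for label masks); outside pixels get `fill`.
// [[Rcpp::export]]
arma::cube cpp_affine_sample(const arma::cube& x, const arma::vec& m,
                             int Ho, int Wo, bool nearest, double fill) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(Ho, Wo, C);
  y.fill(fill);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double xin = m(0) * j + m(1) * i + m(4);
      const double yin = m(2) * j + m(3) * i + m(5);
      if (nearest) {
        const int xr = (int)std::lround(xin), yr = (int)std::lround(yin);
        if (xr < 0 || xr >= W || yr < 0 || yr >= H) continue;
        for (int c = 0; c < C; ++c) y(i, j, c) = x(yr, xr, c);
      } else {
        if (xin < -1 || xin > W || yin < -1 || yin > H) continue;
        const int x0 = (int)std::floor(xin), y0 = (int)std::floor(yin);
        const double fxx = xin - x0, fyy = yin - y0;
        for (int c = 0; c < C; ++c) {
          double v = 0;
          for (int dy2 = 0; dy2 <= 1; ++dy2)
            for (int dx2 = 0; dx2 <= 1; ++dx2) {
              const int xi = x0 + dx2, yi = y0 + dy2;
              const double wgt = (dx2 ? fxx : 1 - fxx) * (dy2 ? fyy : 1 - fyy);
              const double px = (xi < 0 || xi >= W || yi < 0 || yi >= H)
                                  ? fill : x(yi, xi, c);
              v += wgt * px;
            }
          y(i, j, c) = v;
        }
      }
    }
  }
  return y;
}
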