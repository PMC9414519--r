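// Hot-path kernels for the 1-D convolutional encoder: strided valid
// convolution and max pooling over batched single-channel segments.
// Layout: activation cubes are (length, feature, sample); weight cubes are
// (kernel, in_feature, filter). All indices 0-based internally; pooling
// argmax indices are returned 0-based and consumed as such by the backward.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& x, const arma::cube& w,
                         const arma::vec& b, const int stride) {
  const int Lin = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int k = w.n_rows, U = w.n_slices;
  if ((int)w.n_cols != Cin) stop("conv1d: weight in-features do not match input");
  if (Lin < k) stop("conv1d: input shorter than kernel");
  const int Lout = (Lin - k) / stride + 1;
  arma::cube y(Lout, U, N);
  arma::vec acc(Lout);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.memptr() + (std::size_t)n * Lin * Cin;
    for (int u = 0; u < U; ++u) {
      acc.fill(b[u]);
      double* ap = acc.memptr();
      for (int c = 0; c < Cin; ++c) {
        const double* xp = xs + (std::size_t)c * Lin;
        for (int kk = 0; kk < k; ++kk) {
          const double wv = w(kk, c, u);
          if (stride == 1) {
            for (int j = 0; j < Lout; ++j) ap[j] += wv * xp[j + kk];
          } else {
            for (int j = 0; j < Lout; ++j) ap[j] += wv * xp[j * stride + kk];
          }
        }
      }
      y.slice(n).col(u) = acc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1d_bw(const arma::cube& x, const arma::cube& w,
                   const arma::cube& gy, const int stride) {
  const int Lin = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int k = w.n_rows, U = w.n_slices;
  const int Lout = gy.n_rows;
  arma::cube gx(Lin, Cin, N, arma::fill::zeros);
  arma::cube gw(k, Cin, U, arma::fill::zeros);
  arma::vec gb(U, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.memptr() + (std::size_t)n * Lin * Cin;
    double* gxs = gx.memptr() + (std::size_t)n * Lin * Cin;
    for (int u = 0; u < U; ++u) {
      const double* gp = gy.memptr() + ((std::size_t)n * U + u) * Lout;
      double s = 0.0;
      for (int j = 0; j < Lout; ++j) s += gp[j];
      gb[u] += s;
      for (int c = 0; c < Cin; ++c) {
        const double* xp = xs + (std::size_t)c * Lin;
        double* gxp = gxs + (std::size_t)c * Lin;
        for (int kk = 0; kk < k; ++kk) {
          const double wv = w(kk, c, u);
          double accw = 0.0;
          if (stride == 1) {
            for (int j = 0; j < Lout; ++j) {
              accw += xp[j + kk] * gp[j];
              gxp[j + kk] += wv * gp[j];
            }
          } else {
            for (int j = 0; j < Lout; ++j) {
              accw += xp[j * stride + kk] * gp[j];
              gxp[j * stride + kk] += wv * gp[j];
            }
          }
          gw(kk, c, u) += accw;
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List cpp_maxpool1d_fw(const arma::cube& x, const int width, const int stride) {
  const int Lin = x.n_rows, C = x.n_cols, N = x.n_slices;
  if (Lin < width) stop("maxpool1d: input shorter than pooling window");
  const int Lout = (Lin - width) / stride + 1;
  arma::cube y(Lout, C, N);
  IntegerVector idx((R_xlen_t)Lout * C * N);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.memptr() + ((std::size_t)n * C + c) * Lin;
      double* yp = y.memptr() + ((std::size_t)n * C + c) * Lout;
      int* iq = ip + ((std::size_t)n * C + c) * Lout;
      for (int j = 0; j < Lout; ++j) {
        const int base = j * stride;
        double best = xp[base];
        int bi = base;
        for (int kk = 1; kk < width; ++kk) {
          if (xp[base + kk] > best) { best = xp[base + kk]; bi = base + kk; }
        }
        yp[j] = best;
        iq[j] = bi;
      }
    }
  }
  idx.attr("dim") = IntegerVector::create(Lout, C, N);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool1d_bw(const arma::cube& gy, const IntegerVector& idx,
                            const int Lin) {
  const int Lout = gy.n_rows, C = gy.n_cols, N = gy.n_slices;
  arma::cube gx(Lin, C, N, arma::fill::zeros);
  const int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.memptr() + ((std::size_t)n * C + c) * Lout;
      double* gxp = gx.memptr() + ((std::size_t)n * C + c) * Lin;
      const int* iq = ip + ((std::size_t)n * C + c) * Lout;
      for (int j = 0; j < Lout; ++j) gxp[iq[j]] += gp[j];
    }
  }
  return gx;
}
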