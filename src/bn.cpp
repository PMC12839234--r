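// Fused BatchNorm + ReLU forward/backward in double precision.
// Tensors are [H, W, N, C]; normalization is per channel over (H, W, N)
// with biased variance, running statistics updated with the unbiased one.

#include <Rcpp.h>

using namespace Rcpp;

// [[Rcpp::export]]
List bn_relu_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar,
                    bool training, double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  const R_xlen_t M = (R_xlen_t)d[0] * d[1] * d[2];
  const int C = d[3];
  NumericVector y(x.size()), xhat(x.size());
  NumericVector invstd(C), new_rmean(clone(rmean)), new_rvar(clone(rvar));
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double mu, v;
    if (training) {
      double s = 0;
      for (R_xlen_t i = 0; i < M; ++i) s += xc[i];
      mu = s / M;
      double ss = 0;
      for (R_xlen_t i = 0; i < M; ++i) { double t = xc[i] - mu; ss += t * t; }
      v = ss / M;
      new_rmean[c] = (1 - momentum) * rmean[c] + momentum * mu;
      double vu = (M > 1) ? v * M / (M - 1) : v;
      new_rvar[c] = (1 - momentum) * rvar[c] + momentum * vu;
    } else {
      mu = rmean[c];
      v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* yc = y.begin() + M * c;
    double* hc = xhat.begin() + M * c;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      const double o = g * h + b;
      yc[i] = o > 0 ? o : 0.0;
    }
  }
  y.attr("dim") = d;
  xhat.attr("dim") = d;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List bn_relu_bw_cpp(NumericVector dy, NumericVector y, NumericVector xhat,
                    NumericVector invstd, NumericVector gamma, bool training) {
  IntegerVector d = dy.attr("dim");
  const R_xlen_t M = (R_xlen_t)d[0] * d[1] * d[2];
  const int C = d[3];
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + M * c;
    const double* yc = y.begin() + M * c;
    const double* hc = xhat.begin() + M * c;
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double g_ = yc[i] > 0 ? dyc[i] : 0.0;
      s1 += g_;
      s2 += g_ * hc[i];
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double sc = gamma[c] * invstd[c];
    double* dxc = dx.begin() + M * c;
    if (training) {
      const double a1 = s1 / M, a2 = s2 / M;
      for (R_xlen_t i = 0; i < M; ++i) {
        const double g_ = yc[i] > 0 ? dyc[i] : 0.0;
        dxc[i] = sc * (g_ - a1 - hc[i] * a2);
      }
    } else {
      for (R_xlen_t i = 0; i < M; ++i)
        dxc[i] = sc * (yc[i] > 0 ? dyc[i] : 0.0);
    }
  }
  dx.attr("dim") = d;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
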