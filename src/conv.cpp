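// 2-D convolution primitives shared by the network layers, the PSF forward
// model and the loss filters.  Tensors are column-major 4-D arrays laid out
// as [H, W, N, C]; weights as [k, k, Cin, Cout].  The float32 path mirrors
// the single-precision arithmetic of the serialized network; the double path
// backs the loss/metric code where finite-difference gradient checks need
// full precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using Rcpp::NumericVector;
using Rcpp::IntegerVector;

namespace {

inline R_xlen_t idx4(int i, int j, int n, int c, int H, int W, int N) {
  return (R_xlen_t)i + (R_xlen_t)H * ((R_xlen_t)j + (R_xlen_t)W * ((R_xlen_t)n + (R_xlen_t)N * c));
}

template <typename eT>
void zero_pad(const eT* x, int H, int W, int N, int C, int pad, eT* xp) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::fill(xp, xp + (R_xlen_t)Hp * Wp * N * C, eT(0));
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < W; ++j) {
        const eT* src = x + idx4(0, j, n, c, H, W, N);
        eT* dst = xp + idx4(pad, j + pad, n, c, Hp, Wp, N);
        std::copy(src, src + H, dst);
      }
}

// gather the (ki,kj) offset plane of the padded input into an Np x Cin matrix
template <typename eT>
void gather_offset(const eT* xp, int Hp, int Wp, int N, int Cin,
                   int ki, int kj, int stride, int Hout, int Wout, eT* xs) {
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  for (int c = 0; c < Cin; ++c)
    for (int n = 0; n < N; ++n)
      for (int jo = 0; jo < Wout; ++jo) {
        const eT* src = xp + idx4(ki, kj + jo * stride, n, c, Hp, Wp, N);
        eT* dst = xs + (R_xlen_t)Hout * (jo + (R_xlen_t)Wout * n) + Np * c;
        if (stride == 1) {
          std::copy(src, src + Hout, dst);
        } else {
          for (int io = 0; io < Hout; ++io) dst[io] = src[(R_xlen_t)io * stride];
        }
      }
}

// scatter-add the offset plane back (adjoint of gather_offset)
template <typename eT>
void scatter_offset(const eT* ts, int Hp, int Wp, int N, int Cin,
                    int ki, int kj, int stride, int Hout, int Wout, eT* xp) {
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  for (int c = 0; c < Cin; ++c)
    for (int n = 0; n < N; ++n)
      for (int jo = 0; jo < Wout; ++jo) {
        const eT* src = ts + (R_xlen_t)Hout * (jo + (R_xlen_t)Wout * n) + Np * c;
        eT* dst = xp + idx4(ki, kj + jo * stride, n, c, Hp, Wp, N);
        if (stride == 1) {
          for (int io = 0; io < Hout; ++io) dst[io] += src[io];
        } else {
          for (int io = 0; io < Hout; ++io) dst[(R_xlen_t)io * stride] += src[io];
        }
      }
}

template <typename eT>
void conv_fw_core(const eT* x, int H, int W, int N, int Cin,
                  const eT* w, int k, int Cout, const eT* bias,
                  int stride, int pad, eT* y, int Hout, int Wout) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  std::vector<eT> xp((R_xlen_t)Hp * Wp * N * Cin);
  zero_pad(x, H, W, N, Cin, pad, xp.data());
  std::vector<eT> xs(Np * Cin), wk((R_xlen_t)Cin * Cout);
  arma::Mat<eT> Y(y, Np, Cout, false, true);
  if (bias) {
    for (int co = 0; co < Cout; ++co)
      std::fill(y + Np * co, y + Np * (co + 1), bias[co]);
  } else {
    Y.zeros();
  }
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      gather_offset(xp.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, xs.data());
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          wk[(R_xlen_t)ci + (R_xlen_t)Cin * co] =
            w[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))];
      arma::Mat<eT> Xs(xs.data(), Np, Cin, false, true);
      arma::Mat<eT> Wk(wk.data(), Cin, Cout, false, true);
      Y += Xs * Wk;
    }
}

template <typename eT>
void conv_bw_input_core(const eT* dy, int Hout, int Wout, int N, int Cout,
                        const eT* w, int k, int Cin,
                        int stride, int pad, int Hin, int Win, eT* dx) {
  const int Hp = Hin + 2 * pad, Wp = Win + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  std::vector<eT> xp((R_xlen_t)Hp * Wp * N * Cin, eT(0));
  std::vector<eT> ts(Np * Cin), wk((R_xlen_t)Cin * Cout);
  arma::Mat<eT> DY(const_cast<eT*>(dy), Np, Cout, false, true);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          wk[(R_xlen_t)ci + (R_xlen_t)Cin * co] =
            w[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))];
      arma::Mat<eT> Wk(wk.data(), Cin, Cout, false, true);
      arma::Mat<eT> Ts(ts.data(), Np, Cin, false, true);
      Ts = DY * Wk.t();
      scatter_offset(ts.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, xp.data());
    }
  // crop the padding
  for (int c = 0; c < Cin; ++c)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < Win; ++j) {
        const eT* src = xp.data() + idx4(pad, j + pad, n, c, Hp, Wp, N);
        eT* dst = dx + idx4(0, j, n, c, Hin, Win, N);
        std::copy(src, src + Hin, dst);
      }
}

template <typename eT>
void conv_bw_weight_core(const eT* x, int H, int W, int N, int Cin,
                         const eT* dy, int Hout, int Wout, int Cout,
                         int k, int stride, int pad, eT* dw) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  std::vector<eT> xp((R_xlen_t)Hp * Wp * N * Cin);
  zero_pad(x, H, W, N, Cin, pad, xp.data());
  std::vector<eT> xs(Np * Cin), dwk((R_xlen_t)Cin * Cout);
  arma::Mat<eT> DY(const_cast<eT*>(dy), Np, Cout, false, true);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      gather_offset(xp.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, xs.data());
      arma::Mat<eT> Xs(xs.data(), Np, Cin, false, true);
      arma::Mat<eT> DWk(dwk.data(), Cin, Cout, false, true);
      DWk = Xs.t() * DY;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dw[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))] =
            dwk[(R_xlen_t)ci + (R_xlen_t)Cin * co];
    }
}

// fused backward of a conv layer: weight gradient, bias gradient and
// (optionally) input gradient in one pass, sharing the padded input,
// the gathered offset planes and the converted dy
template <typename eT>
void conv_bw_core(const eT* x, int H, int W, int N, int Cin,
                  const eT* dy, int Hout, int Wout, int Cout,
                  const eT* w, int k, int stride, int pad,
                  bool need_dx, eT* dw, eT* db, eT* dx) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  std::vector<eT> xp((R_xlen_t)Hp * Wp * N * Cin);
  zero_pad(x, H, W, N, Cin, pad, xp.data());
  std::vector<eT> xs(Np * Cin), buf((R_xlen_t)Cin * Cout);
  std::vector<eT> gp;
  if (need_dx) gp.assign((R_xlen_t)Hp * Wp * N * Cin, eT(0));
  arma::Mat<eT> DY(const_cast<eT*>(dy), Np, Cout, false, true);
  for (int co = 0; co < Cout; ++co) {
    eT s = 0;
    const eT* p = dy + Np * co;
    for (R_xlen_t i = 0; i < Np; ++i) s += p[i];
    db[co] = s;
  }
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      gather_offset(xp.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, xs.data());
      arma::Mat<eT> Xs(xs.data(), Np, Cin, false, true);
      arma::Mat<eT> DWk(buf.data(), Cin, Cout, false, true);
      DWk = Xs.t() * DY;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dw[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))] =
            buf[(R_xlen_t)ci + (R_xlen_t)Cin * co];
      if (need_dx) {
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            buf[(R_xlen_t)ci + (R_xlen_t)Cin * co] =
              w[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))];
        arma::Mat<eT> Wk(buf.data(), Cin, Cout, false, true);
        arma::Mat<eT> Ts(xs.data(), Np, Cin, false, true);  // reuse xs buffer
        Ts = DY * Wk.t();
        scatter_offset(xs.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, gp.data());
      }
    }
  if (need_dx) {
    for (int c = 0; c < Cin; ++c)
      for (int n = 0; n < N; ++n)
        for (int j = 0; j < W; ++j) {
          const eT* src = gp.data() + idx4(pad, j + pad, n, c, Hp, Wp, N);
          eT* dst = dx + idx4(0, j, n, c, H, W, N);
          std::copy(src, src + H, dst);
        }
  }
}

// fused forward + weight-gradient used by the transposed-conv backward:
// y = conv(a, w) and dw[.,.,ci,co] accumulating gather(a)^T * b,
// sharing the padded/gathered a planes
template <typename eT>
void conv_fw_wgrad_core(const eT* a, int H, int W, int N, int Cin,
                        const eT* w, int k, int Cout,
                        const eT* b, int stride, int pad,
                        eT* y, int Hout, int Wout, eT* dw) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Hout * Wout * N;
  std::vector<eT> xp((R_xlen_t)Hp * Wp * N * Cin);
  zero_pad(a, H, W, N, Cin, pad, xp.data());
  std::vector<eT> xs(Np * Cin), buf((R_xlen_t)Cin * Cout);
  arma::Mat<eT> Y(y, Np, Cout, false, true);
  Y.zeros();
  arma::Mat<eT> B(const_cast<eT*>(b), Np, Cout, false, true);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      gather_offset(xp.data(), Hp, Wp, N, Cin, ki, kj, stride, Hout, Wout, xs.data());
      arma::Mat<eT> Xs(xs.data(), Np, Cin, false, true);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          buf[(R_xlen_t)ci + (R_xlen_t)Cin * co] =
            w[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))];
      arma::Mat<eT> Wk(buf.data(), Cin, Cout, false, true);
      Y += Xs * Wk;
      arma::Mat<eT> DWk(buf.data(), Cin, Cout, false, true);
      DWk = Xs.t() * B;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dw[ki + k * ((R_xlen_t)kj + k * ((R_xlen_t)ci + (R_xlen_t)Cin * co))] =
            buf[(R_xlen_t)ci + (R_xlen_t)Cin * co];
    }
}

template <typename eT>
std::vector<eT> to_eT(const NumericVector& v) {
  std::vector<eT> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (eT)v[i];
  return out;
}

NumericVector with_dim(std::vector<double>&& v, int a, int b, int c, int d) {
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = IntegerVector::create(a, b, c, d);
  return out;
}

NumericVector with_dim(const std::vector<float>& v, int a, int b, int c, int d) {
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i) out[i] = (double)v[i];
  out.attr("dim") = IntegerVector::create(a, b, c, d);
  return out;
}

IntegerVector dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-D [H, W, N, C] array");
  return d;
}

} // namespace

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w,
                            Rcpp::Nullable<NumericVector> bias,
                            int stride, int pad, bool f32) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) Rcpp::stop("weight dims inconsistent with input");
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  if (Hout < 1 || Wout < 1) Rcpp::stop("kernel larger than padded input");
  if (f32) {
    std::vector<float> xf = to_eT<float>(x), wf = to_eT<float>(w), bf;
    const float* bp = nullptr;
    if (bias.isNotNull()) { bf = to_eT<float>(bias.get()); bp = bf.data(); }
    std::vector<float> y((R_xlen_t)Hout * Wout * N * Cout);
    conv_fw_core<float>(xf.data(), H, W, N, Cin, wf.data(), k, Cout, bp, stride, pad,
                        y.data(), Hout, Wout);
    return with_dim(y, Hout, Wout, N, Cout);
  }
  const double* bp = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = bv.begin(); }
  std::vector<double> y((R_xlen_t)Hout * Wout * N * Cout);
  conv_fw_core<double>(x.begin(), H, W, N, Cin, w.begin(), k, Cout, bp, stride, pad,
                       y.data(), Hout, Wout);
  return with_dim(std::move(y), Hout, Wout, N, Cout);
}

// [[Rcpp::export]]
NumericVector conv2d_bw_input_cpp(NumericVector dy, NumericVector w,
                                  int stride, int pad, int Hin, int Win, bool f32) {
  IntegerVector dd = dims_of(dy), dw = dims_of(w);
  const int Hout = dd[0], Wout = dd[1], N = dd[2], Cout = dd[3];
  const int k = dw[0], Cin = dw[2];
  if (dw[3] != Cout) Rcpp::stop("weight dims inconsistent with gradient");
  if ((Hin + 2 * pad - k) / stride + 1 != Hout || (Win + 2 * pad - k) / stride + 1 != Wout)
    Rcpp::stop("target input size inconsistent with gradient size");
  if (f32) {
    std::vector<float> df = to_eT<float>(dy), wf = to_eT<float>(w);
    std::vector<float> dxv((R_xlen_t)Hin * Win * N * Cin);
    conv_bw_input_core<float>(df.data(), Hout, Wout, N, Cout, wf.data(), k, Cin,
                              stride, pad, Hin, Win, dxv.data());
    return with_dim(dxv, Hin, Win, N, Cin);
  }
  std::vector<double> dxv((R_xlen_t)Hin * Win * N * Cin);
  conv_bw_input_core<double>(dy.begin(), Hout, Wout, N, Cout, w.begin(), k, Cin,
                             stride, pad, Hin, Win, dxv.data());
  return with_dim(std::move(dxv), Hin, Win, N, Cin);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw_cpp(NumericVector x, NumericVector dy, NumericVector w,
                         int stride, int pad, bool need_dx, bool f32) {
  IntegerVector dxd = dims_of(x), dd = dims_of(dy), dw_ = dims_of(w);
  const int H = dxd[0], W = dxd[1], N = dxd[2], Cin = dxd[3];
  const int Hout = dd[0], Wout = dd[1], Cout = dd[3];
  const int k = dw_[0];
  if (dd[2] != N) Rcpp::stop("batch dims differ");
  Rcpp::List out;
  if (f32) {
    std::vector<float> xf = to_eT<float>(x), df = to_eT<float>(dy),
                       wf = to_eT<float>(w);
    std::vector<float> dwv((R_xlen_t)k * k * Cin * Cout), dbv(Cout);
    std::vector<float> dxv(need_dx ? (R_xlen_t)H * W * N * Cin : 0);
    conv_bw_core<float>(xf.data(), H, W, N, Cin, df.data(), Hout, Wout, Cout,
                        wf.data(), k, stride, pad, need_dx,
                        dwv.data(), dbv.data(), dxv.data());
    out = Rcpp::List::create(
      Rcpp::_["dw"] = with_dim(dwv, k, k, Cin, Cout),
      Rcpp::_["db"] = NumericVector(dbv.begin(), dbv.end()),
      Rcpp::_["dx"] = need_dx ? with_dim(dxv, H, W, N, Cin) : NumericVector(0));
  } else {
    std::vector<double> dwv((R_xlen_t)k * k * Cin * Cout), dbv(Cout);
    std::vector<double> dxv(need_dx ? (R_xlen_t)H * W * N * Cin : 0);
    conv_bw_core<double>(x.begin(), H, W, N, Cin, dy.begin(), Hout, Wout, Cout,
                         w.begin(), k, stride, pad, need_dx,
                         dwv.data(), dbv.data(), dxv.data());
    out = Rcpp::List::create(
      Rcpp::_["dw"] = with_dim(std::move(dwv), k, k, Cin, Cout),
      Rcpp::_["db"] = NumericVector(dbv.begin(), dbv.end()),
      Rcpp::_["dx"] = need_dx ? with_dim(std::move(dxv), H, W, N, Cin)
                              : NumericVector(0));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_fw_wgrad_cpp(NumericVector a, NumericVector w,
                               NumericVector b, int stride, int pad, bool f32) {
  IntegerVector da = dims_of(a), dw_ = dims_of(w), db_ = dims_of(b);
  const int H = da[0], W = da[1], N = da[2], Cin = da[3];
  const int k = dw_[0], Cout = dw_[3];
  if (dw_[2] != Cin) Rcpp::stop("weight dims inconsistent with input");
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  if (db_[0] != Hout || db_[1] != Wout || db_[2] != N || db_[3] != Cout)
    Rcpp::stop("companion tensor dims inconsistent");
  if (f32) {
    std::vector<float> af = to_eT<float>(a), wf = to_eT<float>(w),
                       bf = to_eT<float>(b);
    std::vector<float> y((R_xlen_t)Hout * Wout * N * Cout);
    std::vector<float> dwv((R_xlen_t)k * k * Cin * Cout);
    conv_fw_wgrad_core<float>(af.data(), H, W, N, Cin, wf.data(), k, Cout,
                              bf.data(), stride, pad, y.data(), Hout, Wout,
                              dwv.data());
    return Rcpp::List::create(Rcpp::_["y"] = with_dim(y, Hout, Wout, N, Cout),
                              Rcpp::_["dw"] = with_dim(dwv, k, k, Cin, Cout));
  }
  std::vector<double> y((R_xlen_t)Hout * Wout * N * Cout);
  std::vector<double> dwv((R_xlen_t)k * k * Cin * Cout);
  conv_fw_wgrad_core<double>(a.begin(), H, W, N, Cin, w.begin(), k, Cout,
                             b.begin(), stride, pad, y.data(), Hout, Wout,
                             dwv.data());
  return Rcpp::List::create(
    Rcpp::_["y"] = with_dim(std::move(y), Hout, Wout, N, Cout),
    Rcpp::_["dw"] = with_dim(std::move(dwv), k, k, Cin, Cout));
}

// [[Rcpp::export]]
NumericVector conv2d_bw_weight_cpp(NumericVector x, NumericVector dy,
                                   int k, int stride, int pad, bool f32) {
  IntegerVector dx = dims_of(x), dd = dims_of(dy);
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int Hout = dd[0], Wout = dd[1], Cout = dd[3];
  if (dd[2] != N) Rcpp::stop("batch dims differ");
  if (f32) {
    std::vector<float> xf = to_eT<float>(x), df = to_eT<float>(dy);
    std::vector<float> dwv((R_xlen_t)k * k * Cin * Cout);
    conv_bw_weight_core<float>(xf.data(), H, W, N, Cin, df.data(), Hout, Wout, Cout,
                               k, stride, pad, dwv.data());
    return with_dim(dwv, k, k, Cin, Cout);
  }
  std::vector<double> dwv((R_xlen_t)k * k * Cin * Cout);
  conv_bw_weight_core<double>(x.begin(), H, W, N, Cin, dy.begin(), Hout, Wout, Cout,
                              k, stride, pad, dwv.data());
  return with_dim(std::move(dwv), k, k, Cin, Cout);
}
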