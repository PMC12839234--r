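# Internal neural-network primitives on [H, W, N, C] tensors.
# Convolution gathers/scatters and GEMM live in src/conv.cpp; everything
# here is cheap elementwise or per-channel arithmetic kept in R.

# network arithmetic runs in float32 (the storage precision); the option
# exists so gradient-verification code can switch to double
f32_default <- function() isTRUE(getOption("bdnet.float32", TRUE))

nn_conv_fw <- function(x, w, b, stride, pad, f32 = f32_default())
  conv2d_fw_cpp(x, w, b, as.integer(stride), as.integer(pad), f32)

nn_conv_bw_input <- function(dy, w, stride, pad, Hin, Win, f32 = f32_default())
  conv2d_bw_input_cpp(dy, w, as.integer(stride), as.integer(pad),
                      as.integer(Hin), as.integer(Win), f32)

nn_conv_bw_weight <- function(x, dy, k, stride, pad, f32 = f32_default())
  conv2d_bw_weight_cpp(x, dy, as.integer(k), as.integer(stride),
                       as.integer(pad), f32)

nn_conv_bw_bias <- function(dy) {
  d <- dim(dy)
  .colSums(dy, d[1] * d[2] * d[3], d[4])
}

# transposed conv, stride 2, pad 1, output_padding 1: the adjoint of a
# stride-2 conv whose weight maps Cout -> Cin; weight stored [k, k, Cout, Cin]
nn_tconv_fw <- function(x, w, b, f32 = f32_default()) {
  d <- dim(x)
  y <- conv2d_bw_input_cpp(x, w, 2L, 1L, 2L * d[1], 2L * d[2], f32)
  if (!is.null(b)) {
    dy <- dim(y)
    y <- y + rep(b, each = dy[1] * dy[2] * dy[3])
  }
  y
}

nn_tconv_bw <- function(dout, x, w, f32 = f32_default()) {
  r <- conv2d_fw_wgrad_cpp(dout, w, x, 2L, 1L, f32)
  list(dx = r$y, dw = r$dw, db = nn_conv_bw_bias(dout))
}

# fused conv backward: dw, db and (optionally) dx in one C++ pass
nn_conv_bw <- function(x, dy, w, stride, pad, need_dx = TRUE,
                       f32 = f32_default()) {
  conv2d_bw_cpp(x, dy, w, as.integer(stride), as.integer(pad), need_dx, f32)
}

relu_fw <- function(x) {
  x[x < 0] <- 0
  x
}

# Fused BatchNorm + ReLU (C++): biased variance in the normalization,
# exponential running statistics for inference (momentum on the new batch).
# Returns y (post-ReLU) plus the cache needed for the backward pass.
bn_relu_fw <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  out <- bn_relu_fw_cpp(x, gamma, beta, rmean, rvar, training, momentum, eps)
  out$training <- training
  out
}

bn_relu_bw <- function(dy, y, cache, gamma)
  bn_relu_bw_cpp(dy, y, cache$xhat, cache$invstd, gamma, cache$training)
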