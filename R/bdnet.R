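#' Architecture specification for the denoising network
#'
#' Describes the encoder-bottleneck-decoder denoiser: four encoder conv
#' blocks (3x3, BatchNorm, ReLU; strides 2,2,1,1; channels 1 -> 32 -> 64 ->
#' 128 -> 256), a convolutional block attention module (CBAM) on the
#' 256-channel bottleneck (channel attention with a shared MLP at reduction
#' `cbam_reduction`, then spatial attention with a `cbam_spatial_kernel`
#' conv), a 3x3 conv back to 128 channels, two stride-2 transposed convs
#' (128 -> 64 -> 32) restoring full resolution, and a final conv to one
#' channel. Three learnable skip connections feed encoder/raw-input detail
#' forward: three sequential 3x3 single-channel convs from the input to the
#' output head, a 1x1 conv (32 -> 64) from the first encoder block to the
#' first upsampling stage, and a 1x1 conv (64 -> 128) from the second
#' encoder block to the 128-channel decoder conv. Outputs are clamped to
#' \[0, 1\].
#'
#' @param encoder_channels Four encoder output widths.
#' @param encoder_strides Four encoder strides (product must be 4: two
#'   stride-2 stages).
#' @param encoder_kernel Encoder conv kernel size.
#' @param cbam_reduction Channel-attention MLP reduction ratio `r`; must
#'   divide the bottleneck width.
#' @param cbam_spatial_kernel Spatial-attention conv kernel size (odd).
#' @param decoder_channels Three decoder widths (conv, tconv1, tconv2).
#' @param output_channels Output channels (1: grayscale).
#' @param final_kernel Kernel of the final conv (3 by default; 1 available).
#' @param attention One of "full", "channel", "spatial", "none" — the CBAM
#'   ablation variants.
#' @return An object of class `bdnet_spec`.
#' @export
network_spec <- function(encoder_channels = c(32L, 64L, 128L, 256L),
                         encoder_strides = c(2L, 2L, 1L, 1L),
                         encoder_kernel = 3L,
                         cbam_reduction = 16L,
                         cbam_spatial_kernel = 7L,
                         decoder_channels = c(128L, 64L, 32L),
                         output_channels = 1L,
                         final_kernel = 3L,
                         attention = c("full", "channel", "spatial", "none")) {
  attention <- match.arg(attention)
  if (length(encoder_channels) != 4L || any(encoder_channels <= 0))
    stop_invalid("encoder_channels must be four positive widths")
  if (length(encoder_strides) != 4L || prod(encoder_strides) != 4L)
    stop_invalid("encoder strides must multiply to a downsampling factor of 4")
  if (length(decoder_channels) != 3L || any(decoder_channels <= 0))
    stop_invalid("decoder_channels must be three positive widths")
  C4 <- encoder_channels[4]
  if (C4 %% cbam_reduction != 0L)
    stop_invalid("cbam_reduction must divide the bottleneck width (",
                 C4, " / ", cbam_reduction, ")")
  if (cbam_spatial_kernel %% 2L == 0L)
    stop_invalid("cbam_spatial_kernel must be odd")
  if (!final_kernel %in% c(1L, 3L))
    stop_invalid("final_kernel must be 1 or 3")
  structure(list(
    encoder_channels = as.integer(encoder_channels),
    encoder_strides = as.integer(encoder_strides),
    encoder_kernel = as.integer(encoder_kernel),
    cbam_reduction = as.integer(cbam_reduction),
    cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
    decoder_channels = as.integer(decoder_channels),
    output_channels = as.integer(output_channels),
    final_kernel = as.integer(final_kernel),
    attention = attention
  ), class = "bdnet_spec")
}

# declaration-order layer table: name, kind, kernel, in, out
layer_table <- function(spec) {
  ec <- spec$encoder_channels; dc <- spec$decoder_channels
  k <- spec$encoder_kernel
  rows <- list(
    list("enc1", "conv_bn", k, 1L, ec[1]),
    list("enc2", "conv_bn", k, ec[1], ec[2]),
    list("enc3", "conv_bn", k, ec[2], ec[3]),
    list("enc4", "conv_bn", k, ec[3], ec[4])
  )
  if (spec$attention %in% c("full", "channel"))
    rows <- c(rows, list(list("ca", "channel_attn", NA, ec[4],
                              ec[4] %/% spec$cbam_reduction)))
  if (spec$attention %in% c("full", "spatial"))
    rows <- c(rows, list(list("sa", "spatial_attn", spec$cbam_spatial_kernel,
                              2L, 1L)))
  rows <- c(rows, list(
    list("conv5", "conv_bn", k, ec[4], dc[1]),
    list("tconv1", "tconv_bn", k, dc[1], dc[2]),
    list("tconv2", "tconv_bn", k, dc[2], dc[3]),
    list("conv6", "conv", spec$final_kernel, dc[3], spec$output_channels),
    list("skip1a", "conv", 3L, 1L, 1L),
    list("skip1b", "conv", 3L, 1L, 1L),
    list("skip1c", "conv", 3L, 1L, 1L),
    list("skip2", "conv", 1L, ec[1], dc[2]),
    list("skip3", "conv", 1L, ec[2], dc[1])
  ))
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], kind = r[[2]], kernel = r[[3]],
               cin = r[[4]], cout = r[[5]], stringsAsFactors = FALSE)))
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(1 / fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

#' Build the denoiser with seeded parameter initialization
#'
#' Convolution weights use Kaiming-uniform initialization scaled by fan-in,
#' biases a matching uniform range, BatchNorm scale/shift ones/zeros. Two
#' builds with the same seed are bit-identical.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `bdnet` holding parameters (`params`) and
#'   BatchNorm running statistics (`buffers`).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "bdnet_spec"))
  lt <- layer_table(spec)
  params <- list()
  buffers <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(lt))) {
      nm <- lt$name[i]; kind <- lt$kind[i]
      k <- lt$kernel[i]; cin <- lt$cin[i]; cout <- lt$cout[i]
      if (kind %in% c("conv", "conv_bn")) {
        fan_in <- k * k * cin
        params[[paste0(nm, ".w")]] <- kaiming_uniform(c(k, k, cin, cout), fan_in)
        params[[paste0(nm, ".b")]] <-
          runif(cout, -sqrt(1 / fan_in), sqrt(1 / fan_in))
      } else if (kind == "tconv_bn") {
        # weight stored [k, k, cout, cin]: the adjoint-conv layout
        fan_in <- k * k * cin
        params[[paste0(nm, ".w")]] <- kaiming_uniform(c(k, k, cout, cin), fan_in)
        params[[paste0(nm, ".b")]] <-
          runif(cout, -sqrt(1 / fan_in), sqrt(1 / fan_in))
      } else if (kind == "channel_attn") {
        C <- cin; Cr <- cout
        params[["ca.fc1"]] <- kaiming_uniform(c(C, Cr), C)
        params[["ca.fc2"]] <- kaiming_uniform(c(Cr, C), Cr)
      } else if (kind == "spatial_attn") {
        k <- lt$kernel[i]
        fan_in <- k * k * 2
        params[["sa.w"]] <- kaiming_uniform(c(k, k, 2L, 1L), fan_in)
        params[["sa.b"]] <- runif(1, -sqrt(1 / fan_in), sqrt(1 / fan_in))
      }
      if (kind %in% c("conv_bn", "tconv_bn")) {
        params[[paste0(nm, ".gamma")]] <- rep(1, cout)
        params[[paste0(nm, ".beta")]] <- rep(0, cout)
        buffers[[paste0(nm, ".rmean")]] <- rep(0, cout)
        buffers[[paste0(nm, ".rvar")]] <- rep(1, cout)
      }
    }
  })
  structure(list(spec = spec, params = params, buffers = buffers),
            class = "bdnet")
}

# ---- CBAM submodules (batched internals) ------------------------------------

cbam_channel_fw <- function(x, w1, w2) {
  d <- dim(x); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]; NC <- N * C
  xm <- x; dim(xm) <- c(HW, NC)
  avg <- .colMeans(xm, HW, NC)
  amax <- max.col(t(xm), ties.method = "first")
  mx <- xm[cbind(amax, seq_len(NC))]
  Ma <- matrix(avg, N, C); Mm <- matrix(mx, N, C)
  ha <- relu_fw(Ma %*% w1); hm <- relu_fw(Mm %*% w1)
  s <- sigmoid(ha %*% w2 + hm %*% w2)
  y <- x * rep(as.vector(s), each = HW)
  list(y = y, s = s, ha = ha, hm = hm, Ma = Ma, Mm = Mm, amax = amax)
}

cbam_channel_bw <- function(dy, x, cache, w1, w2) {
  d <- dim(x); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]; NC <- N * C
  prod_ <- dy * x; dim(prod_) <- c(HW, NC)
  ds <- matrix(.colSums(prod_, HW, NC), N, C)
  do <- ds * cache$s * (1 - cache$s)
  dha <- do %*% t(w2); dha[cache$ha <= 0] <- 0
  dhm <- do %*% t(w2); dhm[cache$hm <= 0] <- 0
  dw2 <- t(cache$ha) %*% do + t(cache$hm) %*% do
  dw1 <- t(cache$Ma) %*% dha + t(cache$Mm) %*% dhm
  dMa <- dha %*% t(w1); dMm <- dhm %*% t(w1)
  dx <- as.vector(dy * rep(as.vector(cache$s), each = HW)) +
    rep(as.vector(dMa) / HW, each = HW)
  sc <- (seq_len(NC) - 1L) * HW + cache$amax
  dx[sc] <- dx[sc] + as.vector(dMm)
  dim(dx) <- d
  list(dx = dx, dw1 = dw1, dw2 = dw2)
}

cbam_spatial_fw <- function(x, w, b, f32 = f32_default()) {
  d <- dim(x); HWN <- d[1] * d[2] * d[3]; C <- d[4]
  k <- dim(w)[1]
  xm <- x; dim(xm) <- c(HWN, C)
  mn <- .rowMeans(xm, HWN, C)
  amax <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(HWN), amax)]
  cat2 <- array(c(mn, mx), c(d[1], d[2], d[3], 2L))
  pre <- nn_conv_fw(cat2, w, b, 1L, (k - 1L) %/% 2L, f32)
  s <- sigmoid(pre)
  y <- x * rep(as.vector(s), times = C)
  list(y = y, s = s, cat2 = cat2, amax = amax)
}

cbam_spatial_bw <- function(dy, x, cache, w, f32 = f32_default()) {
  d <- dim(x); HWN <- d[1] * d[2] * d[3]; C <- d[4]
  k <- dim(w)[1]; pad <- (k - 1L) %/% 2L
  prod_ <- dy * x; dim(prod_) <- c(HWN, C)
  dsv <- .rowSums(prod_, HWN, C)
  sv <- as.vector(cache$s)
  dpre <- dsv * sv * (1 - sv)
  dim(dpre) <- c(d[1], d[2], d[3], 1L)
  dcat <- nn_conv_bw_input(dpre, w, 1L, pad, d[1], d[2], f32)
  dw <- nn_conv_bw_weight(cache$cat2, dpre, k, 1L, pad, f32)
  db <- sum(dpre)
  dmn <- as.vector(dcat[, , , 1L]); dmx <- as.vector(dcat[, , , 2L])
  dx <- as.vector(dy * rep(sv, times = C)) + rep(dmn / C, times = C)
  sc <- (cache$amax - 1L) * HWN + seq_len(HWN)
  dx[sc] <- dx[sc] + dmx
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

#' Channel attention weights for a feature map
#'
#' Global average and max pooling per channel feed a shared two-layer MLP
#' (C -> C/r -> C, ReLU between, no biases); the two MLP outputs are summed
#' and passed through a sigmoid, giving one weight in (0, 1) per channel.
#'
#' @param features 3-D array `[H, W, C]`.
#' @param r Reduction ratio; must divide C.
#' @param w1,w2 Optional MLP weights (`C x C/r` and `C/r x C`); seeded
#'   Kaiming-uniform draws when omitted.
#' @param seed Seed for the default weights.
#' @return Numeric vector of C per-channel weights in (0, 1).
#' @export
channel_attention <- function(features, r = 16L, w1 = NULL, w2 = NULL,
                              seed = 1L) {
  d <- dim(features)
  if (length(d) != 3L) stop_invalid("features must be a 3-D [H, W, C] array")
  C <- d[3]
  if (C %% r != 0L) stop_invalid("r must divide the channel count (", C, ")")
  if (is.null(w1) || is.null(w2)) {
    ws <- with_seed(seed, list(kaiming_uniform(c(C, C %/% r), C),
                               kaiming_uniform(c(C %/% r, C), C %/% r)))
    if (is.null(w1)) w1 <- ws[[1]]
    if (is.null(w2)) w2 <- ws[[2]]
  }
  x <- array(features, c(d[1], d[2], 1L, C))
  as.vector(cbam_channel_fw(x, w1, w2)$s)
}

#' Spatial attention map for a feature map
#'
#' The channel-wise mean and max maps are stacked (2 channels), convolved
#' with a `kernel x kernel` filter (padding `(kernel-1)/2`), and passed
#' through a sigmoid, giving one weight in (0, 1) per spatial location.
#'
#' @param features 3-D array `[H, W, C]`.
#' @param kernel Odd conv kernel size (7 by default).
#' @param w,b Optional conv weight `[kernel, kernel, 2, 1]` and bias;
#'   seeded draws when omitted.
#' @param seed Seed for the default weights.
#' @return Numeric `H x W` matrix of weights in (0, 1).
#' @export
spatial_attention <- function(features, kernel = 7L, w = NULL, b = NULL,
                              seed = 1L) {
  d <- dim(features)
  if (length(d) != 3L) stop_invalid("features must be a 3-D [H, W, C] array")
  if (kernel %% 2L == 0L) stop_invalid("kernel must be odd")
  if (is.null(w) || is.null(b)) {
    ws <- with_seed(seed, list(
      kaiming_uniform(c(kernel, kernel, 2L, 1L), 2 * kernel^2),
      runif(1, -sqrt(1 / (2 * kernel^2)), sqrt(1 / (2 * kernel^2)))))
    if (is.null(w)) w <- ws[[1]]
    if (is.null(b)) b <- ws[[2]]
  }
  x <- array(features, c(d[1], d[2], 1L, d[3]))
  matrix(cbam_spatial_fw(x, w, b, f32 = FALSE)$s, d[1], d[2])
}

# ---- full network forward / backward ----------------------------------------

# x: [H, W, N, 1]; returns y plus (optionally) the activation cache and the
# network with updated BatchNorm running statistics
net_forward <- function(net, x, training = FALSE, cache = FALSE) {
  p <- net$params; bufs <- net$buffers; spec <- net$spec
  st <- spec$encoder_strides; k <- spec$encoder_kernel
  pad <- (k - 1L) %/% 2L
  cc <- if (cache) list(x = x) else NULL

  conv_bn_relu <- function(inp, nm, stride) {
    c_ <- nn_conv_fw(inp, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                     stride, pad)
    bn <- bn_relu_fw(c_, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                     bufs[[paste0(nm, ".rmean")]], bufs[[paste0(nm, ".rvar")]],
                     training)
    bufs[[paste0(nm, ".rmean")]] <<- bn$rmean
    bufs[[paste0(nm, ".rvar")]] <<- bn$rvar
    a <- bn$y
    if (cache) {
      cc[[paste0(nm, ".bn")]] <<- bn[c("xhat", "invstd", "training")]
      cc[[paste0(nm, ".a")]] <<- a
    }
    a
  }

  a1 <- conv_bn_relu(x, "enc1", st[1])
  a2 <- conv_bn_relu(a1, "enc2", st[2])
  a3 <- conv_bn_relu(a2, "enc3", st[3])
  a4 <- conv_bn_relu(a3, "enc4", st[4])

  bot <- a4
  if (spec$attention %in% c("full", "channel")) {
    ca <- cbam_channel_fw(bot, p$ca.fc1, p$ca.fc2)
    if (cache) { cc$ca_in <- bot; cc$ca <- ca[-1L] }
    bot <- ca$y
  }
  if (spec$attention %in% c("full", "spatial")) {
    sa <- cbam_spatial_fw(bot, p$sa.w, p$sa.b)
    if (cache) { cc$sa_in <- bot; cc$sa <- sa[-1L] }
    bot <- sa$y
  }

  if (cache) cc$conv5_in <- bot
  a5 <- conv_bn_relu(bot, "conv5", 1L)
  sk3 <- nn_conv_fw(a2, p$skip3.w, p$skip3.b, 1L, 0L)
  d5 <- a5 + sk3

  tconv_bn_relu <- function(inp, nm) {
    t_ <- nn_tconv_fw(inp, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]])
    bn <- bn_relu_fw(t_, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                     bufs[[paste0(nm, ".rmean")]], bufs[[paste0(nm, ".rvar")]],
                     training)
    bufs[[paste0(nm, ".rmean")]] <<- bn$rmean
    bufs[[paste0(nm, ".rvar")]] <<- bn$rvar
    a <- bn$y
    if (cache) {
      cc[[paste0(nm, ".bn")]] <<- bn[c("xhat", "invstd", "training")]
      cc[[paste0(nm, ".a")]] <<- a
    }
    a
  }

  a6 <- tconv_bn_relu(d5, "tconv1")
  sk2 <- nn_conv_fw(a1, p$skip2.w, p$skip2.b, 1L, 0L)
  d6 <- a6 + sk2
  a7 <- tconv_bn_relu(d6, "tconv2")

  fpad <- (spec$final_kernel - 1L) %/% 2L
  c6 <- nn_conv_fw(a7, p$conv6.w, p$conv6.b, 1L, fpad)
  s1a <- nn_conv_fw(x, p$skip1a.w, p$skip1a.b, 1L, 1L)
  s1b <- nn_conv_fw(s1a, p$skip1b.w, p$skip1b.b, 1L, 1L)
  s1c <- nn_conv_fw(s1b, p$skip1c.w, p$skip1c.b, 1L, 1L)
  pre <- c6 + s1c
  y <- clamp01(pre)
  if (cache) {
    cc$d5 <- d5; cc$d6 <- d6
    cc$s1a <- s1a; cc$s1b <- s1b
    cc$pre <- pre
  }
  net$buffers <- bufs
  list(y = y, cache = cc, net = net)
}

# gradient of a scalar loss wrt all parameters, given dL/dy
net_backward <- function(net, cc, dy) {
  p <- net$params; spec <- net$spec
  st <- spec$encoder_strides; k <- spec$encoder_kernel
  pad <- (k - 1L) %/% 2L
  g <- list()

  # clamp passes gradient only where the pre-clamp output is inside (0, 1)
  dpre <- dy * (cc$pre > 0 & cc$pre < 1)

  fpad <- (spec$final_kernel - 1L) %/% 2L
  a7 <- cc$tconv2.a
  r <- nn_conv_bw(a7, dpre, p$conv6.w, 1L, fpad)
  g$conv6.w <- r$dw; g$conv6.b <- r$db
  da7 <- r$dx
  # skip-1 chain (linear 3x3 convs on the raw input)
  r <- nn_conv_bw(cc$s1b, dpre, p$skip1c.w, 1L, 1L)
  g$skip1c.w <- r$dw; g$skip1c.b <- r$db
  r <- nn_conv_bw(cc$s1a, r$dx, p$skip1b.w, 1L, 1L)
  g$skip1b.w <- r$dw; g$skip1b.b <- r$db
  r <- nn_conv_bw(cc$x, r$dx, p$skip1a.w, 1L, 1L, need_dx = FALSE)
  g$skip1a.w <- r$dw; g$skip1a.b <- r$db

  bnr_bw <- function(dout, nm) {
    bb <- bn_relu_bw(dout, cc[[paste0(nm, ".a")]], cc[[paste0(nm, ".bn")]],
                     p[[paste0(nm, ".gamma")]])
    g[[paste0(nm, ".gamma")]] <<- bb$dgamma
    g[[paste0(nm, ".beta")]] <<- bb$dbeta
    bb$dx
  }

  # tconv2
  dt2 <- bnr_bw(da7, "tconv2")
  tb <- nn_tconv_bw(dt2, cc$d6, p$tconv2.w)
  g$tconv2.w <- tb$dw; g$tconv2.b <- tb$db
  dd6 <- tb$dx
  # skip 2 from enc1 activation
  a1 <- cc$enc1.a
  r <- nn_conv_bw(a1, dd6, p$skip2.w, 1L, 0L)
  g$skip2.w <- r$dw; g$skip2.b <- r$db
  da1_sk <- r$dx
  # tconv1
  dt1 <- bnr_bw(dd6, "tconv1")
  tb <- nn_tconv_bw(dt1, cc$d5, p$tconv1.w)
  g$tconv1.w <- tb$dw; g$tconv1.b <- tb$db
  dd5 <- tb$dx
  # skip 3 from enc2 activation
  a2 <- cc$enc2.a
  r <- nn_conv_bw(a2, dd5, p$skip3.w, 1L, 0L)
  g$skip3.w <- r$dw; g$skip3.b <- r$db
  da2_sk <- r$dx
  # conv5
  dc5 <- bnr_bw(dd5, "conv5")
  conv5_in <- cc$conv5_in
  r <- nn_conv_bw(conv5_in, dc5, p$conv5.w, 1L, pad)
  g$conv5.w <- r$dw; g$conv5.b <- r$db
  dbot <- r$dx
  # CBAM backward (spatial first: it was applied last)
  if (!is.null(cc$sa)) {
    sb <- cbam_spatial_bw(dbot, cc$sa_in, cc$sa, p$sa.w)
    g$sa.w <- sb$dw; g$sa.b <- sb$db
    dbot <- sb$dx
  }
  if (!is.null(cc$ca)) {
    cb <- cbam_channel_bw(dbot, cc$ca_in, cc$ca, p$ca.fc1, p$ca.fc2)
    g$ca.fc1 <- cb$dw1; g$ca.fc2 <- cb$dw2
    dbot <- cb$dx
  }
  da4 <- dbot

  conv_bw <- function(dout, nm, inp, stride, need_dx = TRUE) {
    dc <- bnr_bw(dout, nm)
    r <- nn_conv_bw(inp, dc, p[[paste0(nm, ".w")]], stride, pad, need_dx)
    g[[paste0(nm, ".w")]] <<- r$dw
    g[[paste0(nm, ".b")]] <<- r$db
    if (need_dx) r$dx else NULL
  }

  da3 <- conv_bw(da4, "enc4", cc$enc3.a, st[4])
  da2 <- conv_bw(da3, "enc3", cc$enc2.a, st[3])
  da1 <- conv_bw(da2 + da2_sk, "enc2", cc$enc1.a, st[2])
  conv_bw(da1 + da1_sk, "enc1", cc$x, st[1], need_dx = FALSE)
  g
}

#' Run the denoiser on a single image
#'
#' Inference-mode forward pass (BatchNorm uses its running statistics);
#' output has the same size as the input and is clamped to \[0, 1\]. Height
#' and width must be divisible by 4 (two stride-2 stages); use
#' [denoise_image()] for arbitrary sizes — it reflect-pads and crops.
#'
#' @param network A [build_network()] object.
#' @param noisy Numeric matrix in \[0, 1\], dimensions divisible by 4 and at
#'   least 8.
#' @return Denoised matrix of identical size.
#' @export
forward <- function(network, noisy) {
  stopifnot(inherits(network, "bdnet"))
  check_image(noisy, min_dim = 8L, arg = "noisy")
  if (nrow(noisy) %% 4L != 0L || ncol(noisy) %% 4L != 0L)
    stop_invalid("image dimensions must be divisible by 4 (got ",
                 nrow(noisy), "x", ncol(noisy),
                 "); denoise_image() pads arbitrary sizes")
  out <- net_forward(network, as_tensor(noisy), training = FALSE)
  as_matrix_image(out$y)
}

#' @export
predict.bdnet <- function(object, newdata, ...) forward(object, newdata)

#' Parameter and serialization accounting
#'
#' `count_parameters()` counts learnable entries (conv kernels and biases,
#' BatchNorm scale/shift, attention weights). `serialized_size_mb()` is the
#' float-32 serialized size in MB: (learnable entries + BatchNorm running
#' statistics) * 4 bytes / 1024^2, the usual state-dictionary convention.
#'
#' @param network A [build_network()] object.
#' @return An integer count, or a size in MB.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "bdnet"))
  sum(vapply(network$params, length, integer(1)))
}

#' @rdname count_parameters
#' @export
serialized_size_mb <- function(network) {
  stopifnot(inherits(network, "bdnet"))
  entries <- count_parameters(network) +
    sum(vapply(network$buffers, length, integer(1)))
  entries * 4 / 1024^2
}

#' Per-layer ledger of the network
#'
#' One row per layer with its kernel, channels and number of learnable
#' parameters (BatchNorm scale/shift counted with its conv; running
#' statistics listed separately in the `buffers` column).
#'
#' @param network A [build_network()] object.
#' @return A data.frame ledger; total rows sum to [count_parameters()].
#' @export
describe_network <- function(network) {
  stopifnot(inherits(network, "bdnet"))
  lt <- layer_table(network$spec)
  p <- network$params; b <- network$buffers
  lt$params <- vapply(seq_len(nrow(lt)), function(i) {
    nm <- lt$name[i]
    if (lt$kind[i] == "channel_attn")
      return(length(p$ca.fc1) + length(p$ca.fc2))
    if (lt$kind[i] == "spatial_attn")
      return(length(p$sa.w) + length(p$sa.b))
    n <- length(p[[paste0(nm, ".w")]]) + length(p[[paste0(nm, ".b")]])
    if (lt$kind[i] %in% c("conv_bn", "tconv_bn"))
      n <- n + length(p[[paste0(nm, ".gamma")]]) + length(p[[paste0(nm, ".beta")]])
    n
  }, numeric(1))
  lt$buffers <- vapply(seq_len(nrow(lt)), function(i) {
    nm <- lt$name[i]
    if (lt$kind[i] %in% c("conv_bn", "tconv_bn"))
      length(b[[paste0(nm, ".rmean")]]) + length(b[[paste0(nm, ".rvar")]])
    else 0
  }, numeric(1))
  lt
}

#' Intermediate feature-map shapes for a given input size
#'
#' Runs a real forward pass on a zero image and reports the dimensions of
#' every cached stage, the shape ledger of the architecture.
#'
#' @param network A [build_network()] object.
#' @param height,width Input size (divisible by 4).
#' @return data.frame with stage name, height, width, channels.
#' @export
network_shapes <- function(network, height = 512L, width = height) {
  x <- array(0, c(height, width, 1L, 1L))
  out <- net_forward(network, x, training = FALSE, cache = TRUE)
  cc <- out$cache
  stages <- c(enc1 = "enc1.a", enc2 = "enc2.a", enc3 = "enc3.a",
              enc4 = "enc4.a", cbam = "_cbam", conv5 = "conv5.a",
              tconv1 = "tconv1.a", tconv2 = "tconv2.a", output = "_out",
              skip1 = "s1a", skip2 = "_sk2", skip3 = "_sk3")
  dim_of <- function(key) {
    switch(key,
      "_cbam" = dim(cc$conv5_in),
      "_out" = dim(out$y),
      "_sk2" = c(dim(cc$tconv1.a)[1:3], dim(cc$tconv1.a)[4]),
      "_sk3" = c(dim(cc$conv5.a)[1:3], dim(cc$conv5.a)[4]),
      dim(cc[[key]]))
  }
  do.call(rbind, lapply(names(stages), function(nm) {
    d <- dim_of(stages[[nm]])
    data.frame(stage = nm, height = d[1], width = d[2], channels = d[4],
               stringsAsFactors = FALSE)
  }))
}

#' Save / load network weights as a float-32 file
#'
#' A single binary file: a JSON header (format version, the architecture
#' spec, tensor names and dimensions) followed by all parameter and buffer
#' values in declaration order as little-endian float-32.
#'
#' @param network A [build_network()] object.
#' @param path Output file.
#' @return `save_weights`: invisibly, the path. `load_weights`: a `bdnet`.
#' @export
save_weights <- function(network, path) {
  stopifnot(inherits(network, "bdnet"))
  tensors <- c(network$params, network$buffers)
  header <- jsonlite::toJSON(list(
    format = "bdnet-weights-1",
    spec = unclass(network$spec),
    n_params = length(network$params),
    names = names(tensors),
    dims = lapply(tensors, function(t) if (is.null(dim(t))) length(t) else dim(t))
  ), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (t in tensors)
    writeBin(as.numeric(t), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$format, "bdnet-weights-1"))
    stop_invalid("unrecognized weights file format")
  spec <- do.call(network_spec, header$spec)
  net <- build_network(spec, seed = 1L)
  tensors <- list()
  for (i in seq_along(header$names)) {
    d <- header$dims[[i]]
    v <- readBin(con, "numeric", prod(d), size = 4L, endian = "little")
    if (length(d) > 1L) dim(v) <- d
    tensors[[header$names[i]]] <- v
  }
  np <- header$n_params
  stopifnot(identical(names(tensors)[seq_len(np)], names(net$params)))
  net$params <- tensors[seq_len(np)]
  net$buffers <- tensors[-seq_len(np)]
  net
}

#' @export
print.bdnet <- function(x, ...) {
  cat("<bdnet denoiser>\n")
  cat("  attention variant:", x$spec$attention, "\n")
  cat("  learnable parameters:", count_parameters(x), "\n")
  cat(sprintf("  serialized float-32 size: %.4f MB\n", serialized_size_mb(x)))
  invisible(x)
}
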