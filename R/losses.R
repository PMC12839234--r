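#' Sobel derivative kernels
#'
#' The fixed 3x3 stencils estimating horizontal (`sx`) and vertical (`sy`)
#' intensity derivatives; `sy` is the transpose of `sx` and both sum to
#' zero, so constant images have zero response.
#'
#' @return A list with 3x3 matrices `sx` and `sy`.
#' @export
sobel_kernels <- function() {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(sx = sx, sy = t(sx))
}

# replicate (edge) padding of the first two dims of an [H, W, N, C] tensor
pad_replicate <- function(x, p = 1L) {
  d <- dim(x)
  ri <- c(rep(1L, p), seq_len(d[1]), rep(d[1], p))
  rj <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  x[ri, rj, , , drop = FALSE]
}

# adjoint of pad_replicate: padded row/column a folds onto clamp(a - p, 1, H);
# folding rows first and then columns handles the corners automatically
fold_replicate <- function(v, p = 1L) {
  d <- dim(v)
  H <- d[1] - 2L * p; W <- d[2] - 2L * p
  core <- v[(p + 1L):(p + H), , , , drop = FALSE]
  for (q in seq_len(p)) {
    core[1, , , ] <- core[1, , , ] + v[q, , , ]
    core[H, , , ] <- core[H, , , ] + v[d[1] - q + 1L, , , ]
  }
  out <- core[, (p + 1L):(p + W), , , drop = FALSE]
  for (q in seq_len(p)) {
    out[, 1, , ] <- out[, 1, , ] + core[, q, , ]
    out[, W, , ] <- out[, W, , ] + core[, d[2] - q + 1L, , ]
  }
  out
}

# batched Sobel correlation with replicate padding; x: [H, W, N, 1]
sobel_fw_batch <- function(x, f32 = FALSE) {
  ks <- sobel_kernels()
  xp <- pad_replicate(x, 1L)
  list(gx = nn_conv_fw(xp, array(ks$sx, c(3, 3, 1, 1)), NULL, 1L, 0L, f32),
       gy = nn_conv_fw(xp, array(ks$sy, c(3, 3, 1, 1)), NULL, 1L, 0L, f32))
}

# adjoint of the batched Sobel operator applied to a gradient map
sobel_adjoint_batch <- function(u, kernel, H, W, f32 = FALSE) {
  v <- nn_conv_bw_input(u, array(kernel, c(3, 3, 1, 1)), 1L, 0L,
                        H + 2L, W + 2L, f32)
  fold_replicate(v, 1L)
}

#' Sobel gradient maps of an image
#'
#' Correlates the image with the Sobel stencils under replicate (edge)
#' padding, returning maps of the input size. Replicate padding avoids
#' fabricating spurious gradients at the image border.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return A list with matrices `gx` (horizontal) and `gy` (vertical).
#' @export
sobel_gradients <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop_invalid("image must be a numeric matrix of at least 3x3")
  g <- sobel_fw_batch(as_tensor(image))
  list(gx = as_matrix_image(g$gx), gy = as_matrix_image(g$gy))
}

#' Gradient-consistency loss between two images
#'
#' Mean absolute difference of the horizontal Sobel maps plus the mean
#' absolute difference of the vertical Sobel maps (per-pixel mean
#' convention, so the loss weights keep their meaning at any image size).
#' Insensitive to global intensity offsets, which have zero gradient.
#'
#' @param pred,target Numeric matrices of identical size, at least 3x3.
#' @return Non-negative scalar.
#' @export
gradient_loss <- function(pred, target) {
  check_same_shape(pred, target)
  gp <- sobel_gradients(pred)
  gt <- sobel_gradients(target)
  mean(abs(gp$gx - gt$gx)) + mean(abs(gp$gy - gt$gy))
}

#' Mean absolute and mean squared error
#'
#' Per-pixel mean of `|pred - target|` (`l1_loss`) and of
#' `(pred - target)^2` (`l2_loss`).
#'
#' @param pred,target Numeric matrices or arrays of identical size.
#' @return Non-negative scalar.
#' @export
l1_loss <- function(pred, target) {
  check_same_shape(pred, target)
  mean(abs(pred - target))
}

#' @rdname l1_loss
#' @export
l2_loss <- function(pred, target) {
  check_same_shape(pred, target)
  mean((pred - target)^2)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# SSIM statistics maps via valid Gaussian filtering; x, y: [H, W, N, 1]
ssim_maps <- function(x, y, win, C1, C2, f32 = FALSE) {
  k <- nrow(win)
  w4 <- array(win, c(k, k, 1, 1))
  filt <- function(z) nn_conv_fw(z, w4, NULL, 1L, 0L, f32)
  ux <- filt(x); uy <- filt(y)
  uxx <- filt(x * x); uyy <- filt(y * y); uxy <- filt(x * y)
  sx2 <- uxx - ux * ux
  sy2 <- uyy - uy * uy
  sxy <- uxy - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * sxy + C2
  B1 <- ux * ux + uy * uy + C1; B2 <- sx2 + sy2 + C2
  list(map = (A1 * A2) / (B1 * B2), ux = ux, uy = uy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2)
}

#' Structural similarity index (single scale, Gaussian window)
#'
#' The standard windowed SSIM on \[0, 1\] data: an 11x11 Gaussian window
#' with sigma 1.5, stabilizers `C1 = (0.01 R)^2`, `C2 = (0.03 R)^2` with
#' data range `R = 1`, biased (population) window statistics, averaged over
#' all fully-supported (valid) window positions. These are the
#' MATLAB-default conventions.
#'
#' @param pred,target Numeric matrices of identical size, at least 11x11.
#' @param window_size Gaussian window width (odd).
#' @param sigma Gaussian window standard deviation.
#' @return Scalar in \[-1, 1\] (`ssim`); `ssim_loss` returns `1 - ssim`.
#' @export
ssim <- function(pred, target, window_size = 11L, sigma = 1.5) {
  check_same_shape(pred, target)
  if (nrow(pred) < window_size || ncol(pred) < window_size)
    stop_invalid("image (", nrow(pred), "x", ncol(pred),
                 ") smaller than the ", window_size, "x", window_size,
                 " SSIM window")
  win <- gaussian_window(window_size, sigma)
  m <- ssim_maps(as_tensor(pred), as_tensor(target), win,
                 C1 = 0.01^2, C2 = 0.03^2)
  mean(m$map)
}

#' @rdname ssim
#' @export
ssim_loss <- function(pred, target, window_size = 11L, sigma = 1.5)
  1 - ssim(pred, target, window_size, sigma)

# batched SSIM mean and its gradient wrt x (pred); x, y: [H, W, N, 1]
ssim_fw_bw <- function(x, y, win = gaussian_window(),
                       C1 = 0.01^2, C2 = 0.03^2, f32 = FALSE) {
  d <- dim(x)
  m <- ssim_maps(x, y, win, C1, C2, f32)
  S <- m$map
  nvalid <- length(S)
  # partials of S wrt the filtered statistics
  iBB <- 1 / (m$B1 * m$B2)
  dS_dux <- 2 * m$uy * m$A2 * iBB - 2 * m$ux * S / m$B1 +
    2 * m$ux * S / m$B2 - m$uy * 2 * m$A1 * iBB
  dS_duxx <- -S / m$B2
  dS_duxy <- 2 * m$A1 * iBB
  k <- nrow(win)
  w4 <- array(win, c(k, k, 1, 1))
  adj <- function(u) nn_conv_bw_input(u / nvalid, w4, 1L, 0L, d[1], d[2], f32)
  gx <- adj(dS_dux) + 2 * x * adj(dS_duxx) + y * adj(dS_duxy)
  list(value = mean(S), grad = gx)
}

#' Loss-term weights of the hybrid objective
#'
#' The training objective is
#' `lambda1 * L1 + lambda2 * L2 + lambda3 * (1 - SSIM) + lambdag * Lgrad`,
#' with defaults (1.0, 0.1, 0.2, 0.2). A term with weight 0 is skipped
#' entirely, which yields the standard ablation variants (see
#' [loss_preset()]).
#'
#' @param lambda1,lambda2,lambda3,lambdag Non-negative term weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1.0, lambda2 = 0.1, lambda3 = 0.2,
                         lambdag = 0.2) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         lambdag = lambdag)
  if (any(!is.finite(w)) || any(w < 0))
    stop_invalid("loss weights must be finite and non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Named ablation presets for the loss configuration
#'
#' @param name One of `"l1"`, `"l2"`, `"l1_ssim"`, `"l1_l2_ssim"`, `"giel"`
#'   (the full objective).
#' @return A [loss_weights()] object.
#' @export
loss_preset <- function(name = c("giel", "l1", "l2", "l1_ssim", "l1_l2_ssim")) {
  name <- match.arg(name)
  switch(name,
    l1 = loss_weights(1, 0, 0, 0),
    l2 = loss_weights(0, 1, 0, 0),
    l1_ssim = loss_weights(1, 0, 0.2, 0),
    l1_l2_ssim = loss_weights(1, 0.1, 0.2, 0),
    giel = loss_weights())
}

#' Total hybrid loss between a prediction and its reference
#'
#' @param pred,target Numeric matrices of identical size.
#' @param weights A [loss_weights()] object.
#' @return Non-negative scalar; 0 iff `pred == target` whenever
#'   `lambda1 > 0`.
#' @export
total_loss <- function(pred, target, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  check_same_shape(pred, target)
  total <- 0
  if (weights$lambda1 > 0) total <- total + weights$lambda1 * l1_loss(pred, target)
  if (weights$lambda2 > 0) total <- total + weights$lambda2 * l2_loss(pred, target)
  if (weights$lambda3 > 0) total <- total + weights$lambda3 * ssim_loss(pred, target)
  if (weights$lambdag > 0) total <- total + weights$lambdag * gradient_loss(pred, target)
  total
}

# batched total loss + gradient wrt pred for training; pred, target [H,W,N,1]
total_loss_bw <- function(pred, target, weights, f32 = f32_default()) {
  d <- dim(pred)
  n <- length(pred)
  diff <- pred - target
  loss <- 0
  grad <- array(0, d)
  if (weights$lambda1 > 0) {
    loss <- loss + weights$lambda1 * mean(abs(diff))
    grad <- grad + (weights$lambda1 / n) * sign(diff)
  }
  if (weights$lambda2 > 0) {
    loss <- loss + weights$lambda2 * mean(diff^2)
    grad <- grad + (weights$lambda2 * 2 / n) * diff
  }
  if (weights$lambda3 > 0) {
    s <- ssim_fw_bw(pred, target, f32 = f32)
    loss <- loss + weights$lambda3 * (1 - s$value)
    grad <- grad - weights$lambda3 * s$grad
  }
  if (weights$lambdag > 0) {
    ks <- sobel_kernels()
    gp <- sobel_fw_batch(pred, f32); gt <- sobel_fw_batch(target, f32)
    dx_ <- gp$gx - gt$gx; dy_ <- gp$gy - gt$gy
    loss <- loss + weights$lambdag * (mean(abs(dx_)) + mean(abs(dy_)))
    grad <- grad + weights$lambdag *
      (sobel_adjoint_batch(sign(dx_) / n, ks$sx, d[1], d[2], f32) +
       sobel_adjoint_batch(sign(dy_) / n, ks$sy, d[1], d[2], f32))
  }
  list(loss = loss, grad = grad)
}
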