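test_that("Sobel kernels have zero sum and transpose symmetry", {
  ks <- sobel_kernels()
  expect_equal(sum(ks$sx), 0)
  expect_equal(sum(ks$sy), 0)
  expect_identical(ks$sy, t(ks$sx))
})

test_that("Sobel gradients: constants, ramps and transposition", {
  g0 <- sobel_gradients(matrix(0.42, 9, 9))
  expect_lt(max(abs(g0$gx)), 1e-12)
  expect_lt(max(abs(g0$gy)), 1e-12)
  # horizontal ramp z[i, j] = j * c: interior gx = 8c, gy = 0
  c_ <- 0.01
  ramp <- matrix(rep(seq_len(12) * c_, each = 12), 12, 12)
  g <- sobel_gradients(ramp)
  expect_equal(g$gx[3:10, 3:10], matrix(8 * c_, 8, 8), tolerance = 1e-12)
  expect_equal(g$gy[3:10, 3:10], matrix(0, 8, 8), tolerance = 1e-12)
  # transposing the image swaps and transposes the two maps
  set.seed(4)
  z <- matrix(runif(25), 5, 5)
  g <- sobel_gradients(z)
  gt <- sobel_gradients(t(z))
  expect_equal(gt$gx, t(g$gy), tolerance = 1e-12)
  expect_equal(gt$gy, t(g$gx), tolerance = 1e-12)
  expect_error(sobel_gradients(matrix(1, 2, 5)), "3x3")
})

test_that("gradient loss is offset-invariant, symmetric and brute-force exact", {
  set.seed(8)
  a <- matrix(runif(16), 4, 4)
  expect_identical(gradient_loss(a, a), 0)
  expect_equal(gradient_loss(matrix(0.2, 8, 8), matrix(0.7, 8, 8)), 0)
  b <- matrix(runif(16), 4, 4)
  expect_equal(gradient_loss(a, b), gradient_loss(b, a))
  # independent brute-force oracle over all 16 pixels of a 4x4 pair
  ks <- sobel_kernels()
  brute_sobel <- function(z, k) {
    H <- nrow(z); W <- ncol(z)
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      acc <- 0
      for (u in -1:1) for (v in -1:1) {
        ii <- min(max(i + u, 1), H); jj <- min(max(j + v, 1), W)
        acc <- acc + k[u + 2, v + 2] * z[ii, jj]
      }
      out[i, j] <- acc
    }
    out
  }
  expected <- mean(abs(brute_sobel(a, ks$sx) - brute_sobel(b, ks$sx))) +
    mean(abs(brute_sobel(a, ks$sy) - brute_sobel(b, ks$sy)))
  expect_equal(gradient_loss(a, b), expected, tolerance = 1e-9)
})

test_that("L1 and L2 losses follow their closed forms", {
  a <- matrix(runif(64), 8, 8) * 0.5 + 0.2
  expect_identical(l1_loss(a, a), 0)
  expect_identical(l2_loss(a, a), 0)
  expect_equal(l1_loss(a, a + 0.1), 0.1, tolerance = 1e-12)
  expect_equal(l2_loss(a, a + 0.1), 0.01, tolerance = 1e-12)
  b <- pmin(pmax(a + matrix(rnorm(64, 0, 0.1), 8, 8), 0), 1)
  expect_lte(l2_loss(a, b), l1_loss(a, b))  # |diff| <= 1 pointwise
  expect_error(l1_loss(a, matrix(0, 4, 4)), "identical dimensions")
})

test_that("SSIM matches the independent reference implementation", {
  set.seed(42)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- pmin(pmax(a + matrix(rnorm(1024, 0, 0.05), 32, 32), 0), 1)
  # frozen from scikit-image structural_similarity (gaussian_weights=TRUE,
  # sigma=1.5, win_size=11, use_sample_covariance=FALSE, data_range=1)
  expect_equal(ssim(a, b), 0.9851845327, tolerance = 1e-6)
  set.seed(7)
  c1 <- matrix(runif(64 * 48), 64, 48)
  c2 <- pmin(pmax(c1 * 0.8 + 0.05 + matrix(rnorm(64 * 48, 0, 0.02), 64, 48),
                  0), 1)
  expect_equal(ssim(c1, c2), 0.9672310055, tolerance = 1e-6)
})

test_that("SSIM self-similarity, inversion and size guard", {
  img <- generate_phantom(32, 32, 3, 0.7, seed = 6)
  expect_equal(ssim(img, img), 1, tolerance = 1e-12)
  expect_identical(ssim_loss(img, img), 0)
  expect_lt(ssim(1 - img, img), 1)
  expect_error(ssim(matrix(0.5, 8, 8), matrix(0.5, 8, 8)), "window")
})

test_that("total loss composes the weighted terms and honours zero weights", {
  set.seed(10)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- pmin(pmax(a + matrix(rnorm(1024, 0, 0.08), 32, 32), 0), 1)
  w <- loss_weights()
  expect_identical(total_loss(a, a, w), 0)
  expect_equal(total_loss(a, b, loss_weights(1, 0, 0, 0)), l1_loss(a, b))
  expected <- w$lambda1 * l1_loss(a, b) + w$lambda2 * l2_loss(a, b) +
    w$lambda3 * (1 - ssim(a, b)) + w$lambdag * gradient_loss(a, b)
  expect_equal(total_loss(a, b, w), expected, tolerance = 1e-9)
  expect_error(loss_weights(-1, 0, 0, 0), "non-negative")
  # presets map to the ablation rows
  expect_equal(unlist(loss_preset("l1")), c(lambda1 = 1, lambda2 = 0,
                                            lambda3 = 0, lambdag = 0))
  expect_equal(unlist(loss_preset("giel")), unlist(loss_weights()))
})

test_that("every loss term admits a finite-difference-verified gradient", {
  withr::local_options(bdnet.float32 = FALSE)
  set.seed(14)
  tgt <- array(runif(16 * 16), c(16, 16, 1, 1))
  pred <- array(pmin(pmax(tgt + rnorm(256, 0, 0.1), 0.02), 0.98),
                c(16, 16, 1, 1))
  idx <- c(1, 17, 50, 128, 200, 256)
  for (nm in c("l1", "l2", "l1_ssim", "l1_l2_ssim", "giel")) {
    w <- loss_preset(nm)
    lb <- bdnet:::total_loss_bw(pred, tgt, w, f32 = FALSE)
    f <- function(x) bdnet:::total_loss_bw(array(x, dim(pred)), tgt, w,
                                           f32 = FALSE)$loss
    fd <- fd_grad(f, pred, idx)
    an <- as.vector(lb$grad)[idx]
    expect_lt(max(abs(fd - an) / pmax(abs(fd), abs(an), 1e-4)), 1e-3)
  }
})

test_that("the batched loss agrees with the per-image definitions", {
  set.seed(21)
  imgs <- lapply(1:3, function(i) matrix(runif(32 * 32), 32, 32))
  tgts <- lapply(1:3, function(i)
    pmin(pmax(imgs[[i]] + matrix(rnorm(1024, 0, 0.05), 32, 32), 0), 1))
  x <- bdnet:::stack_batch(imgs); y <- bdnet:::stack_batch(tgts)
  w <- loss_weights()
  batched <- bdnet:::total_loss_bw(x, y, w, f32 = FALSE)$loss
  per_image <- mean(mapply(total_loss, imgs, tgts, MoreArgs = list(weights = w)))
  expect_equal(batched, per_image, tolerance = 1e-9)
})
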