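test_that("network construction is seeded and spec-validated", {
  a <- build_network(network_spec(), seed = 11)
  b <- build_network(network_spec(), seed = 11)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_network(network_spec(), seed = 12)$params))
  expect_error(network_spec(encoder_strides = c(2, 2, 2, 1)), "factor of 4")
  expect_error(network_spec(cbam_reduction = 7L), "divide")
  expect_error(network_spec(cbam_spatial_kernel = 6L), "odd")
})

test_that("per-layer parameter ledger matches the closed-form count", {
  net <- build_network(network_spec(), seed = 1)
  led <- describe_network(net)
  # closed form: k^2*cin*cout + cout biases (+ 2*cout BatchNorm params)
  expected <- c(
    enc1 = 9 * 1 * 32 + 32 + 2 * 32,
    enc2 = 9 * 32 * 64 + 64 + 2 * 64,
    enc3 = 9 * 64 * 128 + 128 + 2 * 128,
    enc4 = 9 * 128 * 256 + 256 + 2 * 256,
    ca = 256 * 16 + 16 * 256,
    sa = 7 * 7 * 2 + 1,
    conv5 = 9 * 256 * 128 + 128 + 2 * 128,
    tconv1 = 9 * 128 * 64 + 64 + 2 * 64,
    tconv2 = 9 * 64 * 32 + 32 + 2 * 32,
    conv6 = 9 * 32 * 1 + 1,
    skip1a = 9 + 1, skip1b = 9 + 1, skip1c = 9 + 1,
    skip2 = 32 * 64 + 64,
    skip3 = 64 * 128 + 128)
  expect_equal(led$params[match(names(expected), led$name)],
               unname(expected))
  expect_equal(count_parameters(net), sum(expected))
  # running statistics: 2 entries (mean, var) per BatchNorm channel
  expect_equal(sum(led$buffers), 2 * (32 + 64 + 128 + 256 + 128 + 64 + 32))
})

test_that("forward pass preserves shape, range and determinism", {
  net <- build_network(tiny_spec(), seed = 2)
  img <- generate_phantom(64, 64, 4, 0.7, seed = 1)
  out <- forward(net, img)
  expect_equal(dim(out), c(64, 64))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, forward(net, img))
  # fully convolutional: other sizes divisible by 4 work, H != W included
  for (d in list(c(32, 32), c(48, 64), c(36, 52))) {
    x <- matrix(runif(d[1] * d[2]), d[1], d[2])
    y <- forward(net, x)
    expect_equal(dim(y), d)
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_error(forward(net, matrix(0.5, 30, 64)), "divisible by 4")
})

test_that("channel attention: range, zero input, and permutation equivariance", {
  set.seed(3)
  f <- array(runif(5 * 6 * 4), c(5, 6, 4))
  w1 <- matrix(rnorm(8), 4, 2); w2 <- matrix(rnorm(8), 2, 4)
  s <- channel_attention(f, r = 2, w1 = w1, w2 = w2)
  expect_length(s, 4)
  expect_true(all(s > 0 & s < 1))
  # all-zero features through the bias-free MLP give sigmoid(0) = 0.5
  expect_equal(channel_attention(array(0, c(4, 4, 4)), r = 2, w1 = w1, w2 = w2),
               rep(0.5, 4))
  # permuting channels together with the MLP rows/columns permutes weights
  perm <- c(3, 1, 4, 2)
  s_perm <- channel_attention(f[, , perm], r = 2,
                              w1 = w1[perm, ], w2 = w2[, perm])
  expect_equal(s_perm, s[perm], tolerance = 1e-12)
  expect_error(channel_attention(f, r = 3), "divide")
})

test_that("spatial attention matches a brute-force convolution oracle", {
  set.seed(5)
  f <- array(runif(5 * 5 * 3), c(5, 5, 3))
  w <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1)) * 0.1
  b <- 0.2
  s <- spatial_attention(f, kernel = 7, w = w, b = b)
  expect_equal(dim(s), c(5, 5))
  expect_true(all(s > 0 & s < 1))
  # constant features with zero conv weights -> uniform sigmoid(0) = 0.5
  s0 <- spatial_attention(array(0.3, c(8, 8, 2)), kernel = 7,
                          w = array(0, c(7, 7, 2, 1)), b = 0)
  expect_true(all(s0 == 0.5))
  # hand convolution of the [mean, max] stack with zero padding
  mean_map <- apply(f, c(1, 2), mean)
  max_map <- apply(f, c(1, 2), max)
  stack2 <- list(mean_map, max_map)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    acc <- b
    for (u in -3:3) for (v in -3:3) for (ch in 1:2) {
      ii <- i + u; jj <- j + v
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5)
        acc <- acc + w[u + 4, v + 4, ch, 1] * stack2[[ch]][ii, jj]
    }
    brute[i, j] <- 1 / (1 + exp(-acc))
  }
  expect_equal(s, brute, tolerance = 1e-9)
})

test_that("attention variants differ exactly by the closed-form sublayer sizes", {
  counts <- vapply(c("none", "channel", "spatial", "full"), function(v)
    count_parameters(build_network(network_spec(attention = v), seed = 1)),
    numeric(1))
  ca_params <- 256 * 16 + 16 * 256    # shared MLP, no biases
  sa_params <- 7 * 7 * 2 + 1          # conv on [avg, max] stack, with bias
  expect_equal(counts[["channel"]] - counts[["none"]], ca_params)
  expect_equal(counts[["spatial"]] - counts[["none"]], sa_params)
  expect_equal(counts[["full"]] - counts[["none"]], ca_params + sa_params)
})

test_that("outputs stay clamped to [0, 1] under fuzzed inputs", {
  net <- build_network(tiny_spec(), seed = 8)
  # exaggerate the output scale to force clamping to engage
  net$params$conv6.b <- net$params$conv6.b + 0.5
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- forward(net, x)
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("weights round-trip through the float-32 file format", {
  net <- build_network(tiny_spec(), seed = 4)
  img <- generate_phantom(32, 32, 3, 0.6, seed = 2)
  path <- file.path(tempdir(), "w.bin")
  save_weights(net, path)
  back <- load_weights(path)
  expect_identical(names(back$params), names(net$params))
  # float-32 storage: round trip within single-precision resolution
  expect_lt(max(abs(unlist(back$params) - unlist(net$params))), 1e-6)
  expect_equal(forward(back, img), forward(net, img), tolerance = 1e-5)
})

test_that("file size on disk reflects the float-32 serialization accounting", {
  net <- build_network(tiny_spec(), seed = 4)
  path <- file.path(tempdir(), "w2.bin")
  save_weights(net, path)
  entries <- count_parameters(net) + sum(lengths(net$buffers))
  expect_equal(serialized_size_mb(net), entries * 4 / 1024^2)
  expect_gte(file.size(path), entries * 4)
})
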