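# shared fixtures: all data is generated in code, deterministically

default_noise <- function() noise_params(80, 0.02)

# paired 64x64 phantom samples at level 1 under the benchmark noise setting
make_phantom_pairs <- function(n, seed0 = 0L, size = 64L, level = 1L,
                               params = default_noise(), tag = "phantom") {
  lapply(seq_len(n), function(i) {
    clean <- generate_phantom(size, size, 5L, 0.8, seed = seed0 + i)
    noisy <- simulate_level(clean, params, level, seed = 10000L + seed0 + i)
    paired_sample(noisy, clean, level, tag)
  })
}

# a small spec (same topology, narrow widths) for fast training unit tests
tiny_spec <- function(attention = "full")
  network_spec(encoder_channels = c(8L, 16L, 32L, 64L),
               decoder_channels = c(32L, 16L, 8L),
               cbam_reduction = 16L,
               attention = attention)

# central-difference gradient of f at x, index-wise
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

expect_rel_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
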