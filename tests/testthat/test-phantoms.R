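test_that("zero-cell phantom is a near-uniform background", {
  img <- generate_phantom(64, 64, 0, 0.5, seed = 1)
  expect_true(all(img >= 0 & img <= 1))
  expect_lt(diff(range(img)), 0.05)
})

test_that("phantom generation is deterministic per seed and validated", {
  a <- generate_phantom(64, 64, 5, 0.8, seed = 7)
  b <- generate_phantom(64, 64, 5, 0.8, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_phantom(64, 64, 5, 0.8, seed = 8)))
  expect_error(generate_phantom(16, 64, 3, 0.5), "at least 32")
  expect_error(generate_phantom(64, 64, -1, 0.5), "non-negative")
})

test_that("cells add Sobel gradient energy over the background", {
  flat <- generate_phantom(64, 64, 0, 0.5, seed = 1)
  cells <- generate_phantom(64, 64, 5, 0.8, seed = 7)
  grad_energy <- function(img) {
    g <- sobel_gradients(img)
    mean(sqrt(g$gx^2 + g$gy^2))
  }
  expect_gt(grad_energy(cells), grad_energy(flat))
})

test_that("phantoms stay in [0, 1] under fuzzed parameters", {
  set.seed(11)
  for (i in 1:12) {
    img <- generate_phantom(sample(32:80, 1), sample(32:80, 1),
                            sample(0:12, 1), runif(1), seed = i)
    expect_true(all(img >= 0 & img <= 1))
  }
})

test_that("image round trips through PNG and TIFF at the format scale", {
  img <- generate_phantom(64, 64, 4, 0.7, seed = 3)
  p8 <- file.path(tempdir(), "rt8.png")
  write_image(img, p8, 8L)
  back8 <- read_image(p8)
  expect_lte(max(abs(back8 - img)), 1 / 510 + 1e-12)
  p16 <- file.path(tempdir(), "rt16.tif")
  write_image(img, p16, 16L)
  back16 <- read_image(p16)
  expect_lte(max(abs(back16 - img)), 1 / 131070 + 1e-12)
})

test_that("intensity quantization uses full scale and round-half-even", {
  # full-scale constants map exactly
  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  p <- file.path(tempdir(), "const.png")
  write_image(ones, p); expect_true(all(read_image(p) == 1))
  write_image(zeros, p); expect_true(all(read_image(p) == 0))
  # 51/255 = 0.2 exactly
  write_image(matrix(51 / 255, 16, 16), p)
  expect_true(all(abs(read_image(p) - 0.2) < 1e-12))
  # 0.5 * 255 = 127.5 rounds half-even to 128
  write_image(matrix(0.5, 16, 16), p)
  expect_true(all(abs(read_image(p) - 128 / 255) < 1e-12))
})

test_that("multi-channel and malformed image inputs are rejected", {
  p <- file.path(tempdir(), "rgb.png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), p)
  expect_error(read_image(p), "multi-channel")
  expect_error(read_image(file.path(tempdir(), "nope.png")), "does not exist")
  expect_error(write_image(matrix(2, 16, 16), p), "\\[0, 1\\]")
  expect_error(write_image(matrix(0.5, 16, 16),
                           file.path(tempdir(), "x.png"), 16L), "8-bit")
})

test_that("stratified split honours the 70/10/20 convention", {
  mk <- function(tag, lv, n) lapply(seq_len(n), function(i)
    paired_sample(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8), lv, tag))
  # 10 samples, one stratum -> sizes (7, 1, 2)
  parts <- split_dataset(mk("a", 1, 10), c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(lengths(parts)[c("train", "val", "test")],
               c(train = 7L, val = 1L, test = 2L))
  # 20 samples in 2 equal strata -> each stratum contributes (7, 1, 2)
  samples <- c(mk("a", 1, 10), mk("b", 1, 10))
  parts <- split_dataset(samples, c(0.7, 0.1, 0.2), seed = 5)
  for (part in parts) {
    tags <- vapply(part, `[[`, character(1), "modality_tag")
    expect_equal(unname(table(tags)["a"]), unname(table(tags)["b"]))
  }
  expect_equal(lengths(parts)[c("train", "val", "test")],
               c(train = 14L, val = 2L, test = 4L))
})

test_that("splits are deterministic, disjoint and conserve the total", {
  set.seed(2)
  samples <- lapply(1:23, function(i)
    paired_sample(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8),
                  sample(c(1, 4), 1), sample(c("x", "y"), 1)))
  p1 <- split_dataset(samples, seed = 9)
  p2 <- split_dataset(samples, seed = 9)
  expect_identical(p1, p2)
  expect_equal(sum(lengths(p1)), length(samples))
  key <- function(s) paste(s$modality_tag, s$level,
                           paste(round(s$noisy * 1e6), collapse = ""))
  all_keys <- unname(unlist(lapply(p1, function(part)
    vapply(part, key, character(1)))))
  expect_equal(sort(all_keys), sort(vapply(samples, key, character(1))))
})

test_that("tiny strata fall back to train with a warning", {
  small <- lapply(1:2, function(i)
    paired_sample(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8), 1, "rare"))
  expect_warning(parts <- split_dataset(small, seed = 1), "rare")
  expect_length(parts$train, 2)
  expect_length(parts$val, 0)
})

test_that("augmentation applies one of four flips, the same to both images", {
  pair <- make_phantom_pairs(1, seed0 = 40L)[[1]]
  # constant pair unchanged under any seed
  const <- paired_sample(matrix(0.3, 8, 8), matrix(0.3, 8, 8), 1, "c")
  for (s in 1:5) expect_identical(augment(const, s), const)
  # applying the same variant twice restores the original (involution)
  for (v in 0:3) {
    once <- bdnet:::apply_flip_variant(pair, v)
    expect_identical(bdnet:::apply_flip_variant(once, v), pair)
  }
  # noisy and clean receive the same flip: PSNR is preserved exactly
  before <- psnr(pair$noisy, pair$clean)
  for (s in 1:8) {
    aug <- augment(pair, s)
    expect_identical(psnr(aug$noisy, aug$clean), before)
  }
})

test_that("flip variants are drawn uniformly", {
  pair <- paired_sample(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8), 1, "u")
  draws <- vapply(seq_len(4000), function(s) {
    aug <- augment(pair, s)
    h <- !identical(aug$noisy[1, ], pair$noisy[1, ]) &&
      identical(aug$noisy[1, rev(seq_len(8))], pair$noisy[1, ]) ||
      identical(aug$noisy, bdnet:::flip_image(pair$noisy, TRUE, FALSE)) ||
      identical(aug$noisy, bdnet:::flip_image(pair$noisy, TRUE, TRUE))
    v <- identical(aug$noisy, bdnet:::flip_image(pair$noisy, FALSE, TRUE)) ||
      identical(aug$noisy, bdnet:::flip_image(pair$noisy, TRUE, TRUE))
    1L + as.integer(h) + 2L * as.integer(v)
  }, integer(1))
  freq <- tabulate(draws, 4) / 4000
  expect_true(all(freq >= 0.22 & freq <= 0.28))
})

test_that("manifests round-trip paired samples through disk", {
  samples <- make_phantom_pairs(3, seed0 = 60L, size = 32L)
  dir <- file.path(tempdir(), "man_rt")
  path <- write_manifest(samples, dir)
  back <- read_manifest(path)
  expect_length(back, 3)
  expect_equal(back[[2]]$level, samples[[2]]$level)
  expect_lt(max(abs(back[[2]]$noisy - samples[[2]]$noisy)), 1 / 131070 + 1e-12)
})
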