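test_that("step schedule follows lr * factor^floor(iter / step)", {
  expect_equal(bdnet:::step_lr(1e-3, 1499, 1500, 0.2), 1e-3)
  expect_equal(bdnet:::step_lr(1e-3, 1500, 1500, 0.2), 2e-4)
  expect_equal(bdnet:::step_lr(1e-3, 3000, 1500, 0.2), 4e-5)
})

test_that("gradient clipping rescales to the requested global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  norm0 <- sqrt(sum(unlist(g)^2))
  cl <- bdnet:::clip_gradients(g, 1.0)
  expect_equal(cl$norm, norm0)
  expect_equal(sqrt(sum(unlist(cl$grads)^2)), 1.0, tolerance = 1e-12)
  small <- bdnet:::clip_gradients(list(a = 1e-3), 1.0)
  expect_identical(small$grads$a, 1e-3)
})

test_that("short training runs are deterministic and reduce the loss", {
  pairs <- make_phantom_pairs(8, seed0 = 200L, size = 32L)
  cfg <- train_config(batch_size = 2, max_iterations = 40, seed = 2025,
                      val_interval = 20)
  net <- build_network(tiny_spec(), seed = 2025)
  f1 <- train_network(net, pairs[1:6], pairs[7:8], cfg)
  f2 <- train_network(net, pairs[1:6], pairs[7:8], cfg)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$history$loss, f2$history$loss)
  # optimization reduces the running loss on average
  expect_lt(mean(tail(f1$history$loss, 10)), mean(head(f1$history$loss, 10)))
  # learning-rate trace obeys the schedule at every logged iteration
  expect_equal(f1$history$lr,
               bdnet:::step_lr(cfg$learning_rate, f1$history$iteration,
                               cfg$step_size, cfg$decay_factor))
  expect_error(train_network(net, list(), pairs[7:8], cfg), "empty")
})

test_that("all loss-ablation presets train end-to-end at desk scale", {
  pairs <- make_phantom_pairs(4, seed0 = 300L, size = 32L)
  cfg <- train_config(batch_size = 2, max_iterations = 4, seed = 2025,
                      val_interval = 4)
  net <- build_network(tiny_spec(), seed = 1)
  for (nm in c("l1", "l2", "l1_ssim", "l1_l2_ssim", "giel")) {
    fit <- train_network(net, pairs[1:3], pairs[4], cfg, loss_preset(nm))
    expect_true(all(is.finite(fit$history$loss)))
  }
})

test_that("denoise_image pads and crops arbitrary sizes", {
  net <- build_network(tiny_spec(), seed = 3)
  x <- matrix(runif(65 * 67), 65, 67)
  y <- denoise_image(net, x)
  expect_equal(dim(y), c(65, 67))
  expect_true(all(y >= 0 & y <= 1))
  # already-aligned sizes pass through the plain forward
  x4 <- matrix(runif(64 * 64), 64, 64)
  expect_identical(denoise_image(net, x4), forward(net, x4))
  # padded forward agrees with the plain forward on shared content scale
  expect_equal(dim(denoise_image(net, matrix(runif(9 * 14), 9, 14))), c(9, 14))
})

test_that("evaluation aggregates per-image metrics over a pair list", {
  net <- build_network(tiny_spec(), seed = 5)
  pairs <- make_phantom_pairs(3, seed0 = 400L, size = 32L)
  rep_ <- evaluate_network(net, pairs)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(rep_$n_images, 3)
  expect_equal(rep_$mean$psnr, mean(rep_$per_image$psnr))
  single <- evaluate_network(net, pairs[1])
  expect_equal(single$mean$rmse, single$per_image$rmse[1])
  # report of the identity mapping equals metrics of noisy vs clean
  noisy_psnr <- mean(vapply(pairs, function(s) psnr(s$noisy, s$clean),
                            numeric(1)))
  id_rows <- vapply(pairs, function(s)
    bdnet:::metric_row(s$noisy, s$clean)$psnr, numeric(1))
  expect_equal(mean(id_rows), noisy_psnr)
  expect_error(evaluate_network(net, list()), "empty")
})

test_that("training aborts with a diagnostic when the loss diverges", {
  pairs <- make_phantom_pairs(4, seed0 = 500L, size = 32L)
  net <- build_network(tiny_spec(), seed = 1)
  net$params$conv6.w[] <- NaN  # poisoned weights force a non-finite loss
  cfg <- train_config(batch_size = 2, max_iterations = 3, seed = 2025,
                      val_interval = 3)
  expect_error(train_network(net, pairs[1:3], pairs[4], cfg),
               "diverged|non-finite")
})
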