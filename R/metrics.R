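#' Peak signal-to-noise ratio on \[0, 1\] data
#'
#' `10 * log10(1 / MSE)` with data range 1 (MATLAB convention). Identical
#' images have zero MSE and are reported as `Inf`; reports serialize this
#' as the string `"inf"`.
#'
#' @param pred,ref Numeric matrices of identical size.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(pred, ref) {
  check_same_shape(pred, ref, c("pred", "ref"))
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Root-mean-square reconstruction error
#'
#' The per-pixel L2 error `sqrt(mean((pred - ref)^2))`; satisfies
#' `psnr = -20 * log10(rmse)` whenever `rmse > 0`.
#'
#' @param pred,ref Numeric matrices of identical size.
#' @return Non-negative scalar.
#' @export
rmse <- function(pred, ref) {
  check_same_shape(pred, ref, c("pred", "ref"))
  sqrt(mean((pred - ref)^2))
}

#' @rdname ssim
#' @export
ssim_metric <- function(pred, target, window_size = 11L, sigma = 1.5)
  ssim(pred, target, window_size, sigma)

#' Learned perceptual distance (optional backbone)
#'
#' Computes a perceptual distance through a user-supplied pretrained
#' feature backbone. The grayscale input is replicated across three
#' channels before being handed to the backbone, matching the convention
#' for VGG-style networks. When no backbone is available the function
#' degrades gracefully: it returns status `"unavailable"` with an `NA`
#' value and never errors, so pipelines that also compute PSNR/RMSE/SSIM
#' keep working.
#'
#' @param pred,ref Numeric matrices of identical size.
#' @param backbone Optional `function(pred_rgb, ref_rgb)` taking two
#'   `[H, W, 3]` arrays and returning a scalar distance.
#' @return A list with elements `value` (scalar or `NA`) and `status`
#'   (`"ok"` or `"unavailable"`).
#' @export
lpips_optional <- function(pred, ref, backbone = NULL) {
  check_same_shape(pred, ref, c("pred", "ref"))
  if (is.null(backbone) || !is.function(backbone))
    return(list(value = NA_real_, status = "unavailable"))
  to_rgb <- function(m) array(rep(m, 3L), c(nrow(m), ncol(m), 3L))
  val <- tryCatch(backbone(to_rgb(pred), to_rgb(ref)),
                  error = function(e) NA_real_)
  if (is.na(val)) list(value = NA_real_, status = "unavailable")
  else list(value = as.numeric(val), status = "ok")
}

#' Informational inference-throughput report
#'
#' Times repeated forward passes on a square input, discarding warm-up
#' runs, and reports frames per second. The figure depends entirely on the
#' host hardware and is informational only — it is never part of any
#' quality assessment.
#'
#' @param network A [build_network()] object.
#' @param image_size Square input side (divisible by 4).
#' @param n_warmup Warm-up runs excluded from the mean.
#' @param n_runs Timed runs; must be >= 1.
#' @return A list with `fps`, `mean_seconds`, `n_runs`, and a `hardware`
#'   disclaimer string.
#' @export
timing_report <- function(network, image_size = 512L, n_warmup = 50L,
                          n_runs = 500L) {
  stopifnot(inherits(network, "bdnet"))
  if (n_runs < 1L) stop_invalid("n_runs must be at least 1")
  if (n_warmup < 0L) stop_invalid("n_warmup must be non-negative")
  x <- matrix(0.5, image_size, image_size)
  for (i in seq_len(n_warmup)) forward(network, x)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_runs)) forward(network, x)
  el <- proc.time()[["elapsed"]] - t0
  mean_s <- el / n_runs
  list(fps = 1 / mean_s, mean_seconds = mean_s, n_runs = n_runs,
       hardware = paste("Throughput depends on the host CPU/BLAS;",
                        "informational only, not a quality metric."))
}

# per-image metric row used by evaluate()
metric_row <- function(pred, ref, backbone = NULL) {
  lp <- lpips_optional(pred, ref, backbone)
  data.frame(psnr = psnr(pred, ref), rmse = rmse(pred, ref),
             ssim = ssim(pred, ref), lpips = lp$value)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> over", x$n_images, "image(s)\n")
  cat(sprintf("  mean PSNR: %s dB\n",
              ifelse(is.finite(x$mean$psnr), sprintf("%.4f", x$mean$psnr), "inf")))
  cat(sprintf("  mean RMSE: %.6f\n", x$mean$rmse))
  cat(sprintf("  mean SSIM: %.4f\n", x$mean$ssim))
  if (!is.na(x$mean$lpips)) cat(sprintf("  mean LPIPS: %.4f\n", x$mean$lpips))
  invisible(x)
}
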