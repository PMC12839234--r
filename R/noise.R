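#' Poisson-Gaussian noise parameters
#'
#' Parameterizes the forward corruption model of a photon-counting detector:
#' per pixel, `y = Poisson(alpha * f(x)) / alpha + N(0, sigma^2)`, where
#' `alpha` is the photon-to-digital gain (larger gain = lower relative shot
#' noise) and `sigma` the Gaussian readout standard deviation on the \[0,1\]
#' intensity scale. `f` is convolution with an optional point spread
#' function; the identity PSF is the default, the usual assumption when the
#' microscope PSF has been calibrated out.
#'
#' The defaults (`alpha = 80`, `sigma = 0.02`) place a single raw capture of
#' a mid-intensity phantom in the low-20s dB PSNR regime typical of raw
#' fluorescence acquisitions.
#'
#' @param alpha Photon-to-digital gain, > 0.
#' @param sigma Readout noise standard deviation, >= 0.
#' @param psf Optional odd-sized square kernel, non-negative, summing to 1.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(alpha = 80, sigma = 0.02, psf = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop_invalid("alpha must be a single value > 0")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop_invalid("sigma must be a single value >= 0")
  if (!is.null(psf)) check_psf(psf)
  structure(list(alpha = alpha, sigma = sigma, psf = psf),
            class = "noise_params")
}

check_psf <- function(psf) {
  if (!is.matrix(psf) || nrow(psf) != ncol(psf))
    stop_invalid("psf must be a square matrix")
  if (nrow(psf) %% 2L == 0L)
    stop_invalid("psf size must be odd (got ", nrow(psf), ")")
  if (any(psf < 0)) stop_invalid("psf entries must be non-negative")
  if (abs(sum(psf) - 1) > 1e-9)
    stop_invalid("psf entries must sum to 1 (got ", signif(sum(psf), 8), ")")
  invisible(psf)
}

#' Apply the deterministic imaging operator (PSF blur)
#'
#' Convolves the clean image with the point spread function using zero
#' padding at the boundaries, returning an image of the same size. With a
#' normalized non-negative kernel the output cannot leave \[0, 1\]; the
#' identity (NULL) PSF returns the input bit-exactly.
#'
#' @param clean Numeric matrix in \[0, 1\].
#' @param psf Optional PSF kernel (odd square, non-negative, sum 1), or a
#'   [noise_params()] object whose `psf` is used.
#' @return Blurred image matrix, same size as `clean`.
#' @export
apply_forward <- function(clean, psf = NULL) {
  check_image(clean)
  if (inherits(psf, "noise_params")) psf <- psf$psf
  if (is.null(psf)) return(clean)
  check_psf(psf)
  k <- nrow(psf)
  y <- conv2d_fw_cpp(as_tensor(clean), array(psf, c(k, k, 1L, 1L)),
                     NULL, 1L, (k - 1L) %/% 2L, FALSE)
  clamp01(as_matrix_image(y))
}

#' Corrupt a clean image with Poisson-Gaussian noise
#'
#' Per pixel, draws `Poisson(alpha * f(x)) / alpha` shot noise and adds
#' independent `N(0, sigma^2)` readout noise. The observation is clipped to
#' \[0, 1\] by default (the data model declares observations on that scale);
#' `clip = FALSE` exposes the raw draw, which is what the closed-form
#' moments of [noise_moments()] describe.
#'
#' @param clean Numeric matrix in \[0, 1\].
#' @param params A [noise_params()] object.
#' @param seed Integer seed; the draw is bit-identical per seed.
#' @param clip Clip the result to \[0, 1\]? Default TRUE.
#' @return Noisy image matrix.
#' @export
add_poisson_gaussian <- function(clean, params = noise_params(), seed = 1L,
                                 clip = TRUE) {
  check_image(clean)
  stopifnot(inherits(params, "noise_params"))
  f <- apply_forward(clean, params$psf)
  n <- length(f)
  y <- with_seed(seed, {
    shot <- rpois(n, params$alpha * as.vector(f)) / params$alpha
    shot + rnorm(n, 0, params$sigma)
  })
  y <- matrix(y, nrow(clean), ncol(clean))
  if (clip) y <- clamp01(y)
  y
}

#' Simulate an observation at a given frame-averaging noise level
#'
#' Mirrors the FMD acquisition convention: an observation at level `L` is
#' the pixel-wise mean of `L` independent single-capture realizations, so
#' the noise variance scales as 1/L and higher levels are *less* noisy
#' (level 16 averages 16 frames; the clean reference corresponds to
#' averaging many more, e.g. 50).
#'
#' Frame `i` uses sub-seed `seed + i - 1`, a fixed counter scheme that makes
#' frames independent and reproducible; level 1 is bit-identical to a single
#' [add_poisson_gaussian()] draw at `seed`.
#'
#' @inheritParams add_poisson_gaussian
#' @param level Positive integer: number of frames averaged.
#' @return Noisy image matrix (mean of `level` frames).
#' @export
simulate_level <- function(clean, params = noise_params(), level = 1L,
                           seed = 1L, clip = TRUE) {
  if (length(level) != 1L || is.na(level) || level < 1 || level != round(level))
    stop_invalid("level must be a positive integer")
  acc <- matrix(0, nrow(clean), ncol(clean))
  for (i in seq_len(level))
    acc <- acc + add_poisson_gaussian(clean, params, seed + i - 1L, clip = FALSE)
  y <- acc / level
  if (clip) y <- clamp01(y)
  y
}

#' Closed-form moments of the un-clipped Poisson-Gaussian observation
#'
#' For a pixel with blurred clean intensity `v`, the observation
#' `Poisson(alpha * v)/alpha + N(0, sigma^2)` has mean `v` and variance
#' `v / alpha + sigma^2`. Used as the analytic oracle for the stochastic
#' simulator.
#'
#' @param clean_value Intensity in \[0, 1\] (scalar or vector).
#' @param params A [noise_params()] object.
#' @return A list with elements `mean` and `variance`.
#' @export
noise_moments <- function(clean_value, params = noise_params()) {
  stopifnot(inherits(params, "noise_params"))
  if (any(clean_value < 0 | clean_value > 1))
    stop_invalid("clean_value must lie in [0, 1]")
  list(mean = clean_value,
       variance = clean_value / params$alpha + params$sigma^2)
}
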