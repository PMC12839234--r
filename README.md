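# bdnet

Supervised denoising of single-channel fluorescence microscopy images in R,
with no external deep-learning runtime.

Raw fluorescence acquisitions are photon-starved: the observation at pixel
*p* follows the mixed Poisson–Gaussian model

    y_p = Poisson(α · f(x)_p) / α + ε_p,   ε_p ~ N(0, σ²)

where `x ∈ [0,1]^{H×W}` is the clean image, `f` the imaging operator (a PSF
convolution; identity once the PSF is calibrated out), `α > 0` the
photon-to-digital gain and `σ` the readout noise. Denoisers trained with
purely pixel-wise objectives remove this noise but blur exactly the
structures biologists care about — membranes, boundaries, puncta.

`bdnet` implements **BDNet**, a lightweight encoder–bottleneck–decoder
convolutional denoiser (≈ 0.8 M parameters, 2.9–3.0 MB of float-32 state)
with a convolutional block attention module (CBAM) at the bottleneck and
three learnable skip connections, trained with the **Gradient Information
Enhancement Loss**

    L_total = λ₁·L1 + λ₂·L2 + λ₃·(1 − SSIM) + λ_g·L_grad,
    L_grad  = ‖S_x∗x̂ − S_x∗x‖₁ + ‖S_y∗x̂ − S_y∗x‖₁

with Sobel stencils `S_x, S_y` and default weights (1.0, 0.1, 0.2, 0.2).
The gradient term penalises edge-map discrepancies directly, so the network
is pushed to reconstruct high-frequency structure instead of over-smoothing.
Optimization uses AdamW (β = 0.9/0.999, weight decay 1e-4), learning rate
1e-3 decayed by 0.2 every 1500 iterations, batch size 30, global
gradient-norm clipping at 1.0, and flip-only augmentation.

Everything is implemented in the package: convolution, transposed
convolution, BatchNorm, channel/spatial attention and their analytic
gradients run on RcppArmadillo kernels (single-precision GEMM through the
host BLAS), so training and inference work on a plain CPU.

The package also ships:

* a **Poisson–Gaussian simulator** with frame-averaging noise levels
  (level *L* = mean of *L* independent captures, the FMD-dataset
  convention: level 16 is the *cleanest*, the clean reference is the
  average of ~50 captures), plus closed-form moment oracles;
* a **phantom generator** producing fluorescence-like cell images with
  bright membrane rims — controlled sharp edges for exercising the
  gradient loss;
* **metrics** with MATLAB-consistent conventions on [0,1] data: PSNR,
  RMSE, Gaussian-window SSIM (11×11, σ = 1.5), an optional perceptual
  distance hook, and an informational FPS utility;
* dataset plumbing (stratified 70/10/20 splits, CSV manifests, 8/16-bit
  PNG/TIFF I/O) and a CLI.

## Worked example

```r
library(bdnet)

params <- noise_params(alpha = 80, sigma = 0.02)
clean  <- generate_phantom(64, 64, n_cells = 5, membrane_contrast = 0.8, seed = 1)
noisy  <- simulate_level(clean, params, level = 1, seed = 42)
psnr(noisy, clean); ssim(noisy, clean)
#> noisy input PSNR: 24.92 dB, SSIM: 0.7282

net <- build_network(network_spec(), seed = 2025)
net
#> <bdnet denoiser>
#>   attention variant: full
#>   learnable parameters: 795586
#>   serialized float-32 size: 3.0403 MB

# 32 training / 8 validation phantom pairs, 300 AdamW iterations at batch 8
# (~2 min on one CPU)
fit <- train_network(net, train_pairs, val_pairs,
                     train_config(batch_size = 8, max_iterations = 300,
                                  seed = 2025))
evaluate_network(fit$network, val_pairs)
#> <metrics_report> over 8 image(s)
#>   mean PSNR: 27.4167 dB
#>   mean RMSE: 0.042622
#>   mean SSIM: 0.9756

denoise_image(fit$network, noisy)
#> denoised PSNR: 27.18 dB, SSIM: 0.9685
```

The desk-scale run gains ≈ 2.5 dB PSNR and lifts SSIM from 0.73 to 0.98
over the raw observation; the full training protocol
(`train_config()` defaults) is the published setting.

The same pipeline is scriptable from a shell via `inst/cli/bdnet.R`:

```sh
Rscript inst/cli/bdnet.R simulate --out data --n-images 20 --levels 1,2,4,8,16
Rscript inst/cli/bdnet.R train    --manifest data/manifest.csv --out run
Rscript inst/cli/bdnet.R denoise  --weights run/weights.bin \
                                  --input data/noisy_0001.tif --output out.tif
Rscript inst/cli/bdnet.R evaluate --manifest data/manifest.csv \
                                  --weights run/weights.bin --out eval
Rscript inst/cli/bdnet.R describe
```

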