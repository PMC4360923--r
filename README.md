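# psnlm

Pre-smoothed non-local means (PSNLM) denoising of Rician-corrupted 3D MR
volumes.

## What it does

Magnitude MRI carries Rician noise: the measured magnitude is
`|z| = sqrt((r + n1)^2 + n2^2)` with independent Gaussian `n1, n2 ~ N(0, σ)`,
so the noise is signal-dependent and biased, and filters built for additive
noise misbehave on it. The non-local means (NLM) filter — each voxel replaced
by a weighted average over an 11×11×11 search window, weights
`w ∝ exp(−‖N_i − N_j‖²_{G_a} / h²)` decaying in 5×5×5 patch distance — has a
second weakness on noisy data: the patch distances themselves are noisy.

`psnlm` addresses both:

1. **Transform** the volume so its noise is approximately additive — squared
   magnitude (`E|z|² = r² + 2σ²`) or a numerically constructed
   variance-stabilizing transform (VST) with unit stabilized variance;
2. **Pre-smooth** the transformed volume (Gaussian / median / anisotropic
   diffusion) into a guidance image;
3. **Filter** the transformed volume by NLM with patch weights computed from
   the guidance image;
4. **Invert** with bias compensation — subtract `2σ²` and take the square
   root (PSNLM1), or apply the exact-unbiased VST inverse mapping each value
   `y` to the `ν` with `E[f(z)|ν] = y` (PSNLM2).

σ is estimated automatically from the image background (median filter → Otsu
threshold → morphological close → 3D hole fill; `σ = sqrt(μ/2)` with `μ` the
background mean of the squared magnitudes). A seeded brain-like phantom
generator and PSNR/MSE evaluation make the whole framework testable without
any external data.

## Worked example

```r
library(psnlm)

clean <- generate_phantom(phantom_spec(c(48, 48, 48), "T1"))   # t = 150
noisy <- add_rician_noise(clean, percent = 17, seed = 11)      # sigma = 25.5

out <- psnlm_pipeline(noisy, pipeline_config("psnlm2"))
attr(out, "psnlm_info")$sigma
#> [1] 25.43773
evaluate_denoising(noisy, clean, cmax = 150)$psnr
#> [1] 13.10608
evaluate_denoising(out, clean, cmax = 150)$psnr
#> [1] 21.26958
```

The estimated σ (25.44) comes from the automatically segmented background
and sits within 0.3% of the true 25.5; denoising with the default `h`
lifts the PSNR of this phantom by about 8 dB, and grid-searching `h` per
method (see `select_h()`) adds roughly 3 dB more. With `h` selected per
method, the pre-smoothed variants beat their unsmoothed counterparts by
over 1 dB, and every transform-based variant beats plain NLM by a wide
margin.

A thin command-line front end is installed with the package
(`exec/psnlm`):

```sh
psnlm simulate --modality T1 --shape 64 --percent 17 --seed 1 \
      --out-clean clean.nii.gz --out-noisy noisy.nii.gz
psnlm denoise --input noisy.nii.gz --output out.nii.gz --variant psnlm2 \
      --presmooth gaussian --sigma auto
psnlm evaluate --result out.nii.gz --reference clean.nii.gz --cmax 150
```

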