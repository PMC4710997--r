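# dwisr

Sparse-representation denoising of diffusion-weighted MR image (DWI)
sequences, for researchers who need cleaner diffusion tensor images (DTI)
— and the fractional anisotropy (FA) maps derived from them — before
quantitative analysis.

## What it does

A DWI sequence samples the Stejskal–Tanner decay
`S = S0 exp(-b gᵀ D g)` along many gradient directions `g`; the per-voxel
tensor `D` is then fit by least squares and summarized by FA. Magnitude MR
noise (Rician) corrupts both. `dwisr` denoises the weighted volumes first,
by modelling image patches as sparse combinations of atoms from an
overcomplete dictionary learned from the noisy data itself.

For a group of `L` adjacent slices `Y = [Y₁ … Y_L]` the method solves

```
argmin_{α,X}  λ‖Y − X‖² + Σ_{ijl} ‖R_{ijl}X − Ψα_{ijl}‖² + Σ_{ijl} μ_{ijl}‖α_{ijl}‖₁
```

by block-coordinate relaxation: (1) each overlapping patch is coded by the
error-constrained minimum-ℓ1 program
`min ‖α‖₁ s.t. ‖p − Ψα‖² ≤ C n² σ²`, solved exactly by lasso homotopy;
(2) dictionary atoms are refined one at a time by the rank-1 SVD of their
restricted residual (K-SVD); (3) each slice is reconstructed in closed
form as `x = (λI + ΣRᵀR)⁻¹(λy + ΣRᵀΨα)`, a per-pixel weighted average.
Adjacent slices of a volume share structure ("context redundancy"), so one
dictionary per slice group both improves the representation and cuts cost;
the learned dictionary warm-starts the same group of the next gradient
volume.

The package also provides the supporting machinery: a seeded DTI phantom
(parametric tensor fields, Stejskal–Tanner forward model, Rician noise), a
log-linear tensor fitter, FA / colour-FA maps and FA error statistics, and
NIfTI + FSL bval/bvec input and output, plus a `dwidenoise-sr` command-line
tool (`simulate`, `run`, `eval`).

## A worked example

```r
library(dwisr)

field  <- make_tensor_field(c(64, 64, 5), "two_region", seed = 1)
scheme <- make_gradient_scheme(32, bval = 1000)     # 1 b=0 + 32 directions
clean  <- simulate_dwi(field, scheme, s0 = 100)
sigma  <- center_noise_level(clean)                 # 1/10 of central b0 mean
noisy  <- add_rician_noise(clean, sigma, seed = 2)

res <- denoise_sequence(noisy, denoise_config(seed = 1))

sqrt(mean((noisy$data        - clean$data)^2))      # 10.4186
sqrt(mean((res$denoised$data - clean$data)^2))      #  6.5265

maps_ref   <- colored_fa(fit_tensors(clean,        mask = field$mask))
maps_noisy <- colored_fa(fit_tensors(noisy,        mask = field$mask))
maps_den   <- colored_fa(fit_tensors(res$denoised, mask = field$mask))
fa_error_stats(maps_ref, maps_noisy)
# fa_error_stats: bias 0.08639, variance 0.01189, RMSE 0.1391 (Q = 13040)
fa_error_stats(maps_ref, maps_den)
# fa_error_stats: bias 0.00872, variance 0.005531, RMSE 0.07487 (Q = 13040)
```

Here `sigma = 10` (signal-to-noise 10 at b=0). Denoising cuts the voxelwise
RMSE to the clean images by about 37 %, shrinks the FA bias by an order of
magnitude and halves the FA error's spread over the tissue mask — the
fitted tensors are both less biased and less dispersed than those from the
noisy data.

The same pipeline runs from the shell:

```sh
dwidenoise-sr simulate --out phantom/ --seed 1
dwidenoise-sr run --in phantom/phantom_dwi.nii.gz \
    --bval phantom/phantom_dwi.bval --bvec phantom/phantom_dwi.bvec \
    --sigma 10 --out denoised.nii.gz --report report.json
dwidenoise-sr eval --ref phantom/phantom_clean.nii.gz --test denoised.nii.gz \
    --bval phantom/phantom_dwi.bval --bvec phantom/phantom_dwi.bvec
```

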