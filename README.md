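# petdle

Deep-learning enhancement (DLE) of reduced-duration PET reconstructions,
as a complete desk-scale pipeline in R.

## The problem

Whole-body FDG-PET images reconstructed with fast, unregularised OSEM
(stopped after ~2 iterations) are noisy and not fully converged, so lesion
SUVmax is biased; convergent Bayesian reconstruction (BSREM) with a
relative-difference-prior penalty of strength β gives low-noise,
high-contrast images but is slow and needs per-site tuning of β. A
residual 3-D convolutional encoder–decoder can be trained to map OSEM
images of full- and reduced-duration scans directly into BSREM-like
images, cutting scan time and reconstruction time at once.

`petdle` implements the whole life cycle of such a model on synthetic
torso phantoms:

* **Simulation** — voxelised torso phantoms in SUV units (body, liver,
  lungs, 3–5 hot lesions); Poisson projection counts through a slice-wise
  parallel-beam projector with an image-space Gaussian PSF; reduced scan
  durations (¾, ½, ¼) by binomial thinning, the exact surrogate for a
  shorter Poisson acquisition.
* **Reconstruction** — OSEM (`x · Aᵀ(y/(Ax))/Aᵀ1`, ordered subsets) and
  BSREM with the relative difference prior
  `R(x) = Σ (xⱼ−xₖ)²/(xⱼ+xₖ+γ|xⱼ−xₖ|+ε)`, diminishing relaxation and a
  divergence detector; β = 0 reduces exactly to OSEM.
* **Enhancement network** — a residual 3-D U-Net (3×3×3 convolutions,
  batch norm, max pooling, tri-linear upsampling, skip connections)
  predicting a signed residue added to its input; smooth/standard/sharp
  variants differ only in channel width (hence trainable-parameter
  count). Forward and backward passes are implemented in the package
  (Rcpp + BLAS) and verified against finite differences.
* **Training** — body cropping (≤ 40 % per transverse axis), equally
  spaced axial patches, shuffled mini-batch MSE with Adam, per-epoch
  validation, and epoch selection by the rank-sum of validation loss and
  validation lesion-SUVmax error.
* **Evaluation** — 7×7×7-voxel organ VOIs (SUVmean, noise SD, background
  variability), adaptive-threshold lesion segmentation (42 % of max−min
  in the box), signed/absolute percent differences vs the full-duration
  BSREM target, OLS calibration slopes, Bland–Altman limits of agreement
  (±1.96 SD), exact/approximate Wilcoxon signed-rank tests, quadratic
  weighted kappa and tie-aware (competition-ranked) reader-score tables.

## Worked example

```r
library(petdle)

# one phantom case: simulate, reconstruct, inspect
spec <- default_phantom_spec(seed = 7)
proj <- projector_config()                     # 48 angles, 5 mm PSF
sim  <- simulate_case(spec, proj, fractions = c(1, 0.5), seed = 7)
osem <- osem_reconstruct(sim$sinos$f100, proj, recon_params("OSEM", 2, 8))
bsrem <- bsrem_reconstruct(sim$sinos$f100, proj,
                           recon_params("BSREM", 20, 8, beta = 1,
                                        relaxation_decay = 0.1))
rois <- phantom_rois(spec)
voi_stats(osem,  rois$vois)$liver_noise_sd     # 0.203  (noisy input)
voi_stats(bsrem, rois$vois)$liver_noise_sd     # 0.138  (regularised target)

# full study: corpus -> train DLE-standard -> quantitative report
config <- experiment_config()                  # 20/4/4 cases, 4 fractions
corpus <- make_corpus(config, seed = 1)
model  <- train_on_corpus(corpus, "standard")
report <- evaluate_corpus(corpus, list(dle_standard = model))
print(report)
#> Quantitative report (reference: full-duration BSREM)
#>             series n_lesions mean_abs_pct_diff mean_pct_diff liver_noise_sd gradient
#>         bsrem_full        18              0.00          0.00          0.141     1.00
#>          osem_f100        18              9.28          9.28          0.204     1.19
#>          osem_f050        18             14.27         14.27          0.277     1.18
#>  dle_standard_f100        18              3.91         -1.25          0.127     1.10
#>  dle_standard_f050        18              4.01          0.37          0.134     1.10
#>  ...
```

The `summary` table gives, per series (OSEM, DLE, BSREM reference at
each duration), the mean liver-noise SD (SUV), the signed and absolute
mean lesion-SUVmax percent difference against the full-duration BSREM
target, the OLS slope of lesion SUVmax against the target, and
Bland-Altman mean/limits. The output above (seed 1) shows the
qualitative signature of the enhancement working: DLE liver noise
(0.127/0.134 SUV) is below its OSEM input (0.204/0.277) and at the
level of the BSREM target (0.141), while the lesion-SUVmax difference
against the target drops from 9.3%/14.3% (OSEM, full/half duration) to
3.9%/4.0%.

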