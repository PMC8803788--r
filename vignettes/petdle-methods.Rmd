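---
title: "Deep-learning enhancement of reduced-duration PET reconstructions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning enhancement of reduced-duration PET reconstructions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical PET reconstruction trades noise against contrast. Unregularised
OSEM stopped after a couple of iterations is fast but noisy and not fully
converged, so lesion SUVmax is biased relative to a converged
reconstruction. Regularised BSREM converges and controls noise explicitly
through a penalty strength $\beta$, at the cost of much longer
reconstruction times and per-site tuning of $\beta$. A deep-learning
enhancement (DLE) model sidesteps the trade-off at inference time: it is
trained to map fast OSEM images of full- and reduced-duration scans into
images that look and quantify like the full-duration BSREM target, in a
single forward pass.

`petdle` implements that pipeline end to end at desk scale — synthetic
phantoms instead of patient scans, a 2-D parallel-beam projector applied
slice-wise instead of a clinical scanner model — together with the full
quantitative evaluation machinery used in reduced-dose PET studies. The
aim is a faithful, testable miniature of the method, not a reproduction
of clinical numbers: every distributional property, update equation and
statistic is the real one, exercised on data small enough to simulate and
train on one CPU in minutes.

## Synthetic data: what the generator emulates

`default_phantom_spec()` builds a 64 × 64 × 24 voxel torso (4 mm
isotropic): an elliptic body at SUV 1.0, a liver ellipsoid at SUV 2.2,
two lungs at SUV 0.5, and 3–5 spherical lesions of radius 2–4 voxels with
SUV drawn from 5–10 — one lesion in the liver, the rest in the body
background. The grid supports the full evaluation protocol (five
7 × 7 × 7 VOIs in the liver and five across the lungs,
placed clear of lesions) while keeping reconstruction and training fast.
Lesion positions, sizes and uptakes vary with the case seed, so a corpus
has genuine inter-case variability.

Projection data are Poisson: `simulate_counts()` draws
$y_i \sim \mathrm{Poisson}(s\,[A x]_i)$ with $A$ the projector and $s$
(`scale`, default 1) the expected-counts multiplier — about $2\times10^6$
counts per phantom at full duration, chosen so that the full-duration
OSEM image is visibly noisy and quarter-duration markedly worse. No
clinical noise-equivalent count level is being matched here; `scale` is
the free calibration knob of the simulation.

Reduced scan durations are produced by binomial thinning
(`thin_counts()`): each count is kept with probability $f$. Thinning a
Poisson variable yields a Poisson variable with rate scaled by $f$, so
this is the exact statistical surrogate for acquiring a shorter scan —
the simulator has no event timestamps to truncate. The property-based
tests verify mean linearity, the distributional identity (chi-square) and
the composition law $f_1 \circ f_2 = f_1 f_2$.

What the generator does *not* emulate: attenuation, scatter and randoms,
time-of-flight, scanner geometry, respiratory motion, and anatomical
texture. Passing tests therefore demonstrate the method's behaviour under
an idealised Poisson imaging model, not clinical performance.

## Projector and reconstruction

`forward_project()` applies an in-plane Gaussian PSF (FWHM
`psf_fwhm` = 5 mm by default) followed by pixel-driven parallel-beam line
integrals at `n_angles` = 48 angles over 180°, slice by slice; each pixel
deposits unit weight per angle, linearly interpolated between the two
nearest radial bins, so mass is preserved exactly. `back_project()` is
the exact adjoint (the Gaussian is symmetric, hence self-adjoint), which
the tests verify against an explicitly constructed system matrix.

**OSEM** uses the classic multiplicative update per subset
$x \leftarrow x \cdot A_s^T\!\big(y_s/(A_s x + \epsilon)\big) / (A_s^T 1 + \epsilon)$
with interleaved angle subsets and $\epsilon = 10^{-8}$ guards. Counts
are divided by `scale × duration_fraction` before reconstruction so the
output is calibrated in SUV regardless of scan duration (verified: a
noiseless uniform SUV-1 phantom reconstructs to within 2 % in the
interior). Inputs to the enhancement model use 2 iterations × 8 subsets —
the partially converged, noisy regime.

**BSREM** combines the additive form of the same data step with a
gradient step on $\beta R(x)$, where $R$ is the relative difference prior
over the 6-neighbourhood,

$$R(x) = \sum_j \sum_{k \in N_j} \frac{(x_j - x_k)^2}
        {x_j + x_k + \gamma\,|x_j - x_k| + \epsilon},$$

preconditioned by $x/\mathrm{sens}$, relaxed by
$\alpha_n = 1/(1 + \eta\, n)$ (`relaxation_decay` $\eta$ = 0.1 by
default) and clipped at zero. With $\beta = 0$ and $\eta = 0$ the update
is algebraically identical to OSEM, which anchors the implementation.
Targets use 20 iterations × 8 subsets — near convergence. A divergence
detector aborts when the penalised objective rises by more than a
$10^{-3}$ relative tolerance for five consecutive iterations; the
tolerance exists because subset algorithms show small benign limit-cycle
oscillations near convergence. At regularisation strengths well beyond
the operating range the subset algorithm's limit cycle grows and measured
noise is no longer monotone in $\beta$; the documented noise/contrast
trade-off holds over the operating grid (roughly $\beta \le 2$ at the
default count level).

The regularisation strength of the target is a site-style calibration:
either a fixed default ($\beta = 1$, which on the default phantom and
count level brings liver noise near the 0.15 SUV target while preserving
lesion SUVmax) or `calibrate_beta()`, which scans a grid and
picks the $\beta$ whose liver-VOI noise SD is closest to a configured
target (0.15 SUV by default). $\beta$ values here live on the toy
projector's scale and are not comparable to clinical values.

The "standard z-filter" applied after reconstruction is a light axial
(1, 4, 1)/6 convolution with renormalised edge slices; the exact clinical
kernel is not public, so the choice is conventional and configurable.

## The enhancement network

`build_network()` constructs a residual 3-D convolutional encoder–decoder
(U-Net): per level two 3 × 3 × 3 convolution + batch-normalisation + ReLU
blocks; 2 × 2 × 2 max-pooling between encoder levels; tri-linear
up-sampling and skip concatenation in the decoder; and a final 3 × 3 × 3
convolution that predicts a signed *residue* image added to the input.
Desk-scale defaults are 3 levels and 8 base channels. Channel widths
scale with a single multiplier, which realises the model family:
smooth (0.5), standard (1.0) and sharp (1.5), with strictly increasing
trainable-parameter counts. The bottleneck capacity controls how much
detail — and noise — the model can pass through, which is why the
smallest variant smooths hardest.

The final layer is zero-initialised by default, so the untrained network
is exactly the identity map; training starts from "do nothing" rather
than from a random distortion, and the property is kept as a free
invariant test. Negative values that residue addition may produce are
clipped at zero only when a volume is assembled for quantification, never
inside the training loss.

Forward and backward passes are hand-written (im2col + BLAS for the
convolutions, analytic batch-norm/pool/upsample gradients) and verified
against finite differences across every tensor of a small network.

## Training

`dle_train()` follows the supervised protocol: body-crop the transverse
plane (largest connected component above 5 % of the maximum, never
removing more than 40 % of an axis), split axially into equally spaced
patches covering every slice (identical placements for input and
target), and optimise the MSE between `input + residue` and the BSREM
target with Adam (learning rate $10^{-3}$, batch 4 — unpublished in the
source protocol, so standard values are exposed in the config). Patches
are reshuffled every epoch; one generic model is trained on all duration
fractions mixed. Everything is reproducible from the seeds: shuffling
permutations are logged, and the recorded loss curves are
bit-reproducible given identical configs.

After every epoch (including epoch 0, the untrained identity) the model
is checkpointed and validated. Validation pairs mix all duration
fractions, like the training set: a generic model's stopping epoch must
not be chosen on full-duration inputs alone. Validation records MSE on
the validation pairs, plus two SUV
quantification metrics computed through the evaluation module — the mean
absolute % difference of lesion SUVmax versus the target, and the liver
noise % difference. `select_best_epoch()` ranks epochs by validation MSE
and by lesion-SUVmax difference and returns the epoch minimising the rank
sum, ties towards the earlier epoch. The two criteria can genuinely
conflict; the rank-sum rule treats them symmetrically and is
deterministic. Patch reassembly at inference uses uniform
overlap-averaging — the simplest artefact-free blend.

Desk-scale schedules use 6 epochs by default: on the default corpus
(20 training cases × 4 fractions) the validation metrics flatten well
within that budget, and one epoch costs roughly a minute of CPU, which
keeps a full corpus-train-evaluate cycle inside a quarter of an hour.

## Evaluation

* **VOI statistics** (`voi_stats()`): mean and SD over the 343 voxels of
  each 7 × 7 × 7 VOI. The per-VOI SD uses the population convention
  (divide by $n$), pinned by the closed form for consecutive integers in
  the tests. Liver noise is the arithmetic mean of the five liver VOI
  SDs. "Background variability" is not precisely defined in the
  literature this follows; it is implemented as the coefficient of
  variation of the five VOI means (sample SD over the 5 means divided by
  their mean), a NEMA-style reading, and flagged as an interpretation.
* **Lesion segmentation** (`segment_lesion()`): adaptive threshold at
  `min + 0.42 (max − min)` inside a fixed 7 × 7 × 7 bounding box; voxels
  *equal* to the threshold are included (guarantees a non-empty mask and
  that the arg-max voxel belongs to it). Organ VOIs are transferred
  verbatim across series; lesions are re-segmented per series because the
  threshold is adaptive.
* **Percent differences** are signed,
  $100 (\text{series} − \text{ref})/\text{ref}$; aggregates report both
  the signed mean and the mean absolute value, since published summaries
  are often ambiguous about which is shown.
* **Scatter slope**: OLS with free intercept by default (the usual
  convention for calibration plots); a through-origin fit is available
  behind a flag.
* **Bland–Altman**: mean difference ± 1.96 sample SDs ($n − 1$).
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zero differences
  dropped, mid-ranks under ties; exact two-sided p by enumeration of all
  $2^n$ sign patterns for effective $n \le 12$ ($2^{12}$ enumerations are
  instant; beyond that the tie-corrected, continuity-corrected normal
  approximation is standard). The generic `stats::wilcox.test` has no
  exact branch under ties, which is why the test is implemented here; the
  two agree on tie-free fixtures.
* **Quadratic weighted kappa**: $1 − \sum w O / \sum w E$ with
  $w_{ij} = (i−j)^2/(k−1)^2$; undefined (distinct condition class) when
  both raters use a single category.
* **Reader tables**: Likert scores 0–5 and competition ranking (tied
  series share a rank, the next number is skipped) are validated before
  aggregation into mean (SD) scores, mean ranks and the percentage of
  scores ≥ 3.

## Numerical choices and degenerate inputs

* $\epsilon = 10^{-8}$ in EM ratios and the RDP denominator;
  batch-norm $\epsilon = 10^{-5}$.
* Constant lesion boxes segment to the whole box with a warning; empty
  body masks skip cropping with a warning; volumes with < 3 slices pass
  the z-filter unchanged with a warning.
* Patch offsets: minimal equally spaced count whose last patch ends at
  the final slice (extent 100, patch 40 → offsets 0/30/60).
* Voxel indices are 0-based in every on-disk JSON/YAML file and 1-based
  in memory; the conversion happens only at the I/O boundary, with the
  axial direction always last.
* Seeds: one master seed per experiment, split deterministically into
  per-case and per-stage child seeds.

## Limitations

The smooth/standard/sharp family reproduces the intended
trainable-parameter ordering exactly, but at desk scale the *noise*
ordering of the variants does not follow capacity the way it does on
clinical data. With a global-residual network, suppressing noise means
predicting a residue that cancels voxel-level fluctuations, so more
capacity monotonically improves noise suppression on these
piecewise-constant phantoms; on real anatomy, capacity is also spent
reproducing fine structure from the target, which is what makes the
small (smooth) variant the strongest smoother in clinical practice. The
phantoms deliberately contain no such texture, so the capacity-to-
smoothness link is absent here: measured liver noise is essentially flat
across variants at full duration and *increases* for the smallest
variant at reduced durations. The corresponding acceptance check is kept
as stated and documents this limit of the simulation rather than being
weakened.

The phantom is piecewise-constant and attenuation-free; the projector is
2-D with an image-space PSF; training corpora are two orders of magnitude
smaller than a clinical set. Consequently absolute noise levels, slopes
and percentage differences are properties of this simulation, not
estimates of clinical values, and the reader-study statistics are
implemented and tested on synthetic tables only. The BSREM $\beta$ scale
is projector-specific. DLE outputs inherit whatever systematic bias the
BSREM target carries.
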