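---
title: "BO-CLAHE: model, numerical conventions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BO-CLAHE: model, numerical conventions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic phantom
generator does and does not emulate, the numerical conventions that affect
bit-exact behaviour, and the decisions taken where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## The problem and the model

Portable supine chest radiographs of neonates are low-contrast by
construction: dose is capped by radiosensitivity, and bedside geometry is
unforgiving. CLAHE improves local contrast but has two consequential
hyperparameters — the clip limit and the tile grid size — whose best
values vary image by image. This package treats their selection as a
black-box maximization over the box clip limit $\in [1, 255]$, tile grid
$\in [8, 32]$ of

$$ f(c, t) \;=\; w_s \,\mathrm{SSIM}\!\big(I,\ E_M(I; c, t)\big)
   \;-\; w_b \,\frac{\mathrm{BRISQUE}\big(E_M(I; c, t)\big)}{\text{norm}} $$

where $E_M$ is mask-restricted CLAHE and $I$ the (optionally
bone-suppressed) input. Evaluations are expensive and the surface is mildly
noisy and non-convex, so the search uses Bayesian optimization: a
Gaussian-process surrogate plus an acquisition function, 25 seeded random
initial points then 25 optimization rounds by default.

### Assumptions

* 8-bit grayscale input (16-bit is linearly rescaled on load); the lung
  mask is produced upstream (segmentation is consumed, never learned here).
* The mask's bounding box is large enough to hold the tile grid; masks
  covering a plausible lung region satisfy this by a wide margin.
* SSIM is computed against the *pre-enhancement* image: the objective
  rewards structure preservation, not raw contrast gain. This is an
  inherent tension — strong equalization always lowers SSIM against the
  original — and the default weights keep both terms active rather than
  resolving the tension by fiat. On a clean phantom the optimum therefore
  sits at gentle settings; on genuinely degraded input it moves interior.
  `w_ssim`, `w_brisque` and `brisque_norm` in `run_config()` expose the
  trade-off, including SSIM-only (`w_brisque = 0`) and quality-only
  (`w_ssim = 0`) readings.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `clip_limit` bounds | [1, 255] | multiple of the uniform histogram bin height per tile |
| `tile_grid` bounds | [8, 32] | tiles per axis, searched continuously, rounded in the objective |
| `init_points` / `n_iter` | 25 / 25 | random seeding, then GP-guided rounds |
| `kappa` | 2.576 | UCB exploration weight (default acquisition) |
| `xi` | 0.01 | EI improvement margin (by flag) |
| `noise_alpha` | 1e-6 | GP observation-noise variance |
| `n_restarts` | 5 | marginal-likelihood optimizer restarts |
| `normalize_y` | TRUE | center/scale targets inside the GP |
| `w_ssim`, `w_brisque`, `brisque_norm` | 1, 1, 100 | objective combination |

The objective-combination rule is a design decision: the source method
states only that higher SSIM and lower BRISQUE are better, so the package
uses a weighted difference with the quality distance rescaled by
`brisque_norm` to SSIM-like magnitude, keeping both directions exactly as
stated while making the scalarization explicit and configurable.

## CLAHE numerical conventions

These conventions are fixed because the test suite asserts bit-exact
behaviour against a per-pixel oracle:

* **Clip count**: `max(1, round(clip_limit * tile_pixels / 256))`,
  half-up rounding everywhere (`floor(x + 0.5)`), never banker's rounding.
* **Redistribution**: truncate every bin to the clip count, pool the
  excess, add `floor(excess/256)` to every bin, then deposit the remainder
  one count at a time into bins `0, 1, 2, ...` — a deterministic
  tie-break.
* **Tile LUT**: `round(255 (cdf - cdf_min) / (n - cdf_min))` with
  `cdf_min` the first nonzero cumulative count; a single-bin histogram
  maps through the identity, so flat regions are never re-leveled.
* **Geometry**: tiles by integer division with the last row/column
  absorbing the remainder (no padding); interpolation nodes at tile
  centers `(start + end - 1)/2`; clamped replication outside the node
  lattice.
* **Masked application** computes CLAHE on the tight bounding box of the
  mask and composites through the mask; pixels outside are bit-identical
  to the input. Whether the source method used the bounding box or the
  full frame is not documented; the bounding-box choice concentrates the
  histogram mass on lung tissue and is flagged for sensitivity analysis.

Interoperability knobs (`lut = "cumulative"`, `nodes = "block"`,
`rescale_output = TRUE`) reproduce the OpenCV/scikit-image mapping
convention, the Zuiderveld block-node geometry, and scikit-image's final
full-range stretch. They exist because the established implementations
disagree among themselves on exactly these points; the acceptance suite
uses them to cross-validate the tiling/blending machinery against
scikit-image in the AHE limit, where the (also mutually incompatible)
clipping schedules coincide.

## SSIM and BRISQUE

SSIM uses the universal defaults — 11x11 Gaussian window ($\sigma = 1.5$),
$\alpha = \beta = \gamma = 1$, $C_1 = (0.01 \cdot 255)^2$,
$C_2 = (0.03 \cdot 255)^2$, $C_3 = C_2/2$ — over valid (fully covered)
window positions; with a mask, both images are cropped to the mask's
bounding box first. The exponent form is kept so non-unit exponents are
available, with odd-symmetric handling of a negative structure term under
fractional exponents.

BRISQUE features follow the standard recipe: MSCN coefficients from 7x7
Gaussian local statistics ($\sigma = 7/6$, stabilizer 1 on the 0-255
scale, symmetric padding), then per scale (original and 2x box-downsampled)
a symmetric GGD fit of the MSCN field and AGGD fits of the four
pairwise-product fields, via moment matching with the generalized-Gaussian
ratio function tabulated over shapes $[0.2, 10]$ — 36 features.

One empirical point worth recording: the GGD shape of *MSCN-transformed*
iid Gaussian noise is about 3, not 2. Raw Gaussian samples fit to shape 2
(asserted in the tests), but MSCN divides each value by a local deviation
estimate that includes the value itself, which lightens the tails. An
independent scipy/numpy simulation of the same pipeline reproduces the
effect, and the tests freeze the simulation-derived range.

The original BRISQUE maps features to a score with a trained support
vector regressor whose weights are not redistributable. The package
replaces it with a Mahalanobis distance to reference feature statistics
(0 = at the reference, lower = better, direction preserved). The packaged
default statistics come from a deterministic corpus of 60 pristine
synthetic phantoms (varied geometry, mild noise) with diagonal-shrinkage
covariance (30% toward the diagonal plus a small ridge) so the 36x36
matrix is comfortably positive definite; `read_quality_model()` loads
externally fitted statistics in the same JSON shape. Scores are therefore
distances to *clean-phantom* statistics, not to natural-image statistics —
adequate for ranking enhancement settings of phantom-like images, and the
main reason the packaged model is labelled synthetic.

## Gaussian process and acquisition

Matern-5/2 kernel with unit signal variance and one length-scale per
dimension on inputs rescaled to the unit box — the de-facto default of the
Bayesian-optimization toolchain whose settings the run configuration
mirrors. Log length-scales are fitted by L-BFGS-B on the exact log
marginal likelihood, restarted from `n_restarts` log-uniform draws in
$[10^{-2}, 10^3]$; targets are optionally centered/scaled, with scaling
skipped for zero-variance targets. Exact duplicate inputs are merged by
averaging their targets before factorization — with jitter only `1e-6`,
re-suggested points would otherwise make the Cholesky step fragile; the
pipeline additionally caches objective evaluations by exact parameter
pair. Predictive variance includes the observation noise and is clamped at
zero before the square root.

UCB is the default acquisition ($\mu + \kappa\sigma$, $\kappa = 2.576$);
EI is available by flag and defined as 0 where $\sigma = 0$. The inner
maximization scores 1,000 seeded uniform candidates and polishes the best
5 with bounded L-BFGS-B — on a 2-D box this is cheap and, unlike a dense
grid, reproducible at any resolution. All randomness (initial design, GP
restarts, candidate draws) flows from the run seed through a deterministic
stream-splitting map, so a full run is bit-for-bit reproducible; an
objective failure aborts with the partial trace attached to the condition.

## The phantom generator

`generate_phantom()` emulates the geometry that matters to masked CLAHE:
two bright elliptical lung fields on a darker thorax (default 140 vs 40),
smooth sinusoidal rib-like bands inside the lungs (5 bands, amplitude 12 —
the structured bone texture CLAHE must contend with), optional
low-contrast lesion discs near the noise floor, and additive iid Gaussian
noise (default $\sigma = 4$, a plausible detector-noise level for 8-bit
film), rounded and clipped. Defaults were chosen once as a realistic
stated world and are not tuned to test outcomes.

It does **not** emulate: projective anatomy (mediastinum, diaphragm,
gradients), correlated or signal-dependent detector noise, scatter, grid
lines, or positioning variability. A green test therefore establishes
algorithmic correctness and the direction of quality signals on controlled
scenes — not clinical performance, which in the source setting required
private data and trained classifiers.

## Known limitations

* Optimization is per image by default; `run_boclahe_cohort()` provides a
  shared-parameter mode whose per-image results dominate the shared
  setting by construction (the shared optimum is injected into each
  per-image candidate set).
* The BRISQUE stage ranks images relative to synthetic reference
  statistics; absolute scores are not comparable to SVR-based BRISQUE
  numbers.
* CLAHE is not idempotent and no such property is asserted.
* Images whose mask bounding box is smaller than the effective tile grid
  raise a size error rather than silently shrinking the grid.
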