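# boclahe

Automatic, per-image selection of CLAHE hyperparameters for low-contrast
grayscale radiographs by Gaussian-process Bayesian optimization of a
combined SSIM/BRISQUE image-quality objective, applied inside a lung-region
mask.

## Who this is for

Portable (supine, bedside) chest radiographs — above all neonatal ones,
where radiation dose cannot be raised — are markedly lower in contrast than
standard films, and that hurts both human reading and downstream
classifiers for visually confusable conditions such as transient tachypnea
of the newborn (TTN) versus respiratory distress syndrome (RDS). CLAHE
(contrast limited adaptive histogram equalization) is the standard remedy,
but its two hyperparameters — the clip limit and the tile grid size — are
usually hand-tuned by brute force, and a single global setting is rarely
right for every image. This package selects them automatically, per image.

## The method

For an image `I` with lung mask `M`, the pipeline maximizes

```
f(c, t) = w_s * SSIM(I, CLAHE_M(I; c, t)) - w_b * BRISQUE(CLAHE_M(I; c, t)) / 100
```

over the box `c in [1, 255]` (clip limit, a multiple of the uniform
histogram bin height) and `t in [8, 32]` (tiles per axis, searched
continuously and rounded inside the objective). `CLAHE_M` applies CLAHE to
the bounding box of the mask and composites enhanced values only inside the
mask. SSIM is the standard windowed luminance/contrast/structure product
(11x11 Gaussian window, sigma 1.5, `K1 = 0.01`, `K2 = 0.03`, `L = 255`);
the BRISQUE term is the Mahalanobis distance of the 36 natural-scene-
statistics features (MSCN + pairwise-product AGGD fits at two scales) to
pristine reference statistics, so higher SSIM and lower BRISQUE are both
rewarded.

The search is Bayesian optimization with a Matern-5/2 Gaussian-process
surrogate (inputs scaled to the unit box, observation noise `1e-6`,
normalized targets, 5 restarts of the marginal-likelihood optimizer) and an
upper-confidence-bound acquisition (`kappa = 2.576`; expected improvement
with `xi = 0.01` available by flag): 25 seeded random evaluations followed
by 25 fit/suggest/evaluate rounds, all reproducible from one seed.

Every stage — the CLAHE core (tiling, histogram clipping with excess
redistribution, per-tile equalization LUTs, bilinear blending between tile
centers), SSIM, the BRISQUE feature pipeline, the GP, the acquisition
functions, and a deterministic synthetic chest-phantom generator used for
offline testing — is implemented from scratch in R and verified against
independent oracles (see `tests/testthat/`).

## Worked example

```r
library(boclahe)

phantom <- generate_phantom(lesion_phantom_spec(seed = 42))   # 128x128 synthetic chest
config  <- run_config(init_points = 8L, n_iter = 12L, seed = 42L)
res     <- run_boclahe(phantom$image, phantom$mask, config)
res$report
```

```
BO-CLAHE report: best clip_limit 1.000, tile_grid 8.000
  objective -0.81824 (SSIM 0.76246, BRISQUE distance 158.070)
  20 evaluations, seed 42
```

Read: over 8 random + 12 Bayesian-optimization evaluations the best
parameter pair was the mildest setting in the box (clip limit 1.0, 8 tiles
per axis); at those settings the enhanced lung region keeps SSIM 0.762
against the input and sits 158 Mahalanobis units from pristine-phantom
statistics, for a combined objective of -0.818. Both objective terms
penalize aggressive equalization of an already-clean phantom, so the
optimizer correctly backs off to gentle enhancement — on genuinely
low-contrast inputs the optimum moves into the interior, and the
`w_ssim` / `w_brisque` / `brisque_norm` weights in `run_config()` set the
trade-off (see the methods vignette). Pixels outside the lung mask are
bit-identical to the input. `res$image` is the enhanced image; the full per-iteration
trace (parameters, SSIM, BRISQUE, objective) is in `res$report$trace` and
round-trips through `write_report()` / `read_report()`.

A command-line interface covers the same ground:

```sh
Rscript inst/exec/boclahe phantom  --out data/ --n 5 --seed 1
Rscript inst/exec/boclahe optimize --input img.png --mask mask.png \
    --out enhanced.png --report report.json --seed 1
Rscript inst/exec/boclahe enhance  --input img.png --mask mask.png \
    --clip-limit 2 --tile-grid 8 --out out.png
Rscript inst/exec/boclahe metrics  --ref img.png --test enhanced.png --mask mask.png
Rscript inst/exec/boclahe evalstats overlap predicted.png truth.png
```

## Evaluation utilities

`dice()` / `jaccard()` for mask overlap, `classification_metrics()` for
confusion tables (macro averaging), `auc_roc()` (rank formulation, ties at
half credit), and `anova_oneway()` mirror the reporting conventions used in
studies of this kind.
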