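# levelseg

Variational level-set segmentation of 2-D grayscale images **without
re-initialization**, with interchangeable Gaussian / bilateral edge
indicators and a region-cropped-PSNR evaluation protocol for comparing the
two. Intended for quantitative bioimage analysis at desk scale (cells,
colonies, coins-on-a-table class scenes) and for studying how the choice of
pre-smoothing filter affects edge-based active contours on noisy images.

## The model

The object boundary is carried implicitly as the zero level set of a scalar
field φ (negative inside, positive outside). Evolution minimizes

```
E(φ) = μ Ep(φ) + λ Lg(φ) + ν Ag(φ)

Ep = ∬ ½ (|∇φ| − 1)²  dx dy          (distance regularization)
Lg = ∬ g δε(φ) |∇φ|   dx dy          (geodesic contour length)
Ag = ∬ g Hε(−φ)       dx dy          (weighted inside area, "balloon")
```

by explicit gradient descent

```
φ ← φ + τ [ μ (Δφ − div(∇φ/|∇φ|)) + λ δε(φ) div(g ∇φ/|∇φ|) + ν g δε(φ) ]
```

`Ep` keeps φ an approximate signed distance function (|∇φ| ≈ 1) throughout,
which is what removes the classical periodic re-initialization step. The
edge indicator

```
g = 1 / (1 + |∇ (smooth(I))|²)  ∈ (0, 1]
```

gates all motion: it is ≈ 1 on flat regions and small at intensity edges.
`smooth` is either a Gaussian kernel (σ) or an edge-preserving **bilateral
filter** (spatial width σs, range width σr, normalized by Wp) — swapping the
former for the latter is the comparison this package operationalizes.
δε/Hε are the compact cosine-bump Dirac/Heaviside regularizations
(half-width ε). With the inside-negative convention, ν > 0 shrinks the
contour and ν < 0 inflates it.

## Worked example

```r
library(levelseg)

fx  <- noisy_disk_fixture(noise_sigma = 10, seed = 0)   # 128x128, R = 30 disk
cfg <- run_config(fx$noisy, variant = "gaussian",
                  params      = evolve_params(n_iter = 250),
                  psnr_region = region(c(30, 100), c(80, 110)),
                  reference   = fx$clean, truth = fx$truth)
res <- run_segmentation(cfg)
```

prints (timings omitted; they are hardware facts):

```
PSNR (clean vs smoothed crop): 24.62 dB
mean contour distance: 0.55 px | Hausdorff: 1.37 px
final SDF band deviation: 0.238
contours found: 1 (closed: TRUE)
```

The contour recovered from the noisy image sits about half a pixel from the
true circle, its worst point 1.4 px off, and φ stayed within 0.24 of the
unit-gradient property over 250 iterations with **zero** re-initialization
calls. `compare_models(cfg)` runs both variants with a shared
initialization and emits the paired report (noise-reduction time, edge
extraction time, total, crop PSNR); on this fixture the bilateral variant's
smoothing PSNR is 41.13 dB vs 24.62 dB for the Gaussian — it removes the
noise without blurring the disk edge inside the crop.

A command-line wrapper is in `inst/cli/levelseg`:

```sh
Rscript inst/cli/levelseg compare --iters 250 --noise-sigma 10 --out runs/demo
Rscript inst/cli/levelseg segment --input image.pgm --variant bilateral --out runs/img
```

Inputs are PGM/PPM (NetPBM); outputs are contour CSVs, energy-trace CSVs,
Markdown/CSV reports and PGM contour overlays at the snapshot iterations
{50, 100, 150, 200, 250}.

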