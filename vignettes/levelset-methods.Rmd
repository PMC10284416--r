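---
title: "Methods: distance-regularized level-set segmentation with bilateral edge indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-regularized level-set segmentation with bilateral edge indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(levelseg)
```

## The model and its assumptions

The contour of interest is the zero level set of a scalar field $\varphi$
defined on the pixel grid, **negative inside** the contour and positive
outside. Segmentation is gradient descent on

$$E(\varphi) = \mu E_p(\varphi) + \lambda L_g(\varphi) + \nu A_g(\varphi),$$

with the distance-regularization penalty
$E_p = \iint \tfrac12 (|\nabla\varphi| - 1)^2$, the geodesic length
$L_g = \iint g\,\delta_\varepsilon(\varphi)\,|\nabla\varphi|$, and the
weighted area $A_g = \iint g\,H_\varepsilon(-\varphi)$. The model assumes:

* **edge-based** segmentation: objects are delimited by intensity edges,
  summarized by the indicator $g = 1/(1 + |\nabla(\text{smooth}(I))|^2)$,
  computed **once** from the input image on the 0--255 intensity scale and
  held fixed (no re-estimation schedule exists for this model family);
* a usable initialization that either encloses the objects (shrink,
  $\nu > 0$) or is enclosed by them (inflate, $\nu < 0$);
* that $E_p$ keeps $\varphi$ close to a signed distance function, so the
  classical periodic re-initialization PDE is never called during
  evolution. The package retains that PDE (`reinitialize`) purely as a
  diagnostic/reference operator.

The descent update implemented by `evolve_step` is

$$\varphi \leftarrow \varphi + \tau\Big[\mu\big(\Delta\varphi -
\operatorname{div}(\tfrac{\nabla\varphi}{|\nabla\varphi|})\big) +
\lambda\,\delta_\varepsilon(\varphi)\,
\operatorname{div}\big(g\tfrac{\nabla\varphi}{|\nabla\varphi|}\big) +
\nu\,g\,\delta_\varepsilon(\varphi)\Big].$$

## Parameters

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `mu` | distance-regularization weight | -- | 0.04 | canonical for this model family; `mu * tau <= 1/4` enforced (explicit diffusion stability) |
| `lambda` | length weight (contour tautness, edge attraction) | -- | 5 | canonical |
| `nu` | balloon weight; $>0$ shrinks, $<0$ inflates | -- | 1.5 | canonical; sign convention fixed by inside-negative $\varphi$ |
| `eps` | Dirac/Heaviside half-width | px | 1.5 | compact cosine bump; standard |
| `tau` | explicit time step | -- | 5 | canonical demo value for this model family (see "known limitations") |
| `n_iter` | iterations (no auto-stop) | -- | 250 | mirrors the fixed-schedule evaluation protocol with snapshots at 50,100,...,250 |
| `c0` | binary-step initialization height | -- | 2 | the penalty term repairs the step into an SDF within a few iterations |
| `sigma` | Gaussian smoothing width | px | 1.5 | light denoising preserving mid-scale edges |
| `sigma_s` | bilateral spatial width | px | 1.5 | matched to `sigma` so the variants differ only in the range kernel |
| `sigma_r` | bilateral range width | 8-bit intensity | 30 | ~3x a moderate noise sd; window radius `ceil(3 sigma_s)` everywhere (<0.4% truncated mass) |

## Numerical choices

* **Discretization**: central differences for $\nabla\varphi$ and
  divergences, 5-point Laplacian, explicit Euler, replicate (nearest-edge)
  boundaries; $|\nabla\varphi|$ is regularized as
  $\sqrt{\varphi_x^2+\varphi_y^2+10^{-10}}$. The module-level gradient
  operator (`gradient_magnitude`, also used by the energies and the edge
  indicator) uses one-sided differences at the frame border, which makes it
  exact on affine fields.
* **Regularizations**: $\delta_\varepsilon(x) = \frac{1}{2\varepsilon}(1 +
  \cos\frac{\pi x}{\varepsilon})$ on $|x|\le\varepsilon$ and its integral
  $H_\varepsilon$; $H_\varepsilon$ is clamped to $[0,1]$ against a few-ulp
  sine overshoot at $\pm\varepsilon$.
* **Initialization** is the binary step $\pm c_0$ (`init_binary_step`), not
  an exact distance transform; an analytic SDF constructor
  (`signed_distance_disk`) exists for tests and diagnostics.
* **Re-initialization diagnostic**: Godunov upwind for
  $\partial\varphi/\partial t = \operatorname{sign}(\varphi_0)(1 -
  |\nabla\varphi|)$, with the Russo--Smereka subcell fix at
  interface-adjacent pixels (they relax toward the frozen estimate
  $\varphi_0 / \max|\text{local slope of }\varphi_0|$). Plain Godunov with
  the exact sign displaces the zero contour by $\sim$0.7 px on a $\pm 2$
  binary step through over-correction at diagonal interface pixels; the
  subcell fix is the standard interface-preserving member of the same
  scheme family and leaves the contour in place to measurement precision.
  `sign(0) = 0`, so exact-interface pixels are stationary. Note an exact
  *disk* SDF is a fixed point only at the interface: off-interface pixels
  drift by $O(h\kappa)$ under the discrete Godunov norm (planar SDFs are
  exact fixed points).
* **Contour extraction** is marching squares with linear interpolation via
  `grDevices::contourLines` (base R), wrapped behind the package API;
  accuracy is verified against analytic circles (max radial error < 0.2 px
  at R = 20) and planes (exact to 1e-9).
* **Coordinates**: all geometry (pixel centers, contours, truth boundaries)
  is 1-based (row, col), matching R matrix indexing; `region` objects are
  1-based *inclusive* ranges in the conventional rows-first table notation.
* **PSNR pairing**: reference = clean/original image crop, test = smoothed
  image crop, peak fixed at 255. This measures the fidelity of the
  noise-reduction stage, which is the quantity the paired comparison
  protocol varies. Timings (noise-reduction stage = smoothing + edge
  indicator; edge-extraction stage = evolution + contour tracing) come from
  a monotonic clock and are reported, never asserted.

## The synthetic world

`make_disk_image` / `make_blobs_image` build piecewise-constant scenes
(defaults: intensity 200 objects on background 50, i.e. a 150-unit
contrast typical of well-stained bright objects), and `add_gaussian_noise`
adds clipped i.i.d. Gaussian noise with a fixed seed. The canonical
evaluation fixture (`noisy_disk_fixture`) is a radius-30 disk centered in a
128x128 frame with noise sd 10 (moderate) or 20 (strong). What this world
does **not** emulate: optical blur (object edges are perfect 1-px steps),
intensity inhomogeneity, texture, correlated noise, and multi-scale
structure. A green test on these fixtures therefore establishes numerical
correctness of the operators and the model's behavior under white noise
with ideal step edges -- not performance on natural micrographs.

## Measured behavior and honest limitations

Two protocol-level expectations are *not* met by this model at the default
parameters, and the package reports them rather than hiding them (both
numbers are computed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`):

1. **Per-iteration energy descent.** The total energy decreases in only
   ~76--92% of iterations (seed-dependent) on the noisy-disk fixture, not
   $\ge 95\%$. The shortfall is *independent of the time step* (fractions
   0.867/0.885/0.882/0.889 at $\tau$ = 5/2/1/0.5 with the physical horizon
   fixed), so it is not an instability: the discrete Dirac-band quadrature
   of $L_g$ and $E_p$ ripples with the sub-pixel phase of the moving front
   at ~1--5% of $E$, which exceeds the per-iteration descent once the front
   slows. The *net* energy always falls and segmentation quality is
   unaffected (mean contour error ~0.5 px). `mu * tau <= 1/4` bounds only
   the penalty diffusion; it is not a monotonicity guarantee.
2. **Bilateral variant on strong white noise.** The bilateral range kernel
   anchors on the raw center pixel, so pure-noise regions keep a
   high-frequency residual: at noise sd 10 and `sigma_r` 30 the background
   edge indicator is *lower* (median ~0.32) than the Gaussian variant's
   (~0.52), and its deep local wells pin the front, which does not reach
   the disk within 250 iterations (mean contour error ~20 px; the Gaussian
   variant converges to ~0.5 px). This is a property of the filter, not of
   this implementation -- evolving against the output of an independent
   bilateral implementation (scikit-image) fails identically, and on the
   *zero-noise* fixture the bilateral variant locks onto the razor-sharp
   edge to 1.1 px Hausdorff. Where the bilateral variant *does* deliver is
   fidelity: its smoothing PSNR on an edge-straddling crop beats the
   Gaussian's in 5/5 seeds at noise sd 20 (by ~5 dB), because it denoises
   without blurring the edge.

Further limitations: single-phase segmentation only (one $\varphi$); no
narrow-band acceleration ($O(N)$ full-grid updates per iteration); fixed
iteration count with no convergence test; 8-bit grayscale NetPBM I/O only
(no PNG/TIFF decoder is available in the supported dependency set); the
$O(N w^2)$ bilateral filter is exact, not an approximation, and is meant
for desk-scale images.
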