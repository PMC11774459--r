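---
title: "Sphere-growing refinement of vessel bifurcation landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-growing refinement of vessel bifurcation landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmark)
```

## The problem

Validating a deformable image registration (DIR) needs ground truth:
matched anatomical points in both images whose post-registration
distance — the target registration error (TRE) — can be measured.
In contrast-enhanced abdominal CT the most reliable such points are
blood-vessel bifurcations, but a bifurcation is not a mathematically
sharp location: two readers (or one reader and a registration
algorithm) will place "the" branch point millimetres apart. This
package implements an automated refinement that maps any rough
bifurcation landmark to a reproducible geometric point — the centre of
the locally widest part of the vessel junction — together with the
phantom machinery needed to quantify how precise that refinement is,
and the evaluation utilities that turn refined landmark pairs into TRE
statistics.

Two bifurcation classes are handled differently:

* **Type 1** — branches of similar diameter. Refined automatically by
  the iterative sphere-growing algorithm below.
* **Type 2** — the larger vessel is at least 2.5 times the diameter of
  the smaller one (boundary inclusive, `classify_bifurcation()`).
  Here the widest-point definition is ambiguous, so the landmark is
  defined geometrically instead: the point where the centreline of the
  small vessel crosses the surface of the large one
  (`type2_point()` locates it by bisection on the interpolated mask).

## The sphere-growing model

A landmark is refined on a cubic patch (default 100 mm per side)
extracted around it, resampled to 0.7 mm isotropic voxels and clamped
to the (−160, 240) HU window that isolates contrast-filled vessels
from air and bone. On this patch a per-voxel *opposing force* is
computed:

$$\vec u(X) \;=\; \bigl(1 - \tilde I(X)\bigr)\,
  \frac{\nabla \tilde I(X)}{\lVert\nabla \tilde I(X)\rVert + \epsilon},$$

where $\tilde I$ is the window-normalised intensity in $[0,1]$,
smoothed with a Gaussian of $\sigma = 1$ voxel (the gradient is the
central difference of the smoothed image). Inside a bright vessel
$\tilde I \to 1$ and the force vanishes; at the vessel wall the
gradient points into the lumen, so the force pushes inward. Both
factors use the *smoothed* intensity: with a binary mask substrate the
raw intensity would give exactly zero force on the inside-wall voxels
and a discontinuous braking profile.

A sphere with centre $\vec c$ and radius $r$ (initially $r_0 = 0.5$
voxel at the seed landmark) is then iterated for `n_iter` (default 30)
steps:

$$\vec c_{n+1} = \vec c_n + \lambda_1\,\overline{\vec u(X)},
\qquad
r_{n+1} = r_n + f_{\mathrm{int}} + \lambda_2\,
  \overline{\hat d(X)\cdot\vec u(X)},$$

with $\hat d(X)$ the outward unit direction from the centre to the
sample point. The means are taken over a shell of half-width 1.5
voxels around the sphere surface (three sub-shells, each sampled on a
deterministic spherical Fibonacci lattice of at least
$\max(64, 4\pi r^2)$ directions, forces trilinearly interpolated at
the continuous sample points). A global support set would let distant
anatomy dominate the update and make the displacement-weighted radius
term grow with patch size, so local support is required for the
recurrence to settle at the widest point of the junction. The loop
contains no randomness: identical inputs give bit-identical
trajectories.

### Parameters and why

| parameter | default | units | role |
|---|---|---|---|
| `lambda1` | 0.2 | – | centre-update gain |
| `lambda2` | 0.3 | – | braking gain on the radius |
| `f_int` | 0.18 | voxels/iter | constant outward force |
| `n_iter` | 30 | – | iteration budget |
| `r0` | 0.5 | voxels | initial radius |
| `shell_half_width` | 1.5 | voxels | support-shell half-width |
| `grad_epsilon` | 0.01 | $\tilde I$/voxel | gradient-norm regulariser |
| `intensity_window` | (−160, 240) | HU | vessel contrast window |
| `radius_cap`, `drift_cap` | 25, 15 | voxels | divergence bounds |

$f_{\mathrm{int}}$ deserves comment. Because $\lVert\vec u\rVert \le 1$
by construction, the braking term is bounded by $\lambda_2$: any
$f_{\mathrm{int}} \ge \lambda_2$ can *never* be arrested by the image
force and the sphere grows without bound. The usable range is further
narrowed because only part of the support shell sits in the
high-force band at the wall; empirically (solid-ball phantoms with the
maximal-inscribed-sphere ground truth) values near 0.2 are marginal —
growth occasionally escapes on long runs — while 0.18 is stable and
converges with radius error below 0.6 voxel and centre error below
0.25 voxel. We therefore default to `f_int = 0.18`. It reaches typical
abdominal vessel radii (3–6 resampled voxels) within the 30-iteration
budget; studies that need full centring from seeds several voxels off
the junction should raise `n_iter` (the ball-oracle tests use 150).

`grad_epsilon` is expressed in units of normalised intensity per
voxel: genuine wall gradients are of order 0.1–0.5, so the default
0.01 leaves them essentially unchanged while suppressing the spurious
unit-length forces that exact normalisation would produce in flat or
mildly noisy background.

At the defaults the divergence caps are conservative: 30 iterations of
0.18 voxels can only reach $r \approx 6$, so `radius_cap = 25` acts
only in long runs. Divergence in practice is detected as the centre
leaving the patch, excessive drift from the seed, or — with a
configured tighter cap — unarrested growth.

### The substrate ladder

`refine_landmark()` applies the algorithm on the windowed image. If
growth diverges it is re-run on an automatically generated vessel
mask: the multiscale Hessian (Frangi-type) vesselness of the patch
(`vesselness()`, scales 0.7–2.8 mm, $\alpha = \beta = 0.5$, $\gamma$
half the per-scale maximum Hessian norm), max-normalised, thresholded
at 0.05 and region-grown (26-connected) from the seed. A mask is
treated as a 0/1 image with an identity window and the same recurrence
applies. If that also fails, a user-supplied (manual) segmentation
mask is tried last; if every substrate diverges the landmark is
returned unmoved and flagged. Each refined landmark records which
substrate produced it.

The vesselness parameters are conventional defaults; the source
describing the refinement workflow does not state scales, thresholds
or connectivity, so all are exposed in `vesselness_config()`.

## The digital phantom engine

Refinement precision is estimated on deformed copies of an image with
an exactly known point map. A `phantom_transform` composes, in order:
rotation about a random axis (angle 0–50°), global scaling within
±10% (both about the patch-centre pivot), then a per-axis sinusoidal
displacement $p' = p_a + A\sin(2\pi p_a/P + \phi)$. Sampling defaults:
amplitude uniform on [0, 5] mm, period on [60, 120] mm, phase on
[0, 2π). The per-axis bound $|2\pi A/P| < 0.9$ keeps the sinusoid a
contraction, so the warp is invertible and
`map_point_inverse()` converges by fixed-point iteration (tolerance
10⁻⁶ mm; the affine part is inverted exactly). Images are warped
backward — output voxel $q$ reads the input at $T^{-1}(q)$ with
trilinear interpolation — so the forward point map used as ground
truth is exact by construction, not estimated from a grid.

The sinusoid parameterisation (per-axis amplitude/period/phase) is a
design choice: it is the simplest smooth, exactly invertible field
with tunable wavelength; amplitudes up to 5 mm over ≥60 mm periods
produce local strains up to ~50%, comparable to severe abdominal
deformation, while remaining well inside the invertibility bound.

### The synthetic vessel generator

`make_vessel_phantom()` rasterises bright tube segments (default
300 HU, clipped to the window ceiling) on an air background
(−1000 HU) with a one-voxel soft wall, plus optional Gaussian noise,
and emits the junction points as typed ground-truth landmarks;
`yjunction_phantom_spec()` builds a single Y-junction. The generator
emulates what matters to the refinement — tube geometry, junction
widening, CT-like contrast after windowing — and deliberately not
what it cannot know: real CECT texture, partial-volume and streak
artifacts, neighbouring organs, contrast-phase variation, or
anatomically curved vessels. Passing the phantom studies therefore
demonstrates the *geometric* consistency of the refinement under
known deformation; it does not certify performance on clinical
images, which in the source workflow is where the vesselness and
manual-mask fallbacks earn their keep.

### Desk-scale study sizes

The packaged phantom study uses 50 random Y-junctions (trunk radius
2.5–3.5 mm, branch radii 2.2–3.5 mm, random branch angles), rendered
at 1 mm spacing, refined on 40 mm patches resampled to 0.7 mm — sizes
chosen so the full study runs in about a minute on a laptop while the
junction geometry is still resolved by several voxels. The ball-oracle
study uses 20 balls of radius 3–8 voxels in 25³ volumes. Larger
patches (the 100 mm refinement default and the 200 mm phantom-study
patches of the source workflow) change nothing algorithmic: growth is
local to the junction.

## Evaluation utilities

`project_landmarks_through_dvf()` maps image-1 landmarks through a
displacement field (mm, sampled at image-1 world coordinates —
the convention of projecting labelled landmarks into the second
image); any registration's DVF can be supplied as NIfTI.
`landmark_errors()` gives per-pair 3-D distances;
`summarize_errors()` reports mean ± sample standard deviation
(n − 1 denominator — the convention for small-sample error reporting)
with an opt-in hard outlier cutoff (the 5 mm rule used to separate
gross failures); `paired_t_test()` compares two methods on matched
landmarks (two-sided, n − 1 df). `evaluate_dir()` composes these into
the dataset's intended TRE use.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere for intensities; nearest
  neighbour for masks. Trilinear reproduces degree-1 fields exactly,
  which the tests exploit as closed-form oracles.
* Indices are 0-based and continuous; `world = O·S·index + origin`
  with the NIfTI sform affine taken as-is. Round trips are exact to
  1e-9 mm.
* Patches have odd voxel counts so the requested centre is a grid
  point; out-of-bounds voxels are filled with −1000 HU (air — neutral
  under the window floor).
* Resampling preserves the world extent to within one voxel; volumes
  with a single slice on any axis are rejected rather than
  extrapolated.
* Shell radii are clamped to ≥ 0.25 voxel in early iterations;
  sample points falling outside the patch are dropped, and an empty
  support set is a divergence (`left_patch`).
* The windowing, patch extraction and summarisation operations are
  idempotent; `hu_window` rejects inverted windows, `summarize_errors`
  refuses an all-excluded set, and the paired test refuses
  zero-variance differences rather than returning NaN.

## Known limitations

* The refinement assumes bright vessels on a darker background; it
  has no model of touching parallel vessels or of junctions at the
  patch border beyond divergence detection and the mask fallbacks.
* The automatic mask depends on a single global vesselness threshold;
  very thin (< 1 voxel) branches are flagged by the generator as
  under-resolved rather than refined.
* The phantom engine's deformations are smooth and globally
  invertible; sliding interfaces and topology changes present in real
  abdominal motion are out of scope.
* Inter-observer numbers reported for the real dataset depend on
  human readers and the original images and are not reproduced here;
  the packaged studies quantify algorithmic precision only.
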