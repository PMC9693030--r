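---
title: "Regional lung biomechanics from displacement fields: models, phantoms and method choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung biomechanics from displacement fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmech)
```

## The problem

Paired breath-hold CT scans of the lung — one near full expiration (residual
volume, RV) and one near full inspiration (total lung capacity, TLC) — can be
related by a deformable registration that assigns every expiration-grid voxel
a displacement $u(x)$ into the inspiration image. The spatial derivatives of
that correspondence carry regional mechanics: where the lung inflates
strongly, locally isotropically or preferentially along one direction, and
how those patterns change with obstructive disease severity. `lungmech`
computes these maps, scores how trustworthy the underlying registration is,
and aggregates both across lobes and cohorts.

## The biomechanical model

Let $\varphi(x) = x + u(x)$ be the transform from the fixed (expiration) grid
into the moving (inspiration) image and $F = I + \nabla u$ its deformation
gradient. The right Cauchy–Green tensor $F^T F$ has eigenvalues
$\lambda_1^2 \ge \lambda_2^2 \ge \lambda_3^2$; the $\lambda_i$ are the
principal stretches. Three scalar maps follow:

* **Jacobian determinant** $J = \lambda_1 \lambda_2 \lambda_3$: local volume
  change; $J > 1$ is expansion, $J < 1$ contraction.
* **Anisotropic deformation index**
  $\mathrm{ADI} = \sqrt{\left(\frac{\lambda_1 - \lambda_2}{\lambda_2}\right)^2
  + \left(\frac{\lambda_2 - \lambda_3}{\lambda_3}\right)^2}$: magnitude of
  direction dependence; zero iff the stretch is isotropic.
* **Slab–rod index**
  $\mathrm{SRI} = \frac{2}{\pi}\arctan\!\frac{\lambda_3(\lambda_1 - \lambda_2)}
  {\lambda_2(\lambda_2 - \lambda_3)} \in [0, 1]$: the *character* of the
  anisotropy — 0 when stretch happens along two directions (slab-like,
  $\lambda_1 = \lambda_2 > \lambda_3$), 1 when along one (rod-like,
  $\lambda_1 > \lambda_2 = \lambda_3$). SRI is undefined when ADI $= 0$.

The shape coordinates $\alpha = \mathrm{sign}(J-1)(\lambda_2/\lambda_3 - 1)$
and $\beta = \mathrm{sign}(J-1)(\lambda_1/\lambda_2 - 1)$ place each voxel in
a polar-like diagram with ADI as radius and SRI as angle; both ratios are
nonnegative by the eigenvalue ordering, so $\alpha$ and $\beta$ share the
sign of $J - 1$. Two typographically plausible readings of the $\alpha/\beta$
definition exist (ratio vs product of eigenvalue pairs); the ratio reading is
implemented because it is the one under which the parenthesised factors are
always nonnegative, which the polar interpretation requires.

```{r maps-example}
dvf <- make_affine_dvf(diag(c(1.4, 1.2, 0.9)), shape = c(12, 12, 12))
maps <- biomech_maps(dvf)
c(J = maps$J$data[6, 6, 6], ADI = maps$ADI$data[6, 6, 6],
  SRI = maps$SRI$data[6, 6, 6])
```

### Direction convention

Published descriptions of such maps are ambiguous about whether $F$ derives
from the inspiration-to-expiration or expiration-to-inspiration map, while
reported "expansion" maps show $J > 1$. `lungmech` does not guess: it
computes maps from whatever field it is given and records the convention in
the `direction` tag carried by every `lm_dvf` and written to output
sidecars. The phantom generator and cohort pipeline use the
expiration-to-inspiration direction, so healthy inflation gives $J > 1$.

### Numerical choices

* $\nabla u$ uses spacing-aware central differences at interior voxels
  (second-order accurate; the convergence test verifies the ~4x error drop
  per grid halving) and one-sided differences on the one-voxel boundary
  shell. Regional statistics exclude that shell (`interior_mask()`) to avoid
  first-order boundary bias.
* Per-voxel eigenvalues of $F^T F$ come from the closed-form trigonometric
  solution for symmetric 3x3 matrices, vectorized over the volume. When the
  eigenvalue spread is at rounding level (below $10^{-12}$ relative to the
  tensor scale) the voxel is snapped to exact isotropy so ADI is exactly
  zero and SRI is masked rather than numerically random.
* At $\lambda_2 = \lambda_3$ with $\lambda_1 > \lambda_2$ the SRI quotient
  diverges; `atan2` resolves it to the limit value 1 (rod), matching the
  geometry of the polar diagram.
* Eigenvalues below $10^{-12}$ are floored and the voxel marked invalid, as
  are voxels with $\det F \le 0$ or non-finite entries; invalid voxels are
  `NA` in every map and excluded from summaries.

## The synthetic phantom

Real cohort data of this kind is access-restricted, so the package ships a
generator that produces everything the pipeline consumes with known ground
truth:

* **Geometry** — two disjoint ellipsoidal lungs; the right is split by two
  oblique planes into three lobes and the left by one plane into two
  (labels 1–5 = RUL, RML, RLL, LUL, LLL). A three-generation binary
  branching tube tree per lung (radius decay 0.7, branch angles 25–50
  degrees drawn deterministically from the seed) provides vessels with
  enough scale diversity to exercise the multiscale vesselness filter.
* **Deformations** — affine and single-axis sinusoidal fields have
  closed-form deformation gradients and Jacobians for exactness and
  convergence tests; cohort subjects get a radial expansion about the
  thoracic centre modulated by a low-frequency sinusoid, giving smooth,
  invertible fields with spatially heterogeneous $J$.
* **Images** — the expiration tissue-fraction image takes fixed values per
  region (parenchyma 0.2, vessels 1.0, soft tissue 1.0 — arbitrary but
  fixed, chosen so the intensity and vesselness terms have contrast to
  drive registration). The inspiration image carries that fraction through
  the deformation divided by the local Jacobian, so total lung tissue
  volume is conserved: this is exactly the intensity model under which the
  tissue-volume registration cost is zero at the true transform. HU values
  follow the linear air/tissue mixture HU $= -1000 + f \cdot 1055$, the
  same mixture `hu_to_density()` inverts (no published HU-to-density rule
  accompanies the cost definition, so the pipeline states one and uses it
  consistently on both sides).
* **Cohorts** — stage $s$ subjects draw their lung-mean $J$ target from
  Normal(stage mean, noise SD); defaults are five stage means
  (1.8, 1.6, 1.4, 1.2, 1.05) with noise SD 0.05, a strictly decreasing
  expansion trend of plausible magnitude for increasing obstruction
  severity.

The inverse map needed to synthesize the inspiration image is computed by
fixed-point iteration ($x \leftarrow y - u(x)$, tolerance $10^{-3}$ voxels,
at most 50 iterations), which converges for the contraction-mapping fields
the generator produces.

What the phantom does *not* emulate: CT texture and noise, airway trees,
fissures as thin structures, sliding at the pleura, or anatomically
realistic lobe shapes. Tests passing on the phantom therefore demonstrate
the correctness of the *computations* (maps, metrics, optimization) under
known truth — not registration performance on clinical images.

## Registration quality metrics

Four complementary measures compare fixed structures against (warped)
moving structures:

* **LDC** — mean Dice overlap of the five lobes.
* **W10SE** — for each vertex of one lung surface, the exact distance to the
  other surface (closest point may lie inside a triangle face); the mean of
  the largest `ceil(0.1 N)` distances, averaged over both directions. The
  ceiling rule is a stated choice; no rounding convention is standard.
* **VTPE** — symmetric mean closest-point distance between vessel masks.
* **SCSE** — the same between vessel-tree curve skeletons.

Surfaces come from marching tetrahedra on the binary mask after a Gaussian
pre-smoothing of 0.65 voxels. The smoothing trades two opposing biases: the
raw binary iso-surface overestimates area (staircase effect, +28% on a
10 mm sphere at 1 mm spacing) while heavy smoothing rounds corners and
undershoots on polyhedral shapes; 0.65 voxels keeps both a voxelized sphere
and an axis-aligned box within 10% of their analytic areas. Vertex density
is a consequence of the mesher; since the worst-10% statistic depends on
vertex sampling, the smoothing parameter is exposed.

Skeletons come from six-subiteration border thinning deleting *simple*
points (one 26-connected foreground component in the 26-neighbourhood, one
6-connected background component in the 18-neighbourhood) that are not
curve endpoints; deletion of simple points provably preserves topology, and
the tests verify component counts and branch endpoints on tube phantoms.
Point-set and point-to-mesh distances are computed exactly in compiled code
and are verified against brute-force oracles to $10^{-9}$.

## Tissue-volume-preserving registration

The internal registration engine minimizes

$$C = \gamma_1\,\overline{(I_f(x) - |J_\varphi(x)|\, I_m(\varphi(x)))^2}
    + \gamma_2\,\overline{(F_v(x) - M_v(\varphi(x)))^2}
    + \gamma_3\,\overline{\|L u(x)\|^2}$$

over a cubic-B-spline-parameterized displacement field, where $I_f, I_m$
are tissue-density images, $F_v, M_v$ vesselness images, and
$L = -0.75\nabla^2 - 0.25\nabla(\nabla\cdot)$ the linear elasticity
operator. The Jacobian factor makes the first term compare tissue *volume*
rather than intensity — the physical assumption that lung tissue mass is
conserved over the breathing cycle while air content is not. $|J_\varphi|$
is computed analytically from the B-spline basis derivatives, not by finite
differences. Means are per-voxel over the evaluation region (the fixed lung
mask dilated by 2 voxels), a normalization choice the cost definition
leaves open.

Choices worth knowing:

* **Schedule** — three levels at 1/4, 1/2 and full resolution with knot
  spacings 8, 8 and 4 mm, iteration caps 60/40/30. This desk-scale schedule
  preserves the coarse-to-fine structure of full-scale six-level setups
  while remaining tractable at $64^3$; any schedule can be passed through
  `reg_config()`.
* **Weights** — $\gamma_1 = \gamma_2 = 1$; $\gamma_3 = 0.05$ by default.
  The regularization weight has no published value; 0.05 keeps phantom
  recovery sub-voxel while preventing folding.
* **Optimizer** — gradient descent with Armijo backtracking on the exact
  cost and the analytic gradient (including the cofactor term from
  differentiating $J$); accepted-cost traces are monotone non-increasing by
  construction, which the tests assert. The analytic gradient is verified
  against finite differences.
* **Folding** — $J \le 0$ voxels are counted and reported (with a warning
  above 10% of the mask), not hard-prevented: small-deformation B-spline
  models cannot guarantee a diffeomorphism, and silent projection would
  mask the diagnostic.
* **Level transfer** — the previous level's dense field is refit to the new
  lattice by separable regularized least squares, which is exact for fields
  the new lattice can represent.

On the standard test pair (a $64^3$ phantom with a 5-voxel-peak smooth
deformation) the engine recovers the field to a mean error of ~0.8 mm
inside the lung and improves all four QA metrics over identity alignment;
`scripts/acceptance.R` recomputes these numbers end to end.

## Cohort statistics

Per subject and region (whole lung + five lobes) the pipeline reports the
mean, SD, RMS and Shannon entropy of $J$, the mean ADI and the entropy of
SRI. Entropy uses 64 uniform bins over fixed ranges ($J$: [0, 4] clipped,
SRI: [0, 1]); fixed ranges make entropies comparable across subjects, and a
constant map has entropy exactly 0. (Some texts refer interchangeably to
the "energy" of SRI; the entropy of the fixed-bin histogram is what is
implemented.) SDs use the $n-1$ denominator throughout.

Stage trends are reported as per-stage group means with a strict
monotonicity flag plus the Spearman rank correlation between stage and
subject values as an effect size — a descriptive report, deliberately
without a significance test, since trend direction rather than inference is
the question the summary answers. Method agreement uses Bland–Altman
limits mean $\pm\,1.96$ SD of the paired differences; the Monte-Carlo test
confirms the limits capture ~95% of Gaussian differences. Subjects whose
processing fails are excluded with a recorded reason and the analysis
continues.

```{r cohort-example}
co <- make_cohort(2, c(1.6, 1.2), noise_sd = 0.02, seed = 3,
                  shape = c(48, 48, 48), images = FALSE)
res <- cohort_run(co, methods = "oracle")
res$trends[["oracle.J_mean"]][c("group_means", "direction")]
```

## Problem sizes and runtime

The shipped tests and the acceptance script run at deliberately small
scale: analytic checks at $12^3$–$41 \times 9 \times 9$, geometry oracles
on instances below 5000 elements, registration and the image-level cohort
at $64^3$ with 2 stages x 2 subjects, and trend power at summary scale
(100 simulated cohorts of 5 x 10 subjects). These sizes were chosen so the
whole pipeline executes in minutes on one CPU while still exercising every
code path at clinically shaped (if miniature) geometry.

## Known limitations

* The registration engine is desk-scale: it is the same cost and transform
  family as production tissue-volume registration but is not tuned or
  sized for 512^3 clinical volumes.
* Only axis-aligned grids are supported; NIfTI orientation matrices beyond
  spacing are not interpreted.
* The vesselness functional is a standard Hessian-based tubularness; its
  absolute response is arbitrary and only relative values are used.
* Large-deformation (diffeomorphic flow) registration engines are out of
  scope; externally produced displacement fields can be ingested through
  `read_dvf()` and analyzed identically.
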