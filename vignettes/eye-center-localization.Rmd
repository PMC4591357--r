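---
title: "Hybrid eye-center localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid eye-center localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyecenter)
```

## The problem and the model

Accurate iris/eye-center localization from a plain camera image underpins
gaze estimation, driver monitoring, and facial-expression analysis. Two
families of estimators have complementary failure modes:

* **Unsupervised isophote voting** exploits the circularity of the
  iris/pupil boundary. An isophote is a curve of constant luminance; at a
  pixel with luminance derivatives $L_x, L_y, L_{xx}, L_{xy}, L_{yy}$ its
  curvature is
  $$k = -\frac{L_y^2 L_{xx} - 2 L_x L_{xy} L_y + L_x^2 L_{yy}}
              {(L_x^2 + L_y^2)^{3/2}},$$
  the reciprocal of the osculating-circle radius. Each pixel casts a vote
  at the center of that circle, displaced from itself by
  $$\{D_x, D_y\} = -\{L_x, L_y\}\,
      \frac{L_x^2 + L_y^2}{L_y^2 L_{xx} - 2 L_x L_{xy} L_y + L_x^2 L_{yy}},$$
  with weight equal to the curvedness
  $\sqrt{L_{xx}^2 + 2L_{xy}^2 + L_{yy}^2}$. The maximum of the resulting
  accumulator — the maximum isocenter (MIC) — is pixel-accurate on clean
  eyes but is lured away by eyebrows, eyelids and glints.
* **Regression-based face alignment** places a full landmark shape using
  global facial appearance, so it is robust to local eye-region nuisances,
  but its per-landmark accuracy is limited.

The hybrid combines them: a two-level cascade of random ferns aligns the
face; five differently smoothed center maps per eye region each contribute
their two strongest, separation-constrained isocenters (up to ten
candidates); the eye center is then *reconstructed* from the aligned
landmarks as an affine-invariant linear combination of its neighbors,
$m' = M'\omega$ with $\sum_i \omega_i = 1$, and the candidate nearest $m'$
is the final estimate — the alignment acts as a constraint while the
unsupervised votes retain their accuracy.

### Fern cascade

Training minimizes $\sum_i \lVert \hat S_i - (S_i^{t-1} + R^t(I_i,
S_i^{t-1})) \rVert$ stage by stage, $S^t = S^{t-1} + R^t(I, S^{t-1})$.
Each of the $T$ stages freezes its appearance: $P$ pixels are sampled at
shape-indexed positions (offset from the nearest landmark, carried through
the per-sample similarity transform from the mean shape), and each of $K$
ferns picks $F$ pixel-difference features from the implicit $P^2$ pool by
maximal absolute correlation with a random projection of the current
residuals. A fern splits the data into $2^F$ threshold bins; a bin's
output is the shrunken mean residual
$$\delta S_b = \frac{1}{1 + \beta/|\Omega_b|}
  \cdot \frac{\sum_{i \in \Omega_b} (\hat S_i - S_i)}{|\Omega_b|},$$
so a single-sample bin with $\beta = 1000$ contributes exactly
$\text{residual}/1001$. Residuals and fern outputs live in the
similarity-normalized frame, which is what makes the learned increments
transfer across face scale and in-plane rotation. Prediction runs five
initializations (mean shape in the face box, plus four perturbed copies at
±5% of box size) and averages the per-landmark results.

### Evaluation metric

For true centers at inter-ocular distance $\omega$ and per-eye errors
$d_{left}, d_{right}$, the normalized error is reported under three
conventions: worst-eye $\max(d_l, d_r)/\omega$ (primary), best-eye and
average; $e \le 0.05$ roughly corresponds to pupil diameter, $0.10$ to
iris diameter, $0.25$ to eye width. A summed variant
$(d_l + d_r)/\omega$ is kept as `e_sum` for auditability, because the
printed formula of the source metric reads as a sum while its prose
describes the worst-eye convention; the prose convention (the standard
Jesorsky score) is primary here.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| cascade `T`, `K`, `P`, `F`, `beta` | 10, 500, 300, 5, 1000 | — | full-scale settings of the underlying regression method |
| scale bank `sigmas` | (1, 1.5, 2.25, 3.4, 5.1) × w/60 | px | geometric ladder spanning fine-to-coarse smoothing; never published, chosen once and made configurable |
| MIC `min_separation` | 21 × w/60 | px | two near-coincident maxima describe one isocenter; 21 px was tuned at a reference eye-region width of 60 px, so it is rescaled by region width (`separation_mode = "fixed"` reproduces absolute pixels) |
| map blur `blur_size` | (6, 6) × w/60 | px | mean filter beats a Gaussian here; size is scale-dependent, so it is rescaled likewise |
| `r_bounds_frac` | (0.05, 0.5) | fraction of region width | accepted displacement radii; brackets plausible iris radii at any region size |
| eye-region margin | 0.4, min aspect 0.8 | fraction of landmark span | the crop is not specified by the method; the margin keeps the full iris plus some sclera inside while excluding most of the brow |
| `tie_tol` in candidate selection | 1 | px | candidates live on integer accumulator cells; distance differences below one cell carry no information, so ties within a cell resolve by vote response (the MIC ordering) |
| prediction perturbation | 0.05 | fraction of box | magnitude of the four extra initializations (unstated in the source; small enough to stay in the cascade's basin) |

## Synthetic fixtures: what they emulate and what they do not

`render_eye()` draws an anti-aliased bright sclera / dark iris / darker
pupil with optional upper-lid occlusion, glint, eyebrow-like bars and
Gaussian noise; `render_face()` renders a 29-landmark schematic face
(brows, eye contours with explicit eye centers, nose, mouth, jaw) whose
features are deterministic functions of the landmark ground truth, under
translation, scale, in-plane rotation and a horizontal shear that stands
in for yaw. Both are pure functions of spec + seed.

Training draws 60 faces with scale 0.85–1.15, rotation ±0.12 rad, shear
±0.15, translation sd 3 px, landmark jitter 0.5 px, image noise sd 0.02
and eyelid coverage 0–0.5 — moderate frontal-to-near-profile variation
with the eye-appearance diversity a real training set would contain. The
planted-distractor regime used in the robustness experiments adds hooded,
thickened brows with dark rounded heads (`brow_strength = 2`,
`brow_drop = 0.06`, `brow_blob = 1.3`) over partially occluded eyes
(coverage 0.2–0.5): a dark *circular* structure is what genuinely competes
with a partially occluded iris for the maximum isocenter — a straight bar
alone cannot outvote a full circle — and this is exactly the regime in
which the plain MIC estimator chases the brow while the shape-constrained
selection stays on the iris.

What the fixtures do **not** model: photometric complexity (shadows,
specular glasses, makeup), out-of-plane rotation beyond shear, inter-face
appearance variation, and sensor artifacts. Passing the desk-scale
experiments therefore demonstrates the *mechanics* of the method — exact
isophote algebra, candidate recall, cascade convergence, affine-invariant
selection and their interaction — not benchmark-level performance on
natural images, which requires the external datasets the `evaluate`
path accepts.

## Numerical and design choices

* **Derivatives.** Central differences on the Gaussian-smoothed image,
  exact for quadratic luminance (the analytic oracle
  $L = x^2 + y^2 \Rightarrow D = (-x, -y)$, $|k| = 1/r$ is exact to
  machine precision). A Sobel operator is an equally standard choice for
  the first-order terms; central differences were chosen because they are
  the easiest to verify against closed forms.
* **Curvedness formula.** The standard curvedness
  $\sqrt{L_{xx}^2 + 2L_{xy}^2 + L_{yy}^2}$ is implemented. A printed form
  of this expression elsewhere nests the exponents ambiguously
  ($2L_{xy}^2 L_{yy}^2$ under the root); that reading is dimensionally
  inconsistent as a weight and is documented here rather than silently
  adopted.
* **Vote gating.** Only pixels whose curvature sign indicates a darker
  interior vote (iris darker than sclera), displacement magnitudes are
  clipped to `r_bounds`, targets round to the nearest cell (no bilinear
  splatting), and the outermost 1-px ring does not vote.
* **Validity tolerances.** Displacements are invalid where the shared
  denominator magnitude falls below $10^{-8} \times$ (dynamic range)$^2$;
  curvature where the gradient magnitude falls below
  $10^{-6} \times$ dynamic range. A flat image is entirely invalid and an
  empty map is a value, not an error, until a maximum is requested.
* **Map blur.** The (6, 6) mean filter is applied in scatter (adjoint)
  form with reflected borders: each vote's mass spreads uniformly over its
  neighborhood and out-of-image mass folds back. This conserves total vote
  mass exactly and equals the ordinary box average in the interior; for an
  even kernel no border handling can simultaneously preserve constants and
  conserve mass, and for an accumulator conservation is the meaningful
  invariant. The even kernel's anchor convention (spread offsets −3…+2) is
  fixed for bit-reproducibility.
* **Residual convention.** Increments move the current shape toward the
  truth ($\hat S - S$); the opposite sign appears once in the source
  material's bin-objective notation and is treated as notational.
* **Augmentation.** Every one of the 20 initial shapes of a training
  sample is borrowed from a *different* sample (aligned into the target's
  box). Including the sample's own true shape as an initialization would
  inject zero-residual instances that teach nothing and dilute the error
  trace.
* **Desk-scale shrinkage.** The full-scale default $\beta = 1000$ is
  calibrated to training sets whose fern bins hold hundreds of members. At
  the desk scale used throughout the tests (60 faces × 20 inits = 1200
  instances, bins of ~40) it over-shrinks fern outputs to ~4% of the bin
  mean; the desk-scale runs therefore use $\beta = 250$, which improves
  both the training-error reduction and the held-out error — i.e. it is
  the better-calibrated regularizer at this data size, not a looser one.
* **MIC-only baseline.** The single-scale comparison baseline runs at the
  scale bank's *base* kernel: the plain MIC method is the single-kernel
  estimator of which the bank is the multi-scale extension, so the base
  kernel is its natural operating point.
* **Tracking.** Frame $n$ seeds its face box from frame $n-1$'s landmark
  bounding box with zero margin by default: the cascade is trained against
  landmark bounding boxes, and any fixed inflation compounds
  multiplicatively across frames (a 5% margin grows the box ~40% in seven
  frames and collapses the alignment). Recovery re-runs detection; a
  configurable window of consecutive failures raises a tracking-lost
  error.
* **Degenerate inputs.** Eye regions below 16 px, shapes with zero
  extent, boxes outside the image, empty maps queried for a maximum, and
  coincident true eye centers all raise early, specific errors; a
  rank-deficient AISC neighbor configuration falls back to a
  ridge-regularized solve with a warning.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
200 eye patches for MIC recall, 200 for candidate recall, a cascade
trained on 60 faces (T = 5, K = 50, P = 100, 20 inits), 20 held-out faces,
200 planted-distractor trials against the MIC-only baseline, and a
10-frame tracking sequence — a few minutes end to end on one CPU. The
full-scale defaults (T = 10, K = 500, P = 300) are intended for real
training sets supplied through the CLI.

## Known limitations

* The default face detector is a brightness-blob heuristic adequate only
  for the schematic fixtures; real images need an external detector bound
  to the plugin interface (any function `image -> box`).
* Candidates carry integer accumulator coordinates; there is no sub-pixel
  refinement (mean-shift or learned post-processing is deliberately out of
  scope).
* The 29-point scheme is this package's synthetic stand-in; real
  annotation schemes plug in via `ec_scheme_*` structures with the same
  fields.
* Left/right eye weights are fitted independently; no cross-eye symmetry
  or asymmetry validation is attempted.
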