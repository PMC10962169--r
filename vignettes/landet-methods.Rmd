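---
title: "Landmark-as-object detection of spinopelvic measures: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-as-object detection of spinopelvic measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the geometric
model of the five spinopelvic measures, the landmark-as-object detection
formulation, the multi-task loss with physics-informed constraints, the
synthetic-radiograph generator, and the design decisions taken where more
than one defensible choice existed.

## 1. Geometry and sign conventions

All geometry lives in raster image coordinates: origin top-left, x to the
right, y **downward**, so "superior" means smaller y. A `facing` sign
(+1 when the patient's anterior side points towards +x) is inferred from
the S1 corner order, and every signed angle is computed in the
facing-corrected (anterior, superior) frame, so left- and right-facing
radiographs yield identical measures and the horizontal-flip augmentation
is label-consistent.

The polarity of endplate inclinations deserves a note, because it is the
one place where two plausible conventions conflict. We define
`signed_inclination()` as **positive when the endplate descends
anteriorly** (anterior corner inferior). This is the physiologic
orientation of the S1 superior endplate — the sacral plateau faces
anterosuperiorly — and, crucially, it is the polarity under which the
classic morphologic identity

$$\mathrm{PI} = \mathrm{PT} + \mathrm{SS}$$

holds *exactly* as a signed identity together with the usual pelvic-tilt
sign (positive when the S1 midpoint lies posterior to the hip axis).
One can verify in closed form that the opposite inclination polarity
(positive-when-anterior-superior) combined with posterior-positive PT
makes the geometric angle between the endplate perpendicular and the
midpoint-to-hip-axis line equal $|\mathrm{SS}-\mathrm{PT}|$, which
contradicts the identity; we therefore fixed the polarity from the
identity, which is the anatomically meaningful invariant.

Pelvic incidence is computed from two signed angles measured against the
vertical: the direction of the S1-midpoint→hip-axis line, and the
direction of the endplate perpendicular oriented to the inferior side of
the plate. Their difference equals PT + SS for *any* landmark
configuration, including configurations beyond 90°, and is invariant
under rigid rotation of the whole landmark set (while SS and PT each
change by exactly the rotation angle). `compute_measures()` checks the
identity to a configurable tolerance (default 0.5°) and warns on
violation — with noisy predicted landmarks this flags internally
inconsistent sets.

Degenerate inputs: coincident endplate corners and an S1 midpoint
coinciding with the hip axis raise errors; missing landmarks make only
the measures that need them `NA` (with `strict = TRUE`, an error naming
the first absent class). Gross misdetections that horizontally swap the
two S1 corners flip the inferred facing and hence the signs of SS/PT/PI;
such frames are counted at face value in the evaluation statistics, which
makes MAE on small test sets sensitive to single catastrophic frames
(see §6).

## 2. Labels: landmarks as objects

Each landmark becomes a square box centred on it: 5% of the maximum image
dimension for the eight spine-corner classes, the fitted head diameter
for the femoral heads (the head centre and radius come from a three-point
circumcircle fit, `circumcircle()`). All coordinates are normalised by
`max(width, height)`. The class order is fixed: fh1, fh2, s1_post,
s1_ant, l5_post, l5_ant, l1_post, l1_ant, c7_post, c7_ant, with the two
femoral heads disambiguated by x-order since a lateral projection carries
no left/right identity. Labels are stored one object per line
(`class bx by bw bh`, six decimals), the dominant plain-text detection
convention.

## 3. Synthetic radiographs

`sample_anatomy()` draws SS, PT, LL and SVA from truncated normal
distributions (bounds SS ∈ [5, 70]°, PT ∈ [−10, 50]°, LL ∈ [0, 90]°,
SVA ∈ [−50, 150] px) with means and SDs of two named populations taken
from the ground-truth statistics of the two clinical cohorts the method
was developed on (`"ds1"`: SS 38.9 (10.3), PT 19.3 (9.4), LL 46.2 (16.2),
SVA 34.9 (3.2); `"ds2"`: SS 30.5 (10.4), PT 22.1 (19.5), LL 37.1 (17.8),
SVA 29.8 (2.1)); PI is never sampled, it is the identity PT + SS.
Skeletal dimensions (pelvic radius, endplate widths, femoral-head radius
and separation, hip-axis anchor) default to fixed fractions of the canvas
with ±5% uniform jitter — values chosen once to put all ten landmarks
comfortably inside a 128 px canvas across the truncation range. The
facing is fixed (+1); mirrored views enter training through the flip
augmentation.

`landmarks_from_params()` constructs landmarks so that
`compute_measures()` reproduces the generating parameters to machine
precision — this round-trip is the module's acceptance test. The lumbar
interior is a smooth arc between the L5 and L1 endplate midpoints with
linearly interpolated inclinations; it is a non-contractual interior
detail (only the two labelled endplates carry measures).

`render_radiograph()` emulates, not simulates, radiography: a soft-tissue
background gradient, vertebral bodies as bright quadrilaterals spanning
the labelled endplates with interpolated mid-lumbar bodies as unlabelled
distractors, thin high-intensity cortical rims along the labelled
endplate lines, a sacral wedge, bright femoral-head discs, Gaussian plus
signal-dependent noise, and three degradations that occlude but never
move landmarks: border cutoffs, opaque hip-region occluders, and
implant-like rods along the lumbar arc. Degradation prevalence defaults
to 5% low-quality and 15% implants, the rates reported for the clinical
cohorts. What the generator does **not** emulate: projective geometry,
scatter, anatomical shape variation beyond the parameter vector, or
device differences between cohorts — so passing tests demonstrate
pipeline correctness and learnability, not clinical-grade accuracy.

## 4. The detector

Three dense grids at strides {8, 16, 32}; each cell carries `N_a = 3`
anchors × `N_o = 15` channels (4 box, 1 objectness, 10 classes). Anchors
are square multiples {0.6, 1.0, 1.6} of the nominal spine-box side,
scaled ×1/×2/×4 per level. Targets are assigned by worst-side-ratio
anchor matching; each matched label claims its responsible cell (cells
are half-open, `floor(centre/stride)`) plus the two nearest side
neighbours, with nearest-centre-wins conflict resolution and a
best-single-anchor fallback for unmatched labels. Box decoding is the
bounded transform `centre = (2σ(t) − 0.5 + cell)·stride`,
`size = (2σ(t))²·anchor`.

Two tolerances coexist deliberately. `grid_spec()` defaults to the
classical ratio tolerance 4.0. The fitting function `landet()` assigns
targets with tolerance 2.5: at 128 px the spine boxes are 6.4 px, and
assigning them to stride-32 cells (which tolerance 4 permits) trains
confident duplicates whose centres the coarse grid cannot resolve; these
pollute the highest-confidence selection. Tolerance 2.5 keeps spine
targets on the two finer grids while femoral heads still span all three.

The backbone is a small CSP-style stack of strided 3×3 conv +
batch-norm + leaky-ReLU blocks with one residual bottleneck, an FPN-style
top-down neck with 1×1 laterals, nearest-neighbour upsampling and 3×3
smoothing, and per-level 1×1 heads ("tiny" preset: channel widths
10-20-28-40-56, neck 32; "small" doubles them). Inputs are standardised
per image (zero mean, unit variance), which makes detection exactly
invariant to constant intensity rescaling, and replicated to three
channels. The reference forward/backward pass is plain R over BLAS
matrix products with compiled im2col/col2im kernels; the training loop
uses a single-precision compiled mirror of the same graph
(`src/net_fast.cpp`) for speed, and the equivalence of the two paths is a
unit test. All gradients are analytic and were verified against central
finite differences end to end.

## 5. The loss

For target grids $G$ and predictions $\hat G$:

- $l_{obj}$: per level, the mean over **all** cells/anchors of
  BCE$(\hat p_o, p_o \cdot \mathrm{IoU}(\hat t, t))$ — at assigned
  entries the objectness target is the IoU of the currently decoded box
  (treated as a constant in the gradient), which calibrates confidence
  towards localisation quality; elsewhere 0.
- $l_{box}$: per level, the mean over assigned entries of
  $1 - \mathrm{IoU}$.
- $l_{cls}$: per level, the mean over assigned entries of the per-entry
  mean multi-label BCE across the ten class channels.
- $l_{cnst}$: per image, over all pairs of present landmark classes, two
  families — angular, the mean of $1 - \cos(\hat r_{ij}, r_{ij})$, and
  distance, the mean of $|\,\lVert\hat r_{ij}\rVert - d_{ij}\,|$ — where
  $r_{ij}$ are ground-truth pairwise displacement vectors in normalised
  coordinates and $\hat r_{ij}$ are derived from the decoded box centres
  of each class's best assigned prediction (highest predicted
  objectness). Deriving $\hat r$ from the box head rather than a
  dedicated output keeps the constraint differentiable through
  localisation and adds no parameters; this is the main interpretive
  choice in the loss and is the package's reading of "intermediate
  constraint satisfaction".

The total is $n_b(\lambda_{obj} l_{obj} + \lambda_{box} l_{box} +
\lambda_{cls} l_{cls} + \lambda_{cnst}(w_{ang} l_{ang} + w_{dist}
l_{dist}))$ with $k = 2$ constraint families (per-pair weights can be
emulated by pre-weighting, but per-family is the documented default).
Cosine similarity enters as the loss $1 - \cos$ so that 0 is perfect.
BCE probabilities are clamped at $\varepsilon = 10^{-7}$.

Defaults: $\lambda_{obj} = 2$, $\lambda_{box} = 0.2$,
$\lambda_{cls} = 0.5$, $\lambda_{cnst} = 0.1$, $w_{ang} = w_{dist} = 1$.
No published values exist for these weights; the box and objectness
weights were chosen in engineering pilots because 6-7 px boxes need a
stronger localisation signal than generic-object settings, and the
objectness term is what makes confidence track IoU across levels —
decisive for the highest-confidence selection rule. $\lambda_{cnst} = 0$
reproduces the unconstrained ablation exactly (constraint components are
still computed and logged).

## 6. Training, inference and the scaled-down study

`landet()` trains with Adam (peak 8e-3, 3-epoch linear warm-up, cosine
decay to 5%), batch 8, random horizontal flips, and an exponential moving
average of the weights (decay 0.99) used at prediction time. Defaults
(60 epochs, 200-image scale) were fixed from convergence pilots.
Inference decodes at a permissive confidence threshold (0.1), applies
class-agnostic NMS at IoU 0.45 (ground-truth boxes of different classes
never overlap at that threshold by construction, so cross-class
suppression removes only co-located duplicates carrying a confused class
label), then takes each class's highest-confidence detection as the
landmark and computes the measures.

The bundled study (`scripts/acceptance.R`, mirrored in the acceptance
tests) trains the tiny preset on 200 synthetic 128×128 DS1-like images
(160/20/20) for 60 epochs, three seeds, with
$\lambda_{cnst} \in \{0, 0.1\}$, and evaluates on the held-out split:
mAP@0.5 and @0.5:0.95, per-class and image-complete detection rates at
the 0.3-IoU success criterion, and per-measure MAE/accuracy. Problem
sizes were chosen so the whole study runs in well under half an hour on a
single CPU core. Two caveats, observed repeatedly in pilots and stated
here so the reported numbers are read correctly: (i) per-run
image-complete rates vary by ±0.1 across seeds at this data scale; and
(ii) per-measure MAE is outlier-dominated — a single frame whose S1
corners swap flips the signs of SS/PT/PI and contributes a ~100° PI
error — so the constrained-vs-unconstrained comparison on 20 test images
is a noisy instrument; the constraint's measurable benefit at full
clinical scale should not be inferred from, nor refuted by, single-seed
differences here.

## 7. Known limitations

- The renderer's simplicity means the detector's synthetic performance is
  an upper bound on nothing: it demonstrates that the pipeline closes,
  not that it transfers to clinical radiographs.
- The constraint term acts only through assigned entries during
  training; it cannot repair a wrong-structure detection at inference.
- ICC is the one-way single-rating consistency form only; two-way forms
  and Bland–Altman analyses are out of scope.
- `mae_sd()`'s SD uses the sample (1/(N−1)) convention while RRMSE uses
  the 1/N definition of its formula; both conventions are exposed where
  they matter.
- Mosaic augmentation yields label-level samples (several instances per
  class), so the per-image constraint term skips such images; the default
  training recipe uses flips only.
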