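---
title: "Seed outline morphometrics and two-stage discriminant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed outline morphometrics and two-stage discriminant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipmorph)
```

`pipmorph` classifies grape pips (seeds) from their dorsal-view outlines:
first into wild versus domesticated morphotypes, then — for the pips that
look domesticated — into individual modern cultivars, with percentage
reports of the resulting allocation by berry colour and geographic origin.
This vignette is the package's own account of the method: the model, the
parameters that matter, the numerical choices, and what the synthetic data
used for validation can and cannot show.

## The shape model

A pip silhouette is reduced to a closed planar outline of 360 points at
equal arc-length spacing. The outline is expanded in elliptic Fourier
descriptors (EFDs): per harmonic $n$, a quadruple $(a_n, b_n, c_n, d_n)$
describing $x(t)$ and $y(t)$ as truncated Fourier series in the arc-length
parameter $t \in [0, T)$, where $T$ is the perimeter. The coefficients are
computed by the exact closed-form sums over polygon segments (Kuhl &
Giardina), not by FFT on resampled signals, so they are well defined for
any simple closed polyline.

Two parameterisation facts shape the implementation and are worth stating
explicitly because they are easy to get wrong:

* The EFD of a curve depends on its parameterisation. We always use the
  arc-length (chord-length) parameterisation, the standard in outline
  morphometrics. A consequence is that an ellipse sampled uniformly in
  *angle* does **not** have first-harmonic coefficients equal to its
  semi-axes: for a 2:1 ellipse the arc-length values are
  $a_1 \approx 1.828$, $d_1 \approx 1.073$. The unit tests pin these
  values against an independent trapezoidal-integration oracle.
* Reconstructing a curve from its coefficients (uniform in $t$) and
  re-extracting descriptors is *not* an exact fixed point, because the
  truncated curve's own arc length differs from $t$. The map is a
  contraction in practice; the package exploits this by storing class
  templates as numerical fixed points of the reconstruct–extract map (see
  `pip_template_features()`), and by defining the generator's "true"
  coefficients as the features of the ideal pre-rasterisation outline.

### Normalisation

Before coefficients are computed the outline is (1) translated so its
centroid is at the origin, (2) divided by centroid size — the RMS distance
of outline points from the centroid; the definition matters and RMS radius
is the one used throughout — (3) re-indexed so the first point is the
outline point farthest from the centroid, and (4) rigidly rotated so that
point lies on the positive $x$ axis. The resulting 24-coefficient vector
(harmonics 1–6) is invariant to translation, scale, rotation and starting
index, which the test suite checks to $10^{-6}$ on exact polylines.

Rotation is deliberately folded into the farthest-point rule rather than
using the full Kuhl–Giardina first-harmonic-ellipse normalisation: the
latter forces some first-harmonic coefficients to constants and would make
several of the 24 variables uninformative. Reflection is *not* normalised
— dorsal-view scans have a fixed handedness. Ties in the farthest-point
rule go to the lowest original index.

One numerical refinement is needed: a sampled outline locates its true
radius maximum only to ±half a sample, and that quantisation would jitter
both the rotation and the Fourier phase origin by ~0.5° between
re-digitisations of the same seed, an error of order $0.01$ on unit-scale
coefficients. `normalize_outline()` therefore fits a quadratic to the
radius profile over an 11-point window around the discrete maximum and
inserts the interpolated tip as a new first vertex. The tip lies on the
polygon, so the curve itself is unchanged; the rule remains "first point =
farthest point", implemented with sub-sample precision. All invariances
are preserved because the construction is similarity-equivariant.

### Outline extraction from images

`trace_outline()` uses Moore-neighbour boundary following with Jacob's
stopping criterion on the largest 8-connected foreground component
(labelled by an in-package BFS; holes are ignored, and components below 32
px are rejected as noise). Two digitisation biases are corrected:
chain-code polygons through pixel centres overestimate perimeter by ~5%
(staircase excess) and underestimate area by a half-pixel rim. The traced
polygon is therefore smoothed with a circular moving average (window 5,
configurable) and offset outward by 0.5 px along the local normal. On
digital disks of radius 30–80 px this brings both perimeter and area
within a few tenths of a percent of the analytic values; the tests assert
the 2% contracts with a wide margin.

## The discriminant machinery

Classification uses linear discriminant analysis with stepwise variable
selection, the standard workflow for seed outline data:

* **Wilks' lambda** $\Lambda = \det W / \det T$ on a feature subset, with
  $W$ and $T$ the within-group and total SSCP matrices.
* **F-to-enter** for candidate $v$ given $p$ variables in the model:
  $F = \frac{n-g-p}{g-1}\left(\Lambda_p/\Lambda_{p+1} - 1\right)$, with
  $\Lambda_0 = 1$; entry requires strictly $F > 3.84$ (the 5% criterion).
* **F-to-remove** analogously; removal when strictly $F < 2.71$.
* **Tolerance** of a candidate — $1 - R^2$ of its within-group regression
  on the in-model variables — must be at least 0.001. The entry threshold
  is stated by the method; the removal threshold and tolerance floor are
  the classic defaults of the stepwise discriminant procedure and are
  configurable.

Removal is examined before entry at each step; a revisited model state
stops selection with a warning event in the trace. Every entry event is
validated in the tests against an exhaustive recomputation of all
candidate F values, and $\Lambda$ against a MANOVA oracle.

Classification functions are
$C_j(x) = \mu_j' W^{-1} x - \tfrac12 \mu_j' W^{-1}\mu_j + \ln\pi_j$ with
$W$ the pooled within-class covariance; posteriors are the softmax of the
$C_j$, which equals the Gaussian Bayes posterior under the shared
covariance model. Ties go to the lowest group index, deterministically.
Priors are equal by default — the reference is deliberately balanced, and
archaeological unknowns carry no abundance prior — with proportional
priors available.

**Leave-one-out cross-validation** refits the group means and pooled
covariance without each case via an exact rank-one (Sherman–Morrison)
downdate; the tests check exact agreement with a literal per-case refit
loop. Variable selection is performed once on the full training set and
held fixed across folds, matching the classic description of the
procedure ("classification functions calculated from all data except the
case currently being classified"); resubstitution accuracy is reported
alongside, since published "overall correct classification" figures do
not always say which of the two they are.

Numerical policy: SSCP matrices are computed on mean-centred data;
near-singularity is detected by a condition-number threshold of $10^{12}$
on the pooled *correlation* matrix (so that rescaling a feature — which
provably does not change the classifier — cannot trip the check) and
reported as an error rather than silently regularised.

## The synthetic-data generator

No archaeological pip images or germplasm reference silhouettes are
publicly deposited, so validation runs on synthetic populations whose
statistical structure matches what the analysis assumes:

* Each shape class is a Gaussian in the 24-dimensional normalised-EFD
  space. The default templates are a rounder, short-beaked "wild" form and
  an elongated, long-beaked "domestic" form built from harmonics 1–3;
  they are illustrative (no quantitative wild/domestic shape parameters
  are published to copy) and live in the packaged YAML configuration, not
  in code. Both templates keep a defined beak: it is the landmark the
  farthest-point rule keys on, as on real pips.
* Per-coefficient standard deviations decay with harmonic rank
  ($\max(0.045/n,\ 0.015)$), mimicking the concentration of biological
  shape variation in low harmonics while keeping every coordinate
  non-degenerate.
* Class separation is a single dial: the Mahalanobis distance $\Delta$
  between class means. Because the reconstruct–extract map is mildly
  non-linear, a separation dialled in drawn-coefficient space shrinks by
  roughly 10% in extracted-feature space; `pip_class_specs()` therefore
  calibrates the separation by deterministic unscented propagation of each
  class Gaussian through the map, so that the *extracted* features realise
  the requested $\Delta$. With equal priors the two-class Bayes accuracy
  is then $\Phi(\Delta/2)$ — a closed-form oracle for the entire pipeline,
  which the acceptance tests check at $\Delta \in \{1, 2, 3\}$ with 500
  pips per class (tolerance ±0.03).
* Sampled coefficient vectors are reconstructed by inverse EFT, rejected
  and redrawn if self-intersecting (budget 100 per sample), and rasterised
  onto a 512×512 canvas at 142 px seed length (≈6 mm at 600 dpi), i.e.
  with realistic discretisation error. All randomness flows from one seed
  through a single generator stream, and the truth table records the
  features of each ideal outline, so parameter recovery is directly
  testable (median per-coefficient recovery error is well under 0.02 at
  this resolution).
* The default separation is $\Delta = 3.4$ between the two morphotype
  templates, a Bayes accuracy of $\Phi(1.7) \approx 0.96$ for the pure
  two-class problem — the accuracy regime reported for wild/domestic pip
  classification on real reference collections. In the full pipeline the
  cultivar and accession sub-structure adds between-class scatter on top
  of the within-class covariance, so the realized reference LOOCV sits a
  few points below that ceiling, as it does for real germplasm.
* Cultivar structure: cultivar sub-means scatter around the domestic mean
  (spread = 1 × the within-class sd per coefficient; wild accessions at
  0.5 ×). Unknown assemblages are per-site mixtures of those sub-classes
  with configurable domestic fractions (defaults 0.92, 0.74, 0.97 for the
  three packaged sites, at sizes 1686, 301, 241).

What the generator does **not** emulate: scanner texture and lighting,
damaged or fragmented pips, touching seeds needing instance segmentation,
non-Gaussian within-cultivar variation, and any real morphological
correspondence between a template and a named cultivar. A green test
suite therefore shows the *machinery* is correct and well calibrated, not
that any particular archaeological conclusion is reproduced.

## The two-stage pipeline

`run_pipeline()` orchestrates simulate → extract → features → stage 1 →
stage 2 → report from one configuration file:

1. The reference is balanced by uniform subsampling to the same number of
   pips per status class (default 1319 + 1319), so status priors are flat
   by construction.
2. Stage 1 fits stepwise LDA on wild/domestic labels, reports LOOCV and
   resubstitution accuracy, and assigns every unknown a status.
3. Stage 2 fits one multi-class LDA over cultivar labels (default 330;
   equal priors; cultivars with fewer than 3 reference pips are dropped
   with a warning) and assigns every domestic-classified unknown to
   exactly one cultivar. A single simultaneous multi-class model is used
   — the natural reading of the published workflow, which does not
   describe a pairwise scheme.
4. Reporting: per-site status counts with integer percentages, a
   per-cultivar count table (full, plus a headline table filtered to
   cultivars with ≥ 10 assigned pips), and colour/region percentage
   breakdowns.

Two reporting conventions are fixed and documented because the published
figures they echo are internally inconsistent in places:

* Percentages are rounded half away from zero. This reproduces worked
  examples such as 1559/1686 → 92% and 127/1686 → 8%, and 223/301 → 74%
  vs 78/301 → 26%. (No integer rounding rule can reproduce every printed
  percentage in the source material — e.g. a 97.5%/2.5% split printed as
  97%/3% — so one consistent rule is applied throughout.)
* Colour and region percentages are computed over *assigned pips*, not
  over distinct cultivars; pip-level weighting is the only convention
  consistent with the published percentage/count pairs.

Conservation holds by construction and is asserted in the tests: per site,
wild-classified pips plus cultivar-assigned pips equal the number of
unknowns, and every reported percentage recomputes from the reported
counts.

## Problem sizes and runtime

The packaged default configuration runs the full design — 2640 reference
silhouettes (330 cultivars × 4 pips + 22 accessions × 60 pips), 2228
unknowns across three sites, 512×512 px images — in a few minutes on a
single CPU; the demo configuration (~200 images) runs in seconds. The
acceptance checks use 500 pips per class for the accuracy oracle and 200
outlines for the harmonic-power summary.

## Known limitations

* The farthest-point start rule is intrinsically sensitive for shapes
  whose radius profile is nearly flat at the maximum; sub-sample
  interpolation reduces but cannot eliminate this, and a small fraction of
  near-symmetric synthetic pips show elevated feature-recovery error.
  Both classes are affected alike, so classification calibration is
  preserved.
* Harmonic-power fractions use a 30-harmonic reference total
  (configurable); "total" power is otherwise unbounded as harmonics are
  added, and published statements of the form "six harmonics capture over
  95% of total power" leave the denominator unspecified.
* The generator's cultivar sub-means are exchangeable Gaussians; real
  cultivar structure is hierarchical and unevenly spaced, so stage-2
  accuracy on synthetic data should not be read as an estimate of
  real-world cultivar assignment accuracy.
* Multi-seed images, hole topology, and 3-D or landmark-based
  morphometrics are out of scope.
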