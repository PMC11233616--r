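---
title: "Aneurysm morphometry and rupture classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aneurysm morphometry and rupture classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneumorph)
```

## The measurement problem

A saccular intracranial aneurysm is a balloon-like out-pouching of an
arterial wall, most often at the Circle of Willis.  Whether an aneurysm
will rupture correlates with its shape, and clinical practice has
accumulated a large vocabulary of shape descriptors: heights and
diameters relative to the ostium (the neck opening into the parent
vessel), ratios of those lengths to the parent-vessel calibre, and
deviation-from-roundness indices built on the convex hull.  `aneumorph`
computes a battery of 35 such parameters from a triangulated surface
mesh of the sac plus a small annotation record (neck contour polyline,
inlet flow direction, parent-vessel axis and diameter, outlet
diameters, and clinical fields), and wraps a complete rupture-status
classification protocol around the resulting feature tables.

The input convention is deliberate: the sac mesh is stored **open**
along the neck, and closing it is an explicit operation (`cap_neck()`,
a centroid fan over the boundary loop).  This keeps the dome area DA
unambiguous (the outer sac surface only) while volume-type quantities
(DV, the convex hull, cross-section sweeps) are computed on the capped,
watertight solid.  Units are millimetres and degrees throughout.

## The parameter battery

Fifteen quantities are measured directly from the geometry:

* **DV, DA** — enclosed volume of the capped sac (divergence-theorem
  sum of signed tetrahedra) and summed triangle area of the open sac.
* **MD** — exact maximum distance between two sac vertices (exhaustive
  scan in compiled code; ties resolve to the lexicographically smallest
  index pair).
* **Neck plane** — total-least-squares plane through the contour
  (smallest eigenvector of the point covariance), origin at the contour
  centroid, normal oriented toward the sac.  The neck area NA is the
  shoelace area of the contour projected into this plane; the neck
  circumference NC is the length of the original 3D polyline.  A
  perimeter is a curve property and a planar projection can only
  shorten it, so this pairing keeps the isoperimetric inequality exact.
* **CPH, MPH** — CPH is the distance from the neck centroid to the
  *farthest* intersection of the normal ray with the sac; MPH is the
  largest vertex distance above the neck plane.  The farthest-hit rule
  makes CPH well defined for folded sacs and guarantees CPH ≤ MPH.
* **ND** — the chord of the projected neck polygon through the neck
  centroid along the in-plane projection of the inlet flow direction.
* **IMDA, MDNA, INA** — angles between the inlet flow, the MD vector
  (oriented from the neck-near endpoint outward) and the neck plane.
* **PL** — extent of the sac's scalar projections on the vessel axis.
* **MDPN** — the offset of the largest sac cross-section parallel to
  the neck plane, found by sweeping 200 uniform offsets across
  `[0, MPH]` (ties resolve toward the neck).  Cross-section areas come
  from oriented mesh/plane intersection segments, so disconnected
  sections are handled without polygon assembly.
* **LB, I** — bifurcation status (0 = lateral, 1 = bifurcation) and the
  irregularity flag.  Irregularity is consumed as a provided annotation;
  when absent the documented fallback proxy is `I = (UI > 0.05)`.

Twelve ratio indices are then computed literally from their defining
formulas: AR = CPH/ND, BR = MD/ND, NR = ND/DPVI, SR = MD/DPVI,
DNR = DA/NA, SF = DA/DV^(2/3), VOA = DV/NA, PR = MPH/DPVI,
CP = 0.5 − MDPN/DPVI, and the hull-based shape scores

$$EI = 1 - (18\pi)^{1/3}\,DV_{CH}^{2/3}/DA_{CH}, \qquad
  NSI = 1 - (18\pi)^{1/3}\,DV^{2/3}/DA, \qquad
  UI = 1 - DV/DV_{CH},$$

where DV_CH and DA_CH are the volume and outer area of the convex hull
of the **capped** sac.  The normalisation makes a hemispherical dome
score NSI = 0; with the capped-hull convention a hemisphere scores
EI = 1/3 (the hull area includes the flat cap, 3π against a dome area
of 2π).  SF keeps its dimensional character, following the printed
formula rather than a normalised variant.

Eight further parameters treat roundness isoperimetrically:
IR = √(NA/π) and IS = (3 DV/4π)^(1/3) are the radii of the circle with
the ostium's area and of the sphere with the sac's volume; their ratios
IRR = 2π·IR/NC and ISR = 4π·IS²/(DA + NA) are bounded above by 1
because the circle minimises perimeter at fixed area and the sphere
minimises surface at fixed volume.  ON, COD and IOR count the outlets,
sum their diameters, and relate the inlet to that total.

## Geometric kernels and numerical choices

Three primitives live in compiled code.  The convex hull is an
incremental quickhull with per-face conflict lists and breadth-first
visibility, which keeps the horizon a closed loop; the input is joggled
by a deterministic, index-keyed perturbation of ~1e-10 of the extent so
co-spherical and coplanar degeneracies (ubiquitous in structured sphere
meshes) never produce inconsistent visibility, while volume and area
are evaluated on the unperturbed coordinates.  The suite cross-checks
it against an independent qhull implementation on random clouds and on
the degenerate grid-sphere case.  Point-in-mesh queries (used only by
the Monte-Carlo volume oracle in the tests) ray-cast along +z with an
x-strip index.  The exact diameter scan is quadratic and compiled.

Other tolerances: degenerate faces are rejected below 1e-12 mm²;
watertightness requires every directed edge exactly once; vertices
within 1e-12 of a cut plane are nudged to the neck side so the sweep at
offset 0 still sees the ostium polygon; mesh boundary and neck contour
must agree within 1e-6 mm before capping; direction vectors must be
unit within 1e-9.  UI is clamped at its mathematical lower bound 0 to
absorb hull-tolerance dust on exactly convex sacs.

## Synthetic geometries with closed-form truth

`make_sac()` builds five parametric families on a polar grid (apex plus
`n_phi` rings of `n_theta` vertices; the last ring is the open rim):
hemispheres, super-hemispherical spherical caps, half ellipsoids,
two-lobed sacs (radial modulation `a·sin²(2θ)cos(2φ)`), and undulated
sacs (`a·sin(4θ)sin(4φ)`).  All modulations vanish at the rim, so the
neck stays a planar circle or ellipse and the ostium metrics keep
closed forms.  Each generated geometry carries a `truth` list: cap
volume/area formulas, ellipse perimeters and spheroid dome areas by
quadrature of the exact integrals, and the half-spheroid diameter by
numerical maximisation over antipodal height pairs (for elongated
domes the extremal pair is *not* the rim–rim or apex–rim pair).
Tests require agreement of the full 35-parameter record with these
truths within 1% at resolution (128, 64) and 5% at (32, 16), plus
monotone refinement convergence, Monte-Carlo volume agreement, scaling
laws, and rigid-motion invariance.

One caveat the fixtures expose: on highly symmetric sacs several vertex
pairs attain the maximum diameter, and which pair wins the tie can
change under rotation.  Dimensionless indices are unaffected (they are
tested to 1e-9 under scaling and rigid motion), but the MD-dependent
angles can jump between symmetry-equivalent values; invariance of the
full record is therefore asserted on an asymmetric fixture.

## Synthetic cohorts

`make_cohort()` emulates the study conditions the classifier protocol
expects: a retrospective case-control cohort of 253 ruptured and 456
unruptured records (one source reports 708 aneurysms in summary text
and 253 + 456 = 709 by composition; the generator follows the explicit
composition).  Rupture risk is planted through a logistic model on
standardized features with default log-odds weights EI +1.2, SR +0.8,
I +0.6; labels are drawn from that model over a feature pool and the
exact case-control counts are then sampled, mimicking how such cohorts
are assembled.  Locations follow a frequency profile dominated by ICA,
MCA and ACA, and roughly two-thirds of records are female, matching the
qualitative composition such registries report.

Each of the 35 features is drawn from its own clinically plausible
marginal, *independently* of the others.  This is deliberate: the
planted effects must be recoverable from their own columns for the
attribution tests to be decisive, and near-duplicate columns (a real
cohort has AR exactly equal to CPH/ND, IR exactly √(NA/π), and so on)
let maximum-margin weights blow up in cancelling pairs on whichever
columns happen to correlate.  The generator therefore prioritises
marginal plausibility and sharp attribution over covariance fidelity;
replicating the inter-feature covariance of real measured cohorts is an
explicit non-goal.  Consequently, passing the recovery tests shows the
protocol attributes planted signal correctly under independence — it
does not certify attribution behaviour under the strong collinearity of
real morphometric tables.

## The classification protocol

`train_models()` implements the evaluation pipeline end to end:

1. **Encoding** — sex to {0, 1}, location one-hot over the six Circle
   of Willis codes; encoded width is fixed at 43 = 35 + 1 + 1 + 6.
2. **Split** — stratified 80/20 train/test holdout (the five-fold
   cross-validation is prescribed; the holdout fraction is this
   package's choice).
3. **Standardization** — z-scores with statistics from the fitted rows
   only; zero-variance columns map to zeros.  Inside the grid search
   the transform is refitted on each fold's training portion, so no
   held-out information leaks into model selection; a canary test (a
   feature equal to the label on held-out rows only) asserts this.
4. **Grid search under stratified five-fold CV** for five families:
   SVM (kernel ∈ {linear, RBF} × cost {0.1, 1, 10}), KNN (k = 3..15),
   random forest (two mtry fractions, 300 trees), gradient boosting
   (depth {2, 4} × rounds {60, 200}, η = 0.1), and an MLP.  The grids
   are this package's defaults; the protocol prescribes grid search but
   not the grids.  Ties select the earlier grid row; every fit receives
   a seed derived from the run seed, so reports reproduce byte-for-byte.
5. **Evaluation** — train and test accuracy, precision and recall with
   ruptured as the positive class (precision is 0 with a warning flag
   when nothing is predicted positive), an overfit flag when train
   accuracy exceeds test accuracy by more than 0.10, and the ROC curve
   with trapezoidal AUC (equal, ties at ½, to the Mann–Whitney
   concordance; verified against a brute-force oracle and pROC).

The MLP takes the "three hidden layers with identity activation"
specification literally: it is a linear network with a sigmoid output,
trained full-batch with momentum and a learning rate halved whenever
the penalised log-loss stops improving.  That architecture is unusual —
it can represent only linear decision boundaries — but it has a real
payoff for interpretation: the product of the connection-weight
matrices *is* the network's coefficient vector, so its signed feature
attribution is exact rather than heuristic, and the tests verify the
algebraic identity directly.

Signed importances come from the linear SVM's hyperplane coefficients
and the MLP's weight products; random forest and boosting report their
native split-gain importances; nonlinear SVM and KNN fall back to
seeded permutation importance.  All importances refer to standardized
features and are ranked by absolute weight.

## Problem sizes and limitations

The test suite and the acceptance script run everything at sizes chosen
to exercise the mathematics, not to benchmark: fixture meshes at
resolutions (16, 8) through (128, 64), isoperimetric sweeps over 100
random contours and 100 random sacs at (32, 16), one-million-point
Monte-Carlo volume checks on five lobulated sacs, and twenty seeded
cohort replicates for importance recovery.

Known limitations: the package measures shape only — no hemodynamics,
no segmentation, and no centerline extraction; the CPH ray rule and the
capped-hull EI convention are documented choices where the battery's
definitions are ambiguous; cross-section areas are exact for the mesh
but MDPN is quantised by the slice sweep (choose `n_slices` to taste);
and synthetic cohorts certify protocol correctness, not clinical
performance — conclusions about real rupture risk require real
measured geometries.
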