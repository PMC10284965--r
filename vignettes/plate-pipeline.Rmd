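---
title: "Automated presurgical plate computation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated presurgical plate computation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatoplate)
```

Presurgical orthopedic (PSO) plates narrow the cleft in neonates with
unilateral (UCLP) or bilateral (BCLP) cleft lip and palate: a passive
plate covers the alveolar ridges tightly, bridges the cleft space with
clearance, and redistributes intraoral forces so the gap narrows on its
own. `palatoplate` turns a triangle-mesh surface scan of the palate into
a watertight, 3D-printable plate, fully automatically. This vignette
explains the models behind each stage, the parameters that matter, and
the design choices made where the problem left the design open.

## Pipeline overview

Given a scan in arbitrary pose and with arbitrary mesh topology:

1. **Landmarking.** A per-vertex scorer predicts ten proximity maps, one
   per anatomical landmark; landmarks are the argmax vertices with a
   certainty read off the clamped peak score.
2. **Alignment.** A weighted Procrustes fit of the predicted landmarks
   onto the template landmarks (weights = certainties) moves the scan
   into the template frame; a second, more precise scorer trained for
   near-aligned poses refines the landmarks.
3. **Registration.** A labeled template is deformed onto the scan by
   region-staged nonrigid ICP; the template's region labels then segment
   the scan, and the scan is effectively resampled at the template's
   topology.
4. **Plate construction.** The plate area is cut out, the cleft region
   is filled around a constrained sphere, the surface is selectively
   smoothed, offset into contact and outer copies, and stitched into a
   watertight solid with a half-ellipse rim.

## Landmark proximity maps

Each landmark $l_j$ is encoded on a mesh with vertices $v_i$ (all
coordinates in millimetres) as a smooth per-vertex map

$$ s_{ij} = \exp\!\left(-\tfrac12\,\lVert l_j - v_i \rVert_2\right), $$

a synthetic probability surface peaking at 1 on the landmark. Training
against these maps with a mean-squared-error loss is far better
conditioned than one-hot vertex labels, whose placement is inherently
imprecise. Landmarks are recovered by an argmax over the vertex
dimension (ties break to the lowest vertex index, for determinism), so
the extraction error is bounded by the local edge length.

**Certainty.** Raw scores are clamped to $[0,1]$ and the certainty of a
landmark is the clamped score at its argmax vertex. Per-column min–max
scaling would force every certainty to 1; clamping keeps the magnitude
informative.

**Two stages.** The stage-1 scorer must work at arbitrary orientation;
the packaged reference backbone is a ridge regression over multi-scale
geometric vertex features (principal-axis canonical coordinates,
Laplacian-smoothed coordinates at several scales, curvature proxies),
trained with uniformly random 3D rotation augmentation. After Procrustes
alignment, the stage-2 scorer — trained with azimuth augmentation
restricted to ±0.2 rad about the z axis — resolves the landmarks more
precisely while remaining robust to the small residual misalignment of
stage 1. Both stages split their dataset 80/20 into train and test by
the training seed. An *oracle* predictor (the exact target maps built
from ground-truth landmarks) is a first-class option, so the geometric
pipeline can be exercised and validated without any training.

The weighted Procrustes step is the closed-form weighted
similarity-transform fit (rotation, translation and uniform scale by
default; neonatal palates vary in size, and the nonrigid registration
removes the residual). With at least three non-collinear positively
weighted landmarks the noiseless recovery is exact.

## Region-staged nonrigid registration

The template is deformed by optimal-step nonrigid ICP: one 3×4 affine
transform per template vertex, minimizing

$$ E(X) = \sum_i w_i \lVert X_i \tilde v_i - c_i \rVert^2
        + \alpha \sum_{(i,j)\in\mathcal{E}} \lVert (X_i - X_j) G \rVert_F^2
        + \beta \sum_k p_k \lVert X_{m_k} \tilde v_{m_k} - l_k \rVert^2 $$

with closest compatible points $c_i$ on the scan, edge set $\mathcal E$
of the template, $G = \mathrm{diag}(1,1,1,\gamma)$, and a landmark term
matching template landmark vertices $m_k$ to predicted positions $l_k$
weighted by their certainties $p_k$. Each inner iteration solves one
sparse linear least-squares problem; the stiffness $\alpha$ anneals
down a fixed schedule (default 50, 20, 5, 2, 0.8; landmark weights 5,
2, 0.5, 0, 0; three inner iterations per step). Correspondences are
rejected beyond 5 mm, beyond 60° of normal disagreement, or on the scan
border. The system is assembled in the source-centroid frame: the
affine stiffness term is origin-dependent, and centring makes the
result exactly equivariant under rigid motion of the problem.

Two properties follow from the construction and are tested: masked-out
vertices keep full stiffness coupling but no data term (local scan
holes are spanned rather than copied), and pinned vertices are
eliminated from the unknowns with a prescribed translation, so they
retain their positions exactly.

**Staging.** Cycle 1 registers only the alveolar ridges (the plate's
contact region), guided by the landmark term. Cycle 2 registers the
remaining regions with the ridge pinned at its cycle-1 positions and no
landmark term. On the UCLP template — built from healthy-ridge palates —
the would-be alveolar gap sector is labeled `bridge`: it never receives
a data term, so the registered ridge spans the scan's cleft gap like a
healthy ridge. BCLP uses its own two-gap template without bridging.

Because the template's vertex/face structure is preserved, the
template's pre-segmented regions label the registered scan directly.
One caveat the tests respect: the deformation-recovery bound
(< 0.1 mm RMS against a known smooth field) applies to the data-active
vertices; border vertices have their correspondences rejected by design
and are carried by stiffness alone.

## Cleft filling around a constrained sphere

A healthy palate presents the tongue a smooth vault. The fill imitates
it by a sphere that connects the left and right alveolar ridges and
approximates the course of the cleft palate region:

* **Anchors** are the margin ring of the fill region — every vertex
  bordering the cleft-palate label, i.e. the ridge arcs on both sides
  plus the surrounding palate. (Anchoring on the ridge arcs alone pulls
  the fill down to ridge level and digs a crater with walls too steep
  to volumize.)
* **Objective**: $\sum_k (\lVert p_k - c\rVert - r)^2$ over anchors
  $p_k$, with the radius eliminated in closed form for each centre and
  the centre optimized by Nelder–Mead from an algebraic sphere-fit
  initialization. The algebraic fit of a near-planar ring is unstable
  normal to the ring, so the initialization is reflected into the
  mouth-side half space and a small multistart is used; the radius is
  capped at twice the anchor span (a healthy course cannot be flatter
  than the arch).
* **Constraint**: every cleft-tissue vertex $q$ keeps
  $\lVert q - c\rVert - r \ge d_{\text{safety}}$ (default 2.5 mm), so
  any point on or inside the sphere clears the tissue by at least the
  safety distance — room for inward growth. For synthetic scans the
  tissue is the ground-truth gap label; for raw scans it is estimated
  as the segmented cleft-region vertices recessed more than 1 mm beyond
  the unconstrained sphere course.

Fill vertices are blended toward their radial projection onto the
sphere (full projection for genuinely recessed gap walls, a graph-
distance blend near the region boundary so the fill meets the palate
smoothly), relaxed by a few Laplacian passes with the region boundary
fixed, and the gap-mouth border segments are smoothed along the
boundary loop so the plate outline spans the gap cleanly. Finally any
vertex closer than the safety distance to the tissue is snapped onto
the sphere, which restores the clearance by the constraint above; the
pipeline re-applies this enforcement after smoothing and offsetting.

## Curvature-selective smoothing, offsetting, volumization

**Convex smoothing.** One pass moves exactly the vertices whose
uniform-Laplacian (discrete mean-curvature) vector points along the
offset direction — the vertices around which a normal offset would
locally self-intersect — by `damping` times the Laplacian. Flat regions
and features bulging toward the mouth are untouched, which is what
preserves the high-frequency detail of the contact region. Boundary
vertices are smoothed along the boundary curve and move along their
normals only, so the two plate copies keep corresponding borders. The
contact copy gets one light pass (default damping 0.5); the outer copy,
whose detail is irrelevant, gets five.

**Offsets.** The contact copy is offset 0.1 mm along the vertex normals
(away from the tissue) to absorb slight scan inaccuracies — this is the
targeted lift-off the fit report should center on. The outer copy is
offset an additional 2 mm, the plate thickness needed against breakage;
per-region thickness scale factors implement optional buccal thinning.
A separation floor (half the thickness along the contact normals)
guards against the strongly smoothed outer copy spanning a groove the
contact copy still follows.

**Volumization.** Corresponding boundary vertices of the two copies are
joined by a sampled half-ellipse (minor axis: the pair separation;
major semi-axis: thickness/2, bulging outward in the surface tangent
plane; 8 samples by default) for a smooth border transition; one sample
degenerates to a straight wall. The outward directions are smoothed
along the loop and the bulge is suppressed across the filled cleft
border, where a lateral bulge could slice the adjacent sheet. The
assembled solid is consistently oriented outward. Residual
self-intersections — tight valleys narrower than the offset — are
removed by a monotone local repair: Laplacian relaxation of the
involved regions, never touching the contact sheet, accepting a round
only if the intersection count drops and escalating the neighbourhood
when stuck. `volumize()` errors rather than return an invalid plate.

**Fit report.** The signed point-to-plane distance from a query point
$q$ to the reference surface is $\langle q - c,\ n_c\rangle$ with $c$
the exact closest point (point-to-triangle projection) and $n_c$ the
barycentrically interpolated vertex normal there. Palate surfaces are
oriented so normals point into the mouth; the sign is therefore
negative exactly when a plate point lies inside the tissue — a
potential pressure point. The report gives mean ± sd over the
alveolar-ridge contact region, the minimum, the fraction below
−0.2 mm, and the cleft clearance.

## The synthetic palate generator

No patient scans ship with the package; every stage is validated on
synthetic palates. The generator emulates a neonatal maxillary scan as
a fan-shaped parametric surface: an elliptic arch (defaults 34 × 28 mm)
carrying a palatal vault (7 mm deep) and an alveolar ridge band (5 mm
wide, 3.5 mm drop), with cleft gaps modelled as constant-width,
steep-walled channels (8 mm for UCLP, two 6 mm gaps isolating a 10 mm
premaxilla for BCLP) whose floor is recessed 8 mm toward the nasal
cavity. Smooth random shape variation (three low-frequency cosine
modes, 0.8 mm), per-vertex surface noise along the normals (0.05 mm)
and an arbitrary rigid pose complete a sample; ten named landmarks and
a five-region label field (ridge, cleft, bridge, plate area, other) are
carried as ground truth. All meshes of one cleft type and resolution
share the grid topology, so templates are vertex-wise averages of a
cohort (five samples by default) and `make_scan_from_template()`
provides fixtures with known dense correspondence. Default resolution
is 48 × 18 (865 vertices, mean edge ≈ 1.5 mm); tests that need many
registrations use 36 × 14.

What the generator does **not** emulate — and hence what passing tests
cannot show about clinical data: scanner-specific artefacts (holes are
exercised synthetically, but not real occlusion patterns), soft-tissue
specularity and color (the method is geometry-only by design),
plaster-cast digitization error, true anatomical shape statistics, and
real mesh topologies (synthetic meshes share a grid; the landmarking
and registration path is exercised under arbitrary rigid pose and with
punched holes instead).

## Parameters at a glance

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `contact_offset` | 0.1 | mm | contact lift-off; the fit report should center here |
| `thickness` | 2.0 | mm | plate thickness (outer offset beyond the contact copy) |
| `safety_distance` | 2.5 | mm | minimum clearance of the fill to cleft tissue |
| `smooth_iterations_contact` | 1 | – | light, detail-preserving pass on the contact copy |
| `smooth_iterations_outer` | 5 | – | stronger smoothing of the outer copy |
| `rim_samples` | 8 | – | half-ellipse samples per boundary pair |
| stiffness schedule | 50…0.8 | – | NICP annealing |
| rejection | 5 mm / 60° / border | – | NICP correspondence gating |

## Numerical choices and degenerate inputs

* Argmax ties break to the lowest vertex index; STL corner merging uses
  a 1e-7 mm tolerance; rigid transforms are validated to 1e-9.
* The Procrustes fit errors on fewer than three positively weighted or
  collinear landmarks; the two-stage pipeline falls back to an
  unweighted fit before giving up.
* NICP raises a singular-system error when a component has neither data
  nor pins; schedules must be positive and non-increasing.
* The sphere fit caps the radius (adaptive, 200 mm for degenerate flat
  rings, with a warning) and reports the violating margin when the
  safety constraint is infeasible.
* `cut_plate_area()` errors when the plate area is disconnected — the
  designated signal of a failed registration.
* Everything is deterministic: all randomness is seed-scoped
  (`with_seed` semantics restore the caller's RNG state), and a rerun
  with the same inputs produces bitwise-identical STL files.

## Problem sizes

The packaged study conditions are desk-scale: templates averaged from 5
synthetic palates at 48 × 18 resolution, fixture suites of 10 seeds per
cleft type, and training cohorts of 16 scans at 36 × 14 for the learned
scorer. A full pipeline run takes a few seconds on one CPU.

## Known limitations

* The learned reference backbone is a deliberately small feature-based
  scorer: it demonstrates the two-stage training/inference harness and
  its accuracy ordering (stage 2 beats stage 1 under arbitrary pose),
  but its absolute landmark error on synthetic data (a few mm) is not
  comparable to a fully trained deep surface network on clinical scans.
* Plates are computed in the template (aligned) frame; the returned
  alignment transform maps results back to the input pose. When the
  Procrustes scale deviates from 1, thickness is defined in the aligned
  frame.
* NAM-style appliances (premaxilla coverage, nasal stents), ventilation
  holes and stimulation elements are out of scope.
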