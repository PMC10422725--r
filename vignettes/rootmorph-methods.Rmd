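---
title: "Quantifying external root resorption from longitudinal tooth meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying external root resorption from longitudinal tooth meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootmorph)
```

## The measurement problem

External root resorption (ERR) is the loss of cementum and dentin from the
outer root surface, a known side effect of orthodontic force — notably of
rapid maxillary expansion (RME), where tooth-borne (TB) appliances transmit
heavy loads through the anchor teeth while bone-borne (BB) appliances load
palatal mini-screws instead. Given segmented surface meshes of the same
tooth at two imaging timepoints (T0 before treatment, T1 after retention),
the package quantifies ERR as:

* the radicular **volume loss** `ΔV = V(T0 root) − V(T1 root)` in mm³ and
  as a percentage of the T0 root volume,
* the **root length change** `ΔL` per root, measured from the assigned
  cusp tip to the most apical point of the root surface (molar
  mesiobuccal root from the MB cusp, distobuccal from DB, palatal from the
  ML cusp; premolars from the buccal cusp),
* a signed **surface-deviation field** between the superimposed root
  shells with a **matching percentage** — the share of samples within a
  tolerance band of ±0.3 mm, the scan voxel size.

The T0 and T1 scans live in unrelated scanner coordinate frames, so every
comparison runs through rigid registration first. All units are
millimetres; the synthetic data use +z occlusal, +x buccal, +y mesial.

## Pipeline

1. **Landmark pre-alignment.** Five matched surface points (buccal,
   lingual/palatal, mesial, distal, occlusal) give a closed-form
   least-squares rigid transform (Kabsch/Procrustes via SVD, reflection
   excluded).
2. **Best-fit refinement (ICP).** Source vertices are matched to their
   nearest points on the target *surface* (exact point-to-triangle
   queries, not nearest vertices); correspondences farther than
   `max(3 × median distance, 0.005 mm)` are rejected. The rigid update
   minimizes the linearized *point-to-plane* error of the surviving
   pairs. Although classical point-to-point (Kabsch) updates are
   available (`method = "point_to_point"`), they converge extremely
   slowly on smooth anatomical surfaces — the closest-point objective is
   almost flat along tangential sliding directions, and hundreds of
   iterations are needed where the point-to-plane step takes five. The
   reported RMS sequence is forced non-increasing: an update that would
   raise the point-to-surface RMS is discarded and iteration stops.
   Registration moves T1 onto T0, so all downstream quantities live in
   the T0 frame — T0 is the reference anatomy on which the cutting plane
   is defined.
3. **Radicular template.** Two cementoenamel-junction landmarks (CEJB
   buccal, CEJL lingual) underdetermine a plane; the third constraint
   chosen here makes the cutting plane parallel to the mesio-distal
   direction: its normal is the component of the tooth long axis (cusp
   centroid → apex centroid) orthogonal to the CEJB–CEJL line. This
   reproduces a near-transverse cervical cut and is fully determined by
   the landmarks, so repeated runs cut at exactly the same level.
4. **Synchronized crown removal.** Both registered models are cut by that
   single template plane (the template's lower surface *is* the plane, so
   re-deriving it from three sampled template points would add randomness
   without changing the geometry); the apical sides are kept and capped.
5. **Volume and deviation.** Watertight volumes come from the divergence
   theorem (signed tetrahedra against the origin). The deviation field
   samples *every* T0 root vertex, takes the distance to the nearest
   point on the T1 triangle surface, and signs it by a generalized
   winding-number inside/outside test: negative where the T1 surface lies
   inside T0 (material loss, blue), positive outside (gain, red), green
   within the tolerance band. The matching percentage is computed on the
   T0→T1 direction (T0 as reference); this one-sided choice is recorded
   in the output metadata.

### Mesh infrastructure

STL files store one vertex triple per facet, so meshes are cleaned on
read: vertices merged within 1e-6 mm and degenerate faces dropped.
Watertightness means every directed edge has exactly one partner in the
opposite direction. Plane cutting splits crossing triangles exactly at
the plane (Sutherland–Hodgman clipping with intersection points shared
per edge); the cut's open boundary is chained into directed loops and
each loop capped by a centroid fan whose triangles traverse the boundary
edges in reverse — pairing and outward orientation then follow from the
surface's own orientation, including the multi-loop case of a molar cut
through the furcation. Capped half-volumes sum to the original volume to
1e-6 relative; volumes of open shells are ill-defined, so caps are always
generated before measurement.

## The synthetic cohort generator

The study data (CBCT segmentations of 40 patients) are not distributable,
so validation rests on synthetic teeth with known ground truth. A tooth
is modelled as a surface *star-shaped about the furcation centre*: a
radial extent function `R(u)` over unit directions combines

* an offset ellipsoid for crown and trunk (its top at the crown top, its
  reach below the furcation set by a trunk-depth parameter), and
* one tapered "finger" per root, `L_k · exp(−(β/α_k)²)` in the angle `β`
  from the root direction, length `L_k`, angular width `α_k`,

blended with a power mean (exponent 8). Sampling `R(u)` on a UV sphere
grid yields a watertight mesh by construction; the grid direction nearest
each root tip is snapped to it exactly, so every apex is a mesh vertex.
Root lengths (premolars ≈ 14 mm, molar roots 12.5–13.5 mm from the
furcation), crown heights (7–7.5 mm) and widths were fixed once so that
radicular volumes land in the anatomically plausible range (premolars
≈ 115–125 mm³, first molar ≈ 310 mm³), which also places percentage
volume losses in the observed range. Landmarks (cusps, CEJB/CEJL at the
CEJ level, apices, five registration points) are computed analytically
from `R(u)`.

**Simulated resorption** has two components, matching the reported
localization (apex, bucco-apical and bucco-medial root surface):

* **Apical truncation**: the root finger is clipped by a flat facet —
  a capped cut of the tip — oriented perpendicular to the cusp–apex line
  and positioned so the cusp–apex distance shrinks by exactly the drawn
  `ΔL`. A 5 µm bulge at the exact apex vertex keeps apex re-detection on
  the flat facet deterministic; its size is included in the length solve,
  so the realized change equals the drawn value to machine precision.
* **Lacunae**: Gaussian pits (radius 2 mm) on the buccal flanks of the
  buccal-facing roots at mid-root and apical-third heights, displacing
  vertices inward along the surface normal. Pit depths are rescaled by a
  root-finding step so the *radicular* (below-CEJ) volume loss matches
  the drawn `ΔV`; a second pass compensates for the small part of the pit
  tails that sits occlusally of the tilted CEJ plane. Negative targets
  (apparent gain on control teeth) become outward displacement. Pits are
  masked within 1.8 mm of each apex so they cannot perturb the realized
  length change.

Ground truth is *measured from the generated meshes themselves* (CEJ-cut
volumes, landmark distances), not taken from the nominal draws, and
written to the cohort manifest.

**Cohort structure.** Two groups (TB, BB) of `n_per_group` patients; per
patient six upper test teeth and six lower control teeth (P1, P2, M1 ×
left/right), a gender draw (P(male) = 0.425) and group-specific ages
(13.1 ± 1.08 vs 14.5 ± 1.11 y). Per-tooth `(ΔV, ΔL)` are drawn jointly
with a latent severity factor giving correlation ρ = 0.5 between volume
and length loss — an assumption, not an observed quantity; the data to
estimate it are not published. Upper-tooth draws are truncated at zero;
control draws keep their sign (their configured means are near-zero noise
of either sign, and the lower M1 palatal entry, not reported for the
control arch, is set to a near-zero 0.02 ± 0.30 mm). Arch landmark files
realize skeletal (PW) and dento-alveolar (DAW) widths with baselines of
26/30/33 mm (PW at P1/P2/M1) and 38/44/50 mm (DAW) plus 1.5 mm
inter-patient noise — plausible adolescent maxillary dimensions — widened
at T1 by the drawn expansion so that PWE/DAE (T0 − T1) are negative. The
T1 frame of every tooth receives a random rigid perturbation (≤ 10°,
≤ 5 mm) standing in for the independent scanner frame. One master seed
drives everything; per-tooth seeds derive from it, and a fixed seed
reproduces the cohort byte for byte. Left and right teeth share the same
geometry statistics; `side` is a bookkeeping factor (the side-pooling
pre-test still runs on it, mirroring the analysis protocol).

Default effect tables (`default_effect_tables()`) encode the group
means/SDs the cohort reproduces, e.g. upper M1 volume loss 26.21 ± 10.03
mm³ (TB) vs 4.62 ± 3.12 mm³ (BB), and palatal-root length loss 0.56 ±
0.19 mm (TB) vs 0.15 ± 0.04 mm (BB). One printed dento-alveolar entry
(BB, P2) appears without its sign in the source table; it is interpreted
as −3.99 mm, consistent with every other expansion value being negative.

## Statistics layer

All classical machinery is delegated to base R (`shapiro.test`, `lm`/
`anova`, `t.test`, `chisq.test`, `pt` with noncentrality) behind thin,
testable wrappers: Shapiro–Wilk per group plus Levene's test on absolute
deviations from group means; one-way ANOVA with Bonferroni-adjusted
pairwise pooled t tests (p × number of pairs, clamped at 1); unpaired
*pooled-variance* Student t tests (the design reports homogeneous
variance; Welch by flag); Pearson chi-square without continuity
correction for gender; per-class OLS of `ΔV` on expander type (TB = 0,
BB = 1), PWE and DAE with standardized betas and 95% CIs; ICC(2,1) —
two-way random effects, absolute agreement, single measurement — chosen
because the source protocol does not state the ICC model, and flagged in
the output; and sample size per group via noncentral-t power iteration.
The observation unit is the tooth (as in the tables being mirrored), with
no clustering correction for teeth within patient — a documented
limitation of the design being reproduced, not of the implementation.

## Numerical choices

* Vertex merge tolerance 1e-6 mm (STL duplicates facet vertices); cut
  vertices merged at 1e-9 × bounding-box scale; zero-area slivers are
  kept after cutting (watertightness outranks sliver hygiene there).
* ICP: 2000 deterministic evenly-spaced sample vertices, tolerance 1e-7
  mm on RMS change, max 100 iterations, rejection floor 0.005 mm. The
  floor matters at convergence: with near-identical surfaces the median
  distance collapses and 3 × median would reject everything.
* The volume-target solve brackets the pit-depth scale so the surface
  stays strictly positive and uses `uniroot` at 1e-9 tolerance.
* Deviation tolerance 0.3 mm by default (the CBCT voxel size),
  colour map clamped at ±0.5 mm.
* Plane normals from three unordered points are oriented toward a
  caller-supplied occlusal reference; the CEJ plane normal points
  occlusally by construction.

## What passing tests do and do not show

The synthetic teeth are stylized: smooth star-shaped surfaces, exact
landmarks, no segmentation noise, no partial-volume effects, no enamel/
dentin distinction, and resorption that is smooth where real lacunae are
ragged. Validation on them demonstrates that the geometric pipeline is
*internally correct* — registration recovers known rigid frames to
fractions of a degree, cut volumes and signed deviations agree with
closed forms, and configured cohort effects are recovered within
sampling error. It does not demonstrate robustness to segmentation
artifacts, landmark placement error beyond the simulated 0.2 mm jitter,
or anatomical variation outside the template family. The problem sizes
used in the shipped validation (meshes of ≈ 2,600 vertices, cohorts of
10 patients per group for recovery runs, 20 per group for effect-size
checks) were chosen as the smallest sizes at which the recovery
tolerances are meaningfully exercised.

## Known limitations

* Percentage volume loss is an emergent quantity (drawn ΔV over the
  template's root volume), so its group means track the observed ones
  only as closely as the template volumes match real anatomy.
* The matching percentage depends on mesh sampling density in partially
  resorbed regions; it is comparable across teeth generated at the same
  resolution but not calibrated against any external software.
* Registration accuracy on real scans will be limited by segmentation
  consistency between timepoints, which the generator does not model.
* PLY input is ASCII-only; STL is read in both binary and ASCII dialects.
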