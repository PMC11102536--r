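---
title: "Measuring the accuracy of prescribed tooth rotations from superimposed dental models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the accuracy of prescribed tooth rotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Clear-aligner treatment plans prescribe, tooth by tooth, a rotation about
the crown's vertical axis. How much of that rotation is actually achieved
is a clinical question that can only be answered by comparing three
digital models of the same arch: the pre-treatment scan (T0), the virtual
setup exported from the planning software (T1), and the post-treatment
scan (T2). `rotometry` implements that comparison as a reproducible
pipeline and validates it on synthetic arches whose true rotations are
known.

The measured quantity is, per tooth,

* **prescription** — the signed angle between the tooth's landmark vector
  at T0 and at T1, projected onto the occlusal plane;
* **achieved movement** — the same angle between T0 and T2;
* **accuracy** — `achieved / prescription * 100` (percent);
* **performance** — `achieved - prescription` (degrees), summarised by
  direction classes (under below -1°, right within ±1°, over above +1°)
  and by the FOPE index, the frequency of |performance| in the ranges
  ≤1°, (1,2], (2,4] and >4°.

## Superimposition and landmark transfer

Angles are only meaningful in a common frame. The pipeline aligns each
comparison model onto T0 in two stages, mirroring standard inspection-
software practice:

1. **Three-point initialisation.** The cusp tips of the right and left
   first molars and the mesial incisal point of the right central incisor
   are matched across timepoints and a closed-form least-squares rigid
   fit (orthogonal Procrustes, reflections excluded) provides the
   starting transform. The same three T0 points define the occlusal
   reference plane, oriented so the crowns lie on its positive side.
2. **Global best fit.** Iterative closest point refinement, capped at 50
   iterations: moving vertices (subsampled to at most 5,000,
   deterministically) are paired with their exact nearest points on the
   fixed surface (point-to-triangle, ties to the lowest face index), and
   the rigid update is solved in closed form. The RMS distance is
   non-increasing over iterations; an early stop triggers when the
   improvement falls below 1e-7 mm, which cannot change the result
   materially and can be disabled (`tol = 0`).

Landmarks are placed once, on T0. To reproduce them on T1 and T2 without
re-picking, each segmented tooth is used as the moving set of its own
surface best fit against the full opposing model; the resulting per-tooth
rigid transform carries the T0 landmarks to their anatomical positions on
the other timepoint. The angle between the T0 vector and its transferred
counterpart, projected onto the occlusal plane, is the tooth's rotation.

**Per-tooth iteration budget.** The 50-iteration cap is part of the
protocol for the *global* fit. Applied to single teeth it is not enough:
canine, premolar and molar crowns are nearly rotation-symmetric, so
point-to-point ICP creeps toward the optimum slowly, and the larger the
rotation the longer the creep (about 2° residual after 50 iterations on a
10° rotation; rotations above 25° still carry ~0.5° residual after 300).
The per-tooth budget is therefore a separate setting,
`tooth_max_iterations = 1000` with `tol = 1e-9`, at which every noise-free
fixture converges to machine precision. This is a deliberate deviation
from reusing the global cap, made because the protocol does not specify
the internal budget of per-tooth fits.

**Moving-set supersampling.** Per-tooth fits use the submesh vertices
plus the face centroids as the moving set. With noisy meshes the rotation
error of a tooth fit is dominated not by the moving points but by which
parts of the rough target surface they interrogate; sampling the moving
surface more densely averages that roughness and roughly quarters the
angular bias in our experiments (vertex jitter 0.05 mm: mean absolute
angle error ~0.5° with vertices only, ~0.37° supersampled).

**Sign convention.** Both angles are measured signed (right-hand rule
about the occlusal normal) and then re-signed by the direction of the raw
prescription, so prescription is always ≥ 0 and a negative achieved value
means the tooth rotated opposite to plan. This makes
`achieved - prescribed` and the under/over classification well defined;
whether the original clinical workflow used signed or absolute angles for
this step is not documented, so the signed convention is this package's
interpretation. Wrong-direction rotations keep their negative accuracy
and classify as under-performance.

## The synthetic world

No raw scans ship with the package; the generator emulates the
statistical structure of a treated cohort so that every measurement-layer
claim can be tested against known ground truth.

* **Geometry.** Fourteen crowns (7 types per quadrant) are placed along a
  parabolic arch (half-width 27–28 mm, depth 38–40 mm) with 0.6 mm
  interproximal clearance. Each crown is a tapered superellipse prism
  with raised rim vertices at the cusp/incisal-corner positions that
  carry the tooth type's two landmarks (molars: disto-vestibular and
  mesio-lingual cusps; premolars: buccal and lingual cusps; incisors and
  canines: mesial and distal incisal points). Cusp heights are
  asymmetric (buccal above lingual, mesial above distal) so no crown is
  invariant under a 180° rotation — otherwise per-tooth registration
  would be ill-posed. Left and right quadrants are mirror images, as real
  dentitions are.
* **Rotations.** Prescribed magnitudes are drawn per tooth type from
  truncated normals whose means and SDs are the per-type cohort
  statistics the package is calibrated to (means roughly 5.5–11.5°, SDs
  3–11°), truncated below at the 2° clinical floor; the sign is a fair
  coin, since per-direction frequencies are not documented. The rotation
  axis is the occlusal normal through the tooth centroid, which makes
  the ground truth equal to the quantity the measurement defines.
* **Response.** Achieved = prescribed × accuracy factor + Gaussian noise
  (SD 0.5°). Accuracy factors are tooth-type normals with means 0.61–0.90
  (the calibrated per-type accuracies divided by 100), SD 0.3, truncated
  to (-0.5, 1.5) so under-, over- and wrong-direction performance all
  occur. The truncation shifts the factor means slightly; recovery tests
  therefore compare against the truncated-normal mean in closed form,
  not the raw configured mean.
* **Nuisance.** T1 and T2 receive independent whole-arch rigid pose
  perturbations (up to 5° / 5 mm), and every timepoint receives
  independent per-vertex Gaussian jitter (default SD 0.05 mm, a typical
  intraoral-scanner error scale). Landmarks are read off the jittered T0
  surface, as an operator would click them.

What the generator does **not** emulate: anatomical crown morphology,
gingiva and palate, translation/tipping/torque/extrusion, interproximal
contacts and collisions, or spatially correlated scanner artifacts. A
green recovery test therefore establishes the self-consistency of the
measurement chain under known rigid motions and white noise — not
equivalence with any commercial metrology tool on real scans.

## Outcome and statistics layer

Records below the 2° prescription cutoff are excluded (superimposition
error makes smaller prescriptions unreliable and spuriously accurate).
Group summaries report mean ± SD and Student-t 95% CIs for prescription,
achieved movement and accuracy. The tabulated "mean performance" is
`|mean(achieved - prescribed)|` — the absolute value of the mean
difference, which reproduces the arithmetic of the reference tables —
with `mean(|difference|)` exposed alongside as `mean_abs_perf`, since the
two are easily conflated and the latter is the stricter statistic.
Accuracy above 100% (over-performance) is kept as-is; it legitimately
inflates group means, which is exactly why the FOPE and direction
breakdowns exist.

Paired prescription-vs-achieved comparisons are gated by a Shapiro–Wilk
test on the differences at α = 0.05: paired t when normality is not
rejected, Wilcoxon signed-rank otherwise (zero differences dropped,
normal approximation with tie correction beyond 25 non-zero pairs). Both
branches are always computed so the gate is auditable. Method error uses
the Dahlberg statistic √(Σd²/2n) and a two-way absolute-agreement
single-measure ICC — the standard choice for operator agreement on
continuous measurements; the consistency form is available as an option.
The regression layer fits accuracy on prescription per tooth type,
pooling teeth across cases; within-patient clustering is ignored, which
the report metadata flags. No multiple-testing correction is applied
across tooth types, also flagged. The power helper inverts the
noncentral-t power function for the two-sided paired t test; two-sided
testing reproduces the conventional n = 24 at d = 0.6, α = 0.05,
power 0.80 (one-sided would give fewer).

## Numerical choices and edge cases

* Vertex welding at 1e-6 mm on STL input; facet normals are recomputed
  from winding and never trusted. Units are millimetres by convention —
  STL carries no unit metadata.
* Faces with mixed tooth labels are excluded from submeshes
  (conservative boundary handling; cusp landmarks are interior).
* A landmark vector numerically perpendicular to the occlusal plane
  (projection < 1e-9 mm) raises a degenerate-vector error; in
  `measure_case` such teeth are skipped and reported, and the case
  continues.
* Angles are kept at full precision throughout and only rounded at
  presentation.
* ICP correspondence ties (equidistant nearest points) break to the
  lowest face index, making every fit bit-reproducible; the closest-point
  search is exact (uniform grid with expanding-shell pruning, verified
  against brute force).
* Sub-seeds fan out from the global seed by a stable string hash of
  (seed, stage, case, arch), so enlarging a cohort never reshuffles
  existing cases.

## Known limitations

Equivalence with commercial inspection software is not claimed — only
recovery of known transforms on synthetic fixtures. Accuracy statistics
on the default synthetic cohort reproduce the calibrated per-type means
by construction and say nothing about any real cohort. The ±1°
right-performance band and the 2° cutoff are clinical conventions, not
statistical constants; both are parameters. The three-point
initialisation assumes the alignment landmarks can be identified on all
timepoints; the synthetic emulation uses shared mesh topology for this,
which real scans do not offer — real use requires picking the three
points on each model.
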