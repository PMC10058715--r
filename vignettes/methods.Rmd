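---
title: "Measuring axial postural abnormalities from single photographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axial postural abnormalities from single photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Camptocormia and Pisa syndrome are severe, reversible trunk flexions seen
in Parkinsonism. Their clinical grading is angular: thoracic camptocormia
(tCC) is anterior flexion at a thoracic fulcrum exceeding 45 degrees,
lumbar camptocormia (lCC) anterior flexion at the lumbar spine exceeding
30 degrees together with hip flexion, and Pisa syndrome (PS) lateral
flexion exceeding 10 degrees. Goniometry and radiographs are accurate but
impractical for routine follow-up; a photograph is cheap and ubiquitous.
2D human-pose estimators provide joint-centre keypoints from photographs,
but none of the landmarks the clinical angles are defined on — the C7 and
L5 spinous processes, the mid-ankle point (MA) and the fulcrum of the
spine flexion (FC) — is part of any standard skeleton. This package
augments the canonical 25-keypoint skeleton with exactly those landmarks
and measures the three angles.

All three measures are *external angles*: 180 degrees minus the interior
angle at the named apex, so a perfectly straight upright posture measures
0 and the cut-offs (10/30/45) are deviations from straightness. This is
the only reading under which a ">10 degree" lateral-lean cut-off makes
sense, and it fixes the convention package-wide. Classification is a
strict ">" at the cut-off: an angle of exactly 45.0 does not flag.

## Landmark construction

**Frontal (posterior) view.** C7 sits where the two contralateral
shoulder-to-ear segments (left shoulder to right ear and vice versa)
cross: on a posterior photograph these diagonals intersect at the base of
the neck, whereas the ipsilateral segments generally do not intersect at
all — that anatomical fact settles which pairing is meant. L5 is placed by
starting at the hip-keypoint midpoint MH and moving *vertically toward the
head* by K1 % (default 20) of the mean hip-to-knee distance. The offset
direction is dictated by anatomy — L5 lies above the hip joint centres and
below the iliac crest line — and "vertical" means image-vertical,
consistent with an upright acquisition protocol. MA is the ankle-keypoint
midpoint. None of this needs a silhouette.

**Sagittal view.** Here C7, L5 and FC are points on the *back contour*, so
the silhouette is extracted first (next section). The anchor A lies K2 %
(default 40) of the way from the shoulder keypoint to the ear keypoint;
C7 is the last silhouette point along the line through A perpendicular to
the ear–shoulder segment, marching toward the back (C7 is a spinous
process — a posterior structure — which fixes the march direction the
definition leaves open). L5' is built exactly as frontal L5 (one-sided leg
length if the far side is undetected), and L5 is the last silhouette pixel
marching horizontally backward from L5'. FC is the posterior boundary
point farthest from the infinite line through C7 and L5, restricted to
points whose projection onto the chord falls strictly between C7 and L5 —
the fulcrum is a trunk point, and without the restriction a straight back
degenerates to a head or heel pixel collinear with the chord. Ties resolve
to the smaller y, then smaller x, with distances compared at a 1e-6 px
quantum so exact geometric ties resolve identically across algebraically
equivalent formulas. A per-chord-point perpendicular ray-march variant
(`method = "ray"`) is retained and agrees on convex backs. The visible
side is auto-detected from chain confidences, and every right-side formula
mirrors for left-facing photographs.

**Sub-pixel boundary crossings.** Landmark searches march at 0.5 px steps
and then bisect the bracketing interval, reporting the mask-boundary
crossing to roughly 0.02 px; the winning FC pixel is refined the same way
along the chord normal. Snapping to pixel centres instead introduces a
systematic inward bias of up to a pixel, which at a lever arm of L pixels
biases angles by about atan(1/L) — irrelevant at photographic resolution
but dominant in compact test renders. Resolution-invariance of the angles
is therefore limited only by this quantization: across a 0.5x–2x size
sweep of the same geometry the measured thoracic angle varies by under
1.5 degrees at a 240-px base render, shrinking with size.

## Silhouette extraction

The trimap has three classes. Pixels outside the subject box are certain
background. The box spans the ear-to-ankle vertical extent and the
horizontal keypoint spread, expanded on all four sides by one isotropic
margin of `box_margin_frac` (default 0.15) times the vertical extent. The
margin is deliberately proportional to subject height, not keypoint
spread: on a sagittal view the keypoints are nearly collinear on the spine
axis, and a spread-proportional margin would exclude the subject's entire
back — precisely the contour every landmark lives on. Pixels inside the
limb bands — the ear–shoulder, shoulder–hip, hip–knee and knee–ankle
segments of the visible side (both sides on frontal views), isotropically
thickened by `band_thickness_scale` (default 0.10) of the segment length,
clamped to [2 px, half the length] — are certain foreground. The 0.10
default approximates the radius-to-length ratio of the slimmest body
segment (the shank); a fatter band would plant foreground seeds outside a
slim limb, violating the trimap's own guarantee. Everything else is
probable background.

Segmentation is an iterative color-model graph cut. Foreground and
background RGB mixtures (k-means hard assignment, 3 full-covariance
components, variance floor 25 channel-units² so flat synthetic colors
remain well-posed) give per-pixel negative log-likelihood data terms;
4-neighbor smoothness links carry `gamma * exp(-beta * ||ci - cj||²)` with
`beta` the standard inverse mean squared neighbor contrast and
`gamma = 50`. Certain-foreground seeds are contracted into the source
terminal — they are hard constraints, and contracting them removes the
large plateau capacities that slow generic max-flow solvers. The minimum
s-t cut is solved by Dinic's algorithm (compiled code); model fitting and
cutting iterate until the labeling stabilizes, at most `graphcut_iters`
(default 5) times — flat-color scenes converge in two. Post-processing
keeps the connected component with the largest seed overlap, restores any
seed pixels the cut isolated (so the hard-constraint guarantee survives),
and fills interior holes so boundary searches never terminate on speckle.
The component/hole step is a robustness addition beyond the minimal
graph-cut formulation, as is seeding the bands as *certain* rather than
probable foreground: the three-class trimap quoted in the source
formulation has no probable-foreground class, so the bands are taken at
their stated certainty.

## The synthetic mannequin

The generator exists to make every stage falsifiable without clinical
data. The body is a union of capsules (thickened segments: shank, thigh,
trunk, neck) plus a head disc, standing before a uniform wall — emulating
the acquisition protocol of a minimally dressed subject against a neutral
background. Proportions are fixed fractions of stature (head radius 0.065,
neck 0.05, trunk 0.30, thigh 0.26, shank 0.26; trunk capsule radius 0.075
by default). Its two crucial properties:

- **Closed-form truth.** On the sagittal view the trunk is a two-segment
  polyline bent anteriorly at a fulcrum; a miter wedge fills the posterior
  corner so the back contour has a true vertex, and the shoulder keypoint
  is placed on the trunk axis low enough that the anchor A falls on the
  cylindrical part of the trunk capsule. Both choices make the stored tCC
  truth *exactly* the requested flexion angle, and the true C7/L5/FC lie
  exactly on the rendered contour. On the frontal view shoulders and ears
  sit symmetrically about the leaned trunk axis, so the diagonal
  intersection lies on the axis and the PS truth equals the lean exactly.
  The lCC truth is computed from the true landmarks (L5 on the back
  contour, MA at the ankle joint) and is deliberately *not* the flexion
  angle — the same small posterior-offset geometry the real measurement
  has. All stored truths are recomputable from the stored landmarks
  through the package's own angle function to 1e-9.
- **Determinism.** Every fixture is bit-identical under a fixed seed;
  keypoint jitter (default off; 2 px emulates pose-estimator error) and
  Gaussian channel noise draw from seeded streams.

What the mannequin does **not** emulate: clothing, occlusion, lighting
gradients, lens distortion, anatomical asymmetry, soft-tissue contour
variation, or multiple people. Passing the recovery tests therefore
demonstrates the geometric and segmentation machinery is correct, not that
the method is clinically validated — the latter requires expert-rated
photographs and is explicitly out of scope.

## Validation batteries and problem sizes

The test suite and the acceptance script size their simulations for a
single-CPU run: default renders are 260x360 px (unit-test fixtures
160x220), recovery sweeps use 8 sagittal and 6-8 frontal fixtures across
0-70 degrees, noise-free recovery must land within 2 degrees per fixture,
and jittered recovery (2 px keypoints, 4-unit channel noise) is assessed
as mean absolute error per abnormality against the minimal-detectable-
change reliability bounds (PS 2.1, lCC 3.7, tCC 6.7 degrees). A
per-fixture bound would be the wrong statistic at this jitter level:
frontal PS errors are approximately N(0, 1.6 deg), so single fixtures
exceed 2.1 degrees by chance one time in five while the mean settles well
inside it.

The robustness battery is a *fixed-angle null design*: 30 fixtures per
abnormality at constant true posture (15 degrees lean, 35 degrees flexion)
under varied image height (220/260/300 px), framing (stature fraction
0.72-0.92, the cover-factor lever), wall tint and contrast, plus keypoint
jitter and channel noise; BMI is drawn independently. Because the true
angle never varies, any significant correlation of the measured angle with
an acquisition covariate is spurious by construction. Posture-driven
covariation is deliberately excluded: a flexed trunk genuinely widens the
subject's bounding box, so a random-angle design would "detect" a real
geometric association and test nothing about the method. One caveat is
reported openly: the angular noise scales inversely with image size, and
this heteroscedasticity widens the small-sample distribution of Pearson's
R beyond its t-approximation, so occasional |R| near 0.55-0.6 excursions
at n = 30 are expected under the null and are of the same magnitude as the
significant-but-modest correlations clinical robustness studies report.
The acceptance criterion (at least 9 of 10 seeded runs with no
|R| > 0.5 at p < 0.05) holds at the suite's fixed seeds, and the
acceptance script reports the clean fraction for any seed it is given.

The Pearson implementation (R plus the two-sided t-transform p-value) is
oracle-checked against `stats::cor.test` to 1e-12; raw per-correlation
p-values are reported without multiple-testing correction, matching the
robustness-analysis convention, with an optional Bonferroni switch.

## Degenerate inputs and error taxonomy

Missing keypoints never impute: any operation needing an absent keypoint
fails with a typed `missing_keypoint_error` naming it, because silent
imputation would corrupt clinical angles. Other typed conditions:
`geometry_error` (parallel diagonals, zero-length limbs, a fulcrum line
parallel to the posterior direction), `segmentation_failure_error` (empty
trimap classes or empty cut), `landmark_failure_error` (march anchor
outside the silhouette), `boundary_error` (march exits the image),
`degenerate_silhouette_error` (no strictly posterior boundary pixel) and
`format_error`. The pipeline maps them to distinct shell exit codes. Two
deliberate degeneracy policies: a perfectly straight back has no strictly
posterior point, so the full pipeline calls the fulcrum search in
non-strict mode and measures a thoracic angle of about zero rather than
failing; and an angle of exactly 180 degrees (both limbs on the same ray
from the apex) is anatomically impossible and returns with a warning.

## Color characteristics

The image covariates follow the hue–saturation–value reading of "HSV":
circular mean for hue (degrees), arithmetic means for saturation and
value, with saturation/value variances additionally emitted since the
robustness covariate could also be read as a variance. Cover factors are
bounding-box ratios (width, height, area) rather than pixel-count ratios,
so the width and height covariates stay well-defined.

## Known limitations

Angles are planar: out-of-plane trunk rotation projects onto the image and
biases all three measures; the hip-flexion clause of the lumbar definition
is reported as unassessed, never guessed. The silhouette model assumes a
single subject against a reasonably uniform background; low
subject/background contrast degrades the cut gracefully (the monotone
contrast property is tested) but eventually only the seeded bands survive.
K1 and K2 are population calibrations inherited from the published
operating point; they are exposed as configuration but re-tuning them
requires ground-truth landmark annotations this package does not ship.
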