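---
title: "Retinal vessel morphometry with fundusgeom: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel morphometry with fundusgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusgeom)
```

## What the package measures

`fundusgeom` quantifies the geometry of the retinal vasculature on
45-degree disc-and-macula-centered fundus photographs, the way such
measurements are used in case-control studies of retinal vein occlusion
(RVO).  Everything is expressed relative to the optic disc diameter, DD,
so that measurements are comparable across cameras and eyes:

* **DD** — the diameter of the *smallest circumscribed circle* of the
  optic disc boundary.  The disc is usually slightly elliptical; the
  circumscribed-circle rule makes DD the major axis, a deterministic and
  rotation-invariant summary.
* **Relative arteriolar / venular caliber** — the mean arteriolar (or
  venular) diameter measured in the annulus between 1.0 DD and 1.5 DD
  from the disc *center*, divided by DD.  Dimensionless, typically around
  0.06 and 0.08.
* **AVR** — the arteriolar-to-venular ratio.  By construction
  `AVR = rel_arteriolar / rel_venular`, identically equal to the ratio of
  mean arteriolar to mean venular diameter; the package computes it from
  that identity, so the three reported numbers are always consistent.
* **Branching angle** — the first angle subtended between the two
  daughter vessels at a bifurcation, reported in degrees and stratified
  by vessel class (artery/vein) and disc-relative quadrant
  (superior/inferior x nasal/temporal, with the nasal direction depending
  on eye laterality).

Alongside the image pipeline, two small calculators handle tabular
MRI/clinical data: the optic nerve subarachnoid space width,
`ONSASW = (mean ONSD - mean OND) / 2` at 3, 9 and 15 mm behind the globe
(a non-invasive surrogate of retrobulbar cerebrospinal fluid pressure),
and the trans-lamina cribrosa pressure difference `TLCPD = IOP - CSFP`.
CSFP is deliberately an *input*: the package does not estimate it from
anthropometrics, because any such regression would be an external model
with its own validity conditions.

## Pipeline stages and their assumptions

**Preprocessing** (`preprocess`). Four stages: circular field-of-view
(ROI) extraction (largest bright connected region; a constant image falls
back to the full frame), denoising (3x3 median plus a light Gaussian,
sigma 0.5 px), min-max normalization to [0, 255] inside the ROI, and
unsharp-mask enhancement (gain 0.5) inside the ROI only.  Output
dimensions always equal input dimensions.

**Vessel segmentation** (`segment_vessels`). Segmentation is a pluggable
backend behind a registry, so a learned segmenter can be dropped in
without touching the geometry code; no network weights ship with the
package.  The included `"baseline"` backend is classical: a dark top-hat
(grayscale closing with a 17 px disc brush minus the image) isolates dark
structures thinner than the brush and cancels the step edge around the
bright disc; a multiscale Hessian vesselness (sigmas 1–4 px, beta 0.5)
responds to dark ridges; hysteresis thresholding (low 0.30, high 0.35 of
the per-image maximum) keeps weak ridge pixels only when connected to
strong ones; components under 60 px are removed.  Because the vesselness
map is normalized per image, a minimum absolute top-hat depth (30 units
on the 0-255 scale, after smoothing) is also required — otherwise a
vessel-free image would rescale noise into "vessels".  The `"truth"`
backend passes a supplied mask through and is used to isolate geometry
errors from segmentation errors in validation.

**Artery/vein discrimination** (`classify_arteries_veins`). Veins run
darker than arteries on fundus photographs (an `invert` flag covers the
opposite convention).  Each centerline edge gets the median image
intensity under its chain; edges are grouped into connected trees; tree
median intensities are split into two classes by an exact 1-D two-means
scan (deterministic, unlike a randomly initialized k-means); the darker
class is labeled vein.  Labels are therefore constant along each
connected tree by construction, the topological-consistency rule.

**Optic disc** (`locate_and_segment_disc`). Localization: largest
connected blob above the 98.5th intensity percentile.  Segmentation: the
image is first closed with a 17 px brush to erase vessels, then resampled
in polar coordinates around the candidate center (1 degree angular step,
0.5 px radial step); per angle the boundary is the outermost strong
(>= 40% of the strongest) negative radial derivative — the bright-to-dark
transition — refined to sub-pixel by a parabolic fit around the
derivative extremum, which sits exactly on the boundary of a smoothed
step.  The radius profile is median-smoothed circularly (window 9), and
center and DD come from the smallest enclosing circle (Welzl's algorithm,
deterministic) of the unwrapped contour.  A blob touching the frame flags
the result `low_confidence` rather than silently truncating, and a
user-supplied contour can override tracing entirely (manual disc-margin
correction).

**Centerline** (`extract_centerline`). Topology-preserving Guo-Hall
thinning reduces the mask to a 1 px skeleton.  Plain morphological
erosion does not leave a connected medial line, and the more common
Zhang-Suen scheme leaves two-pixel-wide staircases on 45-degree vessels
that corrupt junction detection — Guo-Hall avoids both.  Skeleton pixels
with three or more neighbours (junctions, clustered with their immediate
neighbourhood) and line ends become graph nodes; ordered 8-connected
chains become edges; terminal spurs shorter than 5 px are pruned
iteratively; micro-loops and interior degree-2 artifacts are spliced
away.  Degree-3 nodes are bifurcations; degree >= 4 nodes are
artery/vein crossings and are excluded from angle analysis but tallied.

**Diameters** (`measure_diameters`). At each chain point the tangent
comes from centered differences over +/-3 chain pixels; the diameter is
the chord along the orthogonal between the two sub-pixel half-maximum
crossings of the mask (bilinear samples every 0.25 px, linear
interpolation to the 0.5 level).  Points whose normal leaves the frame
are skipped and tallied.  Near junctions the vessel silhouettes fuse into
a bulge, so points closer to a junction-side chain end than
max(2 px, 1.2 x their own measured diameter) are excluded; making the
margin proportional to the diameter (rather than the fixed 2 px margin
one might first write down) is what keeps the caliber summary invariant
when the same retina is sampled at twice the resolution.

**Annulus summary** (`annulus_calibers`). Points with radial distance in
[1.0, 1.5] DD from the disc center are kept.  The bounds are measured
from the disc *center* — the literal reading of the zone definition —
although part of the literature measures from the disc margin; a `zone`
argument accepts alternative bounds.  Each vessel's retained run is split
into at least 10 equal-arc sections, section means are averaged per
vessel and vessels averaged per class, each vessel weighted equally.  Two
scale-free guards stabilize the summary: runs shorter than 0.1 DD (sliver
crossings of the annulus boundary) are dropped, and points wider than
1.5x their run median (oblique chords through a junction caused by a
centerline kink) are discarded — within one run the true width is
near-constant, so such points are unambiguous artifacts.  When a class is
absent from the annulus the summary is flagged incomplete and AVR is NA.

**Branching angles** (`branching_angle`). At a degree-3 node the parent
is the incident edge with the largest mean diameter (tie-break: longer
edge).  Each daughter direction is a total-least-squares line fit over
chain pixels from 3 px to 18 px from the node, oriented away from it.
The first 3 px are skipped because thinning a wide junction biases the
first skeleton pixels toward the bisector; on rendered ground truth this
skip reduces the mean angle error from about 5 degrees to well under 2.
Daughters shorter than the probe are fitted on what exists and flagged.

## The synthetic generator: what it emulates and what it does not

No raw images or per-patient records from the motivating study are
available, so validation rests on a simulator with exact ground truth.

`generate_vessel_tree` grows straight, tapering vessel trees outward from
the disc margin.  Bifurcation apex angles are drawn uniformly from a
configurable range and recorded exactly — daughters are placed
symmetrically about a jittered bisector, so joint rotation never changes
the recorded angle.  A rejection step keeps non-adjacent segments one
vessel radius plus clearance apart, guaranteeing the rendered mask
contains exactly the recorded bifurcations and no crossings.  Defaults
(2 trees per image, depth 2, apex angles 40-110 degrees, root widths
9-12 px with taper 0.67, arteries 0.8x vein width, DD 60-100 px on a
512 px field) bracket the widths 4-12 px and angles that the validation
battery sweeps.  `render_fundus` strokes each segment with an
anti-aliased circular brush of diameter equal to the truth width — so the
half-coverage contour sits exactly half a width from the centerline and a
distance-transform oracle recovers the width to 0.5 px — and renders the
disc as a bright ellipse with aspect 0.9-1.0 (exercising the
circumscribed-circle rule), veins darker than arteries by the
`av_contrast` parameter (default 30 of 255), Gaussian pixel noise
(sd 5 of 255, a realistic camera-noise level).

What the simulator does **not** emulate: curvature and tortuosity,
crossing vessels, central light reflex, pigmentation texture, pathology
(hemorrhage, edema), or uneven illumination.  Passing the synthetic
battery therefore shows that the geometric measurement chain is correct
on images whose difficulty is dominated by discretization, noise, and
junction topology — not that the baseline segmenter matches a trained
network on clinical photographs.

`generate_cohort` simulates the paired case-control structure: per
subject one affected and one contralateral normal eye, in BRVO (branch)
and CRVO (central) occlusion groups of 34 and 25 subjects by default,
every per-eye variable drawn from the published group summaries
(mean +/- SD per group x eye-role cell), truncated at the physiologic
floor 0.  Hypertension duration is zero-inflated log-normal with the
zero fraction and log-scale chosen to match the published medians and
interquartile ranges (BRVO: median 0, 75th percentile 4.5 y, giving
P(0) = 0.5 and a log-normal median of 4.5; CRVO: median and 75th
percentile both 0, P(0) = 0.8).  BMI is derived as weight/height^2 and
AVR as relA/relV, so the defining identities hold in every record (the
published BMI and AVR summaries are then matched only approximately —
the identities were judged more important than the marginal moments).
Eyes are exchangeable within subject apart from the affected-eye effect:
no inter-eye correlation is modeled because none is published; paired
tests on simulated data are therefore conservative relative to real
paired eyes, which correlate positively.  Columns are drawn
independently for the same reason.  An `effects = FALSE` switch collapses
all cells to the BRVO-contralateral parameters for null calibration.

## Statistical workflow

Test selection follows the usual clinical-paper battery, made explicit
and logged: normality by Shapiro-Wilk below n = 50 and Lilliefors
(Kolmogorov-Smirnov with estimated parameters) above; variance
homogeneity by Levene's test centered at the mean (the SPSS convention);
the two-group test is then pooled t, Welch t, Mann-Whitney U, paired t,
or Wilcoxon signed-rank as the gate and pairing dictate, two-sided at
alpha 0.05 with no multiplicity correction — matching the analysis style
of the studies this reproduces, and documented as such.  The 2x2
chi-square is Pearson *without* continuity correction: on the published
sex table (18, 16; 16, 9) the uncorrected statistic reproduces the
printed 0.722 where the Yates-corrected value (0.340) does not.
Logistic models are maximum-likelihood fits (IRLS via `glm`, tolerance
1e-8, up to 100 iterations) with Wald 95% intervals; odds ratios for the
dimensionless calibers are reported per 0.01 caliber increment so they
live on an interpretable scale.  Perfect separation is detected (near-zero
deviance or runaway coefficients) and reported as an error naming the
separating covariate; listwise deletion counts are reported.  The
analysis unit is the eye, with subject clustering ignored — matching the
reproduced models; this understates standard errors when both eyes of a
subject enter the same model and is flagged as a limitation.

Two adjusted models mirror the study design: (a) CRVO-affected vs
BRVO-affected eyes with the imaging markers adjusted for age,
hypertension duration, BMI and IOP; (b) CRVO affected vs contralateral
eyes adjusted for IOP.

## Numerical and testing choices

* Coordinates are 0-based pixel centers, x rightward, y downward;
  contours closed and counter-clockwise.
* All seeded generators accept an integer seed and restore the caller's
  RNG state; the pipeline fans a single global seed into per-stage
  substreams keyed by stable stage names, so stage order cannot change
  results.
* Welzl's enclosing-circle implementation processes points in input
  order (no shuffle): deterministic, and still fast at contour sizes
  (360 points).
* The validation battery sizes were chosen to keep a full run on one CPU
  in minutes: 20 rendered images for geometry recovery, 5000/2000
  replicates for type-I calibration, n = 5000 for logistic recovery,
  n = 10^4 per group for simulator moments.
* The simulator-moment check compares 64 cell means against their
  targets at once; at 3 SE per cell a run of 64 independent checks fails
  spuriously about one time in six, so the test asserts that at least
  95% of cells sit within 3 SE, none beyond 4 SE (a Bonferroni-style
  familywise bound), and the mean |z| stays below 1.5.
* The end-to-end pattern check (venular-caliber effect present in CRVO,
  absent in BRVO, venular odds ratio above 1) runs five simulated
  cohorts of 200 subjects per group: the BRVO venular difference in the
  published summaries is a genuine but tiny -0.001, which a paired test
  at that size correctly misses only about 80% of the time, so a
  majority criterion over replicates is the stable formulation of
  "reproduces the pattern".
* Scale equivariance is verified by re-rendering the same ground-truth
  geometry on a twice-finer grid, the clean analogue of imaging the same
  retina at twice the resolution; nearest-neighbour upscaling of an
  already-rendered binary mask would add its own 2 px boundary
  quantization and contaminate the property under test.

## Known limitations

The baseline segmenter is a classical filter chain tuned for the
simulator's contrast regime; on clinical photographs a trained backend
should be plugged in.  The A/V rule assumes at least two vessel trees
with usable intensity contrast; a single tree falls back to a
background-relative heuristic.  Calibers assume the occluded quadrant's
vessels are measurable; the package does not attempt to detect or mask
pathology.  ONSASW averaging of two observers is linear either way
(before or after the subtraction), so the loader accepts either
convention.  TLCPD requires a user-supplied CSFP.
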