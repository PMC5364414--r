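---
title: "Landmark morphometry of the posterior maxillary sinus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark morphometry of the posterior maxillary sinus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusmorph)
```

## The clinical problem

The maxillary sinus often extends downward into the alveolar process (the
"alveolar recessus"), reducing the residual ridge height available for
dental implants in the posterior maxilla. Pre-prosthetic planning therefore
hinges on two quantities read from a coronal CT slice at the
zygomaticoalveolar crest: how deep the sinus floor dips below the hard
palate (**sinus depth**, SD) and how much bone remains between the sinus
floor and the alveolar crest (**alveolar height**, AH). A third quantity,
the **sinus opening angle** (α) at the deepest floor point between the two
sinus walls, relates to the difficulty of membrane elevation during sinus
augmentation.

`sinusmorph` implements a complete measurement pipeline for these
quantities from manually placed landmarks, a quartile-based three-class
sinus classification built on sinus depth, the associated group
comparisons, and a synthetic-cohort generator that makes every stage
testable end to end.

## Measurement model

Each patient image carries twelve labelled landmarks. P1/P2 sit on the
ends of a digital ruler of known physical length; the scale in mm/px is
the ruler length divided by their pixel distance, estimated per sheet.
P3–P7 describe the right side (lateral wall top, deepest floor point,
medial wall top, alveolar tip, palatal point) and P8–P12 the left side
symmetrically. Coordinates follow the raster convention: origin top left,
y increasing inferiorly.

The palatal reference line runs through P7 and P12; its unit normal is
oriented toward image-inferior. The three statistics per side are

* **SD** — the signed perpendicular distance of the floor point from the
  palatal line, positive below (inferior to) the palate. The sign
  convention makes "floor above the palate" negative, which is what class
  I captures; a depth of exactly 0 belongs to class II.
* **AH** — the Euclidean distance between the alveolar tip and the floor
  point. The definition of this "difference between" two points is
  genuinely ambiguous (straight segment vs. projection onto the palatal
  normal); both are implemented (`alveolar_height(method =)`) and the
  Euclidean segment, which is what a caliper on the image would give, is
  the default.
* **α** — the angle at the floor point subtended by the two wall-top
  points, computed as `atan2(|cross|, dot)` rather than `acos` of the
  normalized dot product, which loses precision near 0° and 180°. Angles
  of exactly 0 or 180 (collinear rays) are rejected as degenerate rather
  than silently returned.

All three statistics are invariant under rigid motions of the landmark
set and under calibration-scale changes; the test suite asserts this on
randomized transforms to 1e-9.

The pipeline orients the palatal normal by the raster inferior direction
(+y) instead of pointing it at the alveolar tips: in a deep class I
configuration with a short ridge the tip can legitimately sit *above* the
palatal line, and a tip-based hint would silently flip the sign of every
depth on the sheet. The standalone `palatal_axis()` keeps an explicit
orientation hint so the geometry is usable outside raster conventions.

## Replicate consensus and the 2 mm rule

Every landmark is placed four times (two observers × two sessions). The
consensus location is the coordinate-wise median; an even count uses the
midpoint of the central order statistics. A replicate deviating more than
2 mm (Euclidean, from the median) marks the landmark as a gross
measurement error. The original protocol resolved such flags by human
re-adjudication; a pipeline cannot do that, so the mechanical stand-in is:
drop replicates beyond the threshold, recompute the median from the
survivors, and record how many were used. If fewer than two replicates
survive while others were discarded, the point is reported *unresolved*
and every measurement depending on it is excluded with a logged reason —
the pipeline never invents a coordinate. The deviation metric (distance to
the median rather than pairwise distances or deviations of derived
measurements) is a design choice; the threshold is a parameter
(`consensus_threshold_mm`) with default 2.

## Quartile classification

Class limits are the first and third quartiles of signed sinus depth,
estimated with the linear-interpolation quantile (type 7, the default of
R, in which the original analysis was carried out), computed per stratum
(dentate vs. edentulous), rounded to the nearest integer millimetre with
halves away from zero (so 0.3 → 0, 0.0 → 0, 5.9 → 6, 6.2 → 6). When all
strata round to the same pair the classification is *consistent* and the
shared limits (0 and 6 mm in the reference cohort) apply; otherwise the
pooled rounded quartiles are used and the disagreement is reported.
Classes are: I below the lower limit (floor above the palate), II inside
the closed interval, III strictly above the upper limit. The closed upper
boundary follows the classification statement "0–6 mm below" for class II;
`boundary = "open_upper"` is available because the boundary sinus is
clinically arguable either way. Sinuses are classified independently — a
patient's two sides may differ in class.

With *unrounded* limits a continuous sample splits 25/50/25 by
construction (up to interpolation off-by-one); with rounded limits the
proportions are only approximate. Both modes are exposed
(`use_rounded`).

## Group comparisons

`one_way_anova()` and `additive_anova()` wrap least-squares linear models
with sequential (type I) sums of squares — `anova(lm(y ~ a + b + c))` —
because that is the behaviour of the environment in which the reference
analysis was run. The multi-factor models are additive single-response
ANOVAs, not multivariate-response models, and the package documents them
as such. Constant factors and rank deficiencies raise errors naming the
aliased term instead of silently dropping it. Sinuses are treated as
independent observations even though patients contribute two each;
`patient_id` is retained in the cohort table so a clustered sensitivity
analysis remains possible downstream.

## The synthetic cohort generator

No landmark data were deposited with the study this package
operationalises, so validation rests on a generator whose defaults encode
the reported cohort structure:

* **Class structure**: class probabilities (0.25, 0.50, 0.25).
* **Sinus depth**: a three-component mixture whose supports partition at
  the class boundaries — a negative half-normal below 0, a truncated
  normal centred at 3 mm on [0, 6], and a positive half-normal above
  6 mm. A single normal cannot have mean ≈ 3, SD ≈ 5.4 *and* quartiles at
  0 and 6; the mixture satisfies the quartile constraint exactly by
  construction, and the two half-normal spreads are calibrated
  (closed-form moment equations solved by `uniroot`) so the pooled mean
  and SD hit their targets (default 3.0 ± 5.4 mm; per-gender overrides
  such as the female 3.1 ± 5.44 mm are supported). The shape between the
  quartiles is not identifiable from the published summaries; the
  truncated-normal middle component is a modelling choice.
* **Alveolar height**: truncated-normal (> 0) per class with means
  13.0/7.7/5.44 mm and SDs 4.9/2.9/2.52 mm, plus an additive dentition
  offset (default ±1.3 mm, reproducing the ≈2.6 mm dentate–edentulous
  gap while leaving class means unchanged in balanced cohorts). The
  stated mean is the mean *of the truncated distribution* — the location
  parameter is calibrated accordingly, so truncation never biases group
  means.
* **Opening angle**: truncated normal on (0, 180)° per class,
  113.87 ± 17.56, 101.19 ± 13.32, 90.13 ± 10.73.
* **Age**: normal 57.5 ± 16.5 years truncated at 18 (the inclusion
  floor).

`sampling = "random"` draws everything independently (seeded).
`sampling = "deterministic"` replaces draws by midpoint quantiles
u = (i − ½)/n of the same distributions within each gender × dentition
cell — a stratified design whose sample moments match the model to a few
thousandths (midpoint-rule error), so distributional recovery can be
tested without Monte-Carlo slack. In deterministic mode the within-class
AH/angle ranks pair *inversely* with depth rank: deeper sinus extension
goes with smaller ridge height and narrower angle, the trend seen across
classes, and the pairing keeps every virtual patient anatomically
coherent (no alveolar tip above the palate at extreme depths).

The renderer inverts the measurement geometry exactly: palatal line at a
configurable tilt, floor points at the true signed offset, tips at the
true Euclidean distance along the inferior normal, wall points on rays
subtending exactly the true angle and opening superiorly, ruler points
consistent with the scale (default 0.5 mm/px, a typical coronal CT
in-plane resolution). Replicate sheets add isotropic Gaussian noise
(default SD 0.3 mm, a plausible manual-placement precision at sub-pixel
scale) to anatomical landmarks. The ruler endpoints get their own noise
term defaulting to 0: a digital ruler is a rendered graphic with
unambiguous ends, and noisy ruler clicks would inject a coherent
calibration error proportional to a landmark's distance from the image
origin — a property of the simulation, not of the instrument. Gross
errors displace one replicate of an anatomical landmark by a fixed
magnitude (default 5 mm) in a random direction at a configurable rate, so
the consensus flag rate can be checked against the injected rate.

At zero noise, rendering then measuring is the identity on (SD, AH, α)
to floating-point accuracy for any tilt and scale — the core round-trip
invariant of the test suite.

What the generator does **not** emulate: real bone-contour ambiguity
(landmark error here is isotropic and homogeneous), correlation between
the two sides of a patient beyond shared covariates, within-class
depth–AH correlation (a hook exists via the deterministic pairing only),
sinus pathology, and any 3-D structure. Passing tests therefore validate
the *pipeline arithmetic and bookkeeping* under the reported cohort
structure, not the clinical measurement process itself.

## Numerical and design notes

* Quantiles: type 7 everywhere; other estimators can be compared through
  the raw per-stratum quartiles that `class_limits()` always reports.
* Rounding: half away from zero, implemented directly
  (`sign(x) * floor(|x| + 0.5)`) because base `round()` rounds halves to
  even.
* Noise propagation: sinus depth subtracts two consensus-noised
  quantities (floor point and palatal line). With 0.3 mm landmark noise
  the median-of-4 consensus has SD ≈ 0.164 mm per point, giving a depth
  error SD ≈ 0.23 mm — about 95 % of sinuses within 0.5 mm and 99 %
  within 0.75 mm of truth, which is what the suite asserts.
* Deterministic mode needs no seed; random mode funnels all randomness
  through the spec/render seeds, and identical inputs yield
  byte-identical pipeline outputs.
* Problem sizes in the suite mirror the reference cohort where the claim
  depends on n (788 sinuses, 19 200 landmark placements, 100 seeded
  replicate cohorts for the significance pattern) and use 10–50 virtual
  patients elsewhere.
* The significance-pattern check asks each model to behave as expected
  (alveolar height rejecting on class and dentition at p < 0.01; depth
  not rejecting on dentition or gender at p > 0.05) in at least 95 % of
  100 seeded cohorts, *per term*. A joint per-cohort requirement would be
  unattainable by construction: two independent 5 %-level null tests both
  accept with probability ≈ 0.90.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_patients = 25, seed = 1)
truth <- simulate_truth(spec)
landmarks <- render_landmarks(truth, render_spec(noise_sd_mm = 0.3,
                                                 gross_error_rate = 0.02,
                                                 seed = 1))
out <- run_pipeline(landmarks, truth_metadata(truth),
                    out_dir = "sinus-out")
cohort_summary(out$cohort, "alveolar_height_mm", "sinus_class")
```

The run log reports sheet counts, flagged landmarks, exclusions with
reasons, the class limits with their raw quartiles, and the class
distribution; `out$models` holds the term-wise ANOVA table.

## Limitations

The package measures 2-D coronal-slice geometry only — the palatal
"plane" is a line here, as in the measurement protocol it follows; 3-D
extension is out of scope. The exact F and p values of the original
clinical cohort are functions of undeposited data and are not reproduction
targets; the package reproduces the measurement arithmetic, the
classification construction, and the qualitative inference pattern.
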