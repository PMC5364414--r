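# sinusmorph

Landmark-based morphometry of the posterior maxillary sinus on coronal CT
slices, for clinicians and methodologists working on pre-prosthetic
planning and sinus-augmentation decision making.

The maxillary sinus can extend down into the alveolar process, eating into
the residual ridge height available for dental implants. From twelve
manually placed landmarks per image (two digital-ruler calibration points
plus five anatomical points per side), `sinusmorph` computes, per sinus:

- **sinus depth (SD)** — the signed perpendicular distance of the deepest
  sinus-floor point (P4 right, P9 left) from the hard-palate line through
  P7 and P12, positive below the palate;
- **alveolar height (AH)** — the distance between the alveolar tip (P6 /
  P11) and the deepest floor point, i.e. the bone available for implants;
- **sinus opening angle (α)** — the angle at the floor point subtended by
  the lateral and medial wall-top points (P3/P5 right, P8/P10 left).

Around those statistics the package provides the full study pipeline:

1. per-sheet **mm/px calibration** from the digital ruler;
2. **replicate consensus** across 2 observers × 2 sessions: coordinate-wise
   median with a 2 mm gross-error flag, outlier exclusion and an
   unresolved-point audit trail;
3. a **three-class sinus classification** built on the rounded first and
   third quartiles of sinus depth (class I above the palate, class II
   0–6 mm below, class III > 6 mm below), stratified by dentition;
4. **group comparisons** — one-way and additive multi-factor ANOVA with
   sequential sums of squares, plus mean ± SD (range) summary tables;
5. a seeded **synthetic-cohort generator** (class-structured depth
   mixture, class-conditional AH/angle models, dentition effect) and a
   landmark **renderer** with observer noise and gross-error injection, so
   the whole pipeline is testable end to end without clinical data.

## Worked example

Simulate a 100-patient cohort (25 per gender × dentition cell), render it
to noisy replicated landmark sheets with 2 % gross errors, and run the
pipeline:

```r
library(sinusmorph)

spec <- cohort_spec(n_patients = 25, seed = 1)
truth <- simulate_truth(spec)
landmarks <- render_landmarks(truth, render_spec(noise_sd_mm = 0.3,
                                                 gross_error_rate = 0.02,
                                                 seed = 1))
out <- run_pipeline(landmarks, truth_metadata(truth))
#> pipeline: 4800 landmark rows, 400 sheets (400 complete), 100 patients
#> measured 200 sinuses from 100 patients (19 flagged landmarks, 0 excluded sides)
#> classified 200 sinuses: limits (1, 6) mm [quartile]; classes I/II/III = 59/92/49

cohort_summary(out$cohort, "alveolar_height_mm", "sinus_class")
#> # A tibble: 3 × 6
#>   level     n  mean    sd   min   max
#> 1 I        59 11.9   6.06 1.35   26.5
#> 2 II       92  8.28  2.89 2.38   16.0
#> 3 III      49  5.64  2.83 0.314  12.4
```

Reading the output: 19 of the 1000 anatomical landmark bundles were
flagged by the 2 mm consensus rule (the injected gross-error rate is 2 %),
no sinus had to be excluded, and the quartile-derived class limits of this
small cohort round to (1, 6) mm — at the reference cohort size the default
depth model rounds to the canonical (0, 6). Mean alveolar height falls
from ~12 mm in class I to ~5.6 mm in class III: the deeper the sinus
dips below the palate, the less implant bone remains. The term-wise ANOVA
table in `out$models` shows alveolar height depending strongly on sinus
class and dentition but not gender, while sinus depth depends on neither —
the pattern that makes sinus depth a usable constitutional classification
variable.

A thin command-line wrapper for the same flow is installed at
`inst/scripts/sinusmorph.R` (subcommands `simulate` and `run`).

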