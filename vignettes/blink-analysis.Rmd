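---
title: "Blink detection, incomplete-blink classification and fatigue trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink detection, incomplete-blink classification and fatigue trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdtblink)
```

## The problem

Prolonged viewing of screens (visual display terminals, VDT) induces
visual fatigue: the tear film over the cornea evaporates faster than
blinking replenishes it, and blink behaviour changes measurably —
people blink more often, in bursts, and for longer. `vdtblink`
implements a camera-only analysis of that behaviour: blinks are
detected from a 68-point facial-landmark stream, classified as
complete or incomplete from eye-region images, summarised per session
phase by seven features, and the phase trends are tested with
nonparametric repeated-measures statistics. A typical session is 120
minutes of 60 frames/s video split into four 30-minute phases, with a
short questionnaire (five items scored 0/1/2) answered between phases.

Because face recordings cannot be bundled, the package ships a
ground-truthed synthetic session generator; every stage of the
pipeline is tested against planted truth.

## Blink detection

The eye aspect ratio of one eye is computed from its six landmark
points (two corners `p1`, `p4`; upper-lid pair `p2`, `p3`; lower-lid
pair `p6`, `p5`):

$$EAR = \frac{\lVert p_2 - p_6\rVert + \lVert p_3 - p_5\rVert}
             {2\,\lVert p_1 - p_4\rVert}.$$

EAR sits near 0.3 for an open eye and falls towards 0 with lid
closure. A blink is a maximal run of frames with EAR *strictly* below
0.2; a frame at exactly 0.2 counts as open and ends the run. This
strict reading makes the segmentation an exact, testable rule: the
covered frames are precisely `{t : EAR(t) < 0.2}`.

Decisions taken where the procedure was underdetermined:

* **Eye fusion.** EAR is computed per eye; whether one eye or both
  feed the analysis is not fixed by the method. The default is the
  mean of the two eyes (`mode = "mean"` in `build_ear_trace()`),
  which damps unilateral landmark jitter; either single eye is
  available by configuration.
* **Minimum blink length.** Runs shorter than `min_blink_frames = 2`
  (≈33 ms at 60 frames/s) are discarded as landmark noise. Real
  blinks span roughly 7+ frames at 60 frames/s, so this filter cannot
  touch them; it is configurable down to 1.
* **Boundary runs.** A run truncated by the start or end of the trace
  is kept and flagged `open_ended` rather than silently dropped, so
  blink counts are not biased; feature code can exclude flagged events.
* **Timing.** All timing is in frame indices; the frame rate is applied
  only when intervals and durations are reported in seconds. Dropped
  frames are reported (`gaps`), and their EAR values are imputed from
  the previous valid frame and flagged, never silently invented.

## Incomplete-blink classification

An incomplete blink is one whose upper lid does not descend far enough
to cover the cornea. The imaging chain measures lid descent per frame
from a grayscale eye crop:

1. **Single-scale retinex** (`enhance_ssr()`): subtract, in the log
   domain, a Gaussian surround of scale 300 px, then rescale to
   0–255. With a surround far larger than the crop this mainly
   compresses dynamic range and removes slow illumination.
   Zero-intensity pixels are handled by an epsilon offset (default 1
   on the 0–255 scale; a message notes when it takes effect). A
   numerically constant log-ratio returns a flat zero image instead of
   amplifying rounding noise.
2. **Magnification** (`magnify()`): separable Keys bicubic
   convolution (`a = -0.5`, reproduces quadratics exactly), factor 33.
   The factor is taken literally but is configurable — it is unusually
   large and may matter only for sub-pixel boundary placement; the
   classification rule below is ratio-based, so the factor cannot
   change labels.
3. **Binarization** (`binarize()`): fixed threshold 139; intensity ≥
   threshold is foreground. The polarity was fixed against rendered
   fixtures: after retinex rescaling the bright sclera of the visible
   eye opening exceeds 139 while skin and iris fall below it.
4. **Contour** (`extract_contour()`): largest connected foreground
   component, morphological closing plus hole filling (so the dark
   iris does not puncture the shape), then the ordered boundary. Two
   reference points are read off the component: `upper_mid`, the
   topmost pixel in the component's horizontal midpoint column (the
   upper-eyelid midpoint), and `corner`, the extreme-x boundary pixel
   on the designated side. The temporal (outer) corner is the default
   — it is less occluded in real footage — and the side is
   configurable.

`compute_duc()` returns the signed vertical offset
`D_uc = y(upper_mid) − y(corner)` in magnified-image pixels. Three
conventions deserve justification:

* **Vertical, not horizontal.** The distance is described in the
  source method both as a "vertical distance" and via "x-axis
  coordinates"; only the vertical reading makes the closure geometry
  meaningful (a descending lid moves the lid midpoint in y, not x),
  so the x-axis phrasing is read as a figure-axis label.
* **Sign.** y points down (image convention), so a descending upper
  eyelid *increases* `D_uc`. The per-blink maximum `max_duc`
  (`max_duc_per_blink()`) is then the deepest descent of the blink,
  which is what separates complete from incomplete blinks.
* **Scale.** `D_uc` is reported at the magnified pixel scale; the
  classification rule is a ratio, so the scale choice is cosmetic.

**Calibration.** `calibrate_duc()` takes the `max_duc` values of
*labelled complete* blinks inside the calibration window (default the
first 10 minutes) and sets `mm_duc` to their median (mid-mean for even
counts, i.e. `stats::median`). A blink is incomplete iff
`max_duc < 0.75 * mm_duc`; exact equality is complete. At least 5
calibration blinks are required by default (the labelled cohorts this
mirrors had on the order of a hundred complete blinks per subject in
the window; 5 is a permissive floor, exposed as configuration). An
unattended mode (`auto_calibrate()`) uses the upper quartile of
calibration-window `max_duc` as pseudo-complete blinks — complete
blinks dominate real sessions, so this is a conservative stand-in when
no labels exist.

A geometric caveat the user should know: the ratio rule presumes a
descent measure that is near zero for a lid that has not descended
(as in the source method's eye-corner anchoring). If a particular
crop geometry adds a large constant offset to `D_uc`, the 75% cut is
no longer a depth ratio; the synthetic ground truth therefore plants
`max_duc` proportional to lid-descent depth (`duc_scale`, default
400 px per unit depth), and the imaging chain is validated separately
for *ordering* (monotonicity in planted descent), which is the
property the rule needs after per-subject calibration.

## Phase features

Events are assigned to phases by their start frame (half-open windows
`[kL, (k+1)L)`); an event spilling over a boundary belongs to its
start phase, and intervals never span phase boundaries. Per phase,
`blink_features()` computes:

| feature | definition |
|---|---|
| `BN` | number of blinks (complete + incomplete) |
| `Mean_BI` | mean start-to-start interval between adjacent blinks (s) |
| `Mean_BD` | `sum(n_i) / (fr * BN)` — mean frames per blink over the frame rate (s) |
| `GBN` | number of blink groups: maximal runs of ≥ 2 blinks with successive start-to-start intervals < 1 s |
| `Mean_GBI` | mean start-to-start interval between adjacent groups (s) |
| `IBN` | number of incomplete blinks |
| `Mean_IBI` | mean start-to-start interval between adjacent incomplete blinks (s) |

All intervals are start-to-start — the only interval the source method
draws. Two readings of "group blink number" are defensible: the number
of bursts, or the number of blinks inside bursts. The default counts
bursts (`group_count = "bursts"`), which keeps `Mean_GBI` ("interval
between adjacent group blinks") well defined as the gap between burst
starts; the member count is available behind the switch. `Mean_IBI`
is measured between adjacent incomplete blinks regardless of complete
blinks in between. Any mean over fewer than one interval is `NA`,
and `BN = 0` phases report zero counts with all means `NA`.

## Statistics

`score_questionnaire()` sums the five 0/1/2 item scores (range 0–10).
`friedman_trend()` is the Friedman test: within-subject mid-ranks,
tie-corrected chi-square approximation on `k − 1` degrees of freedom.
`wilcoxon_signed_rank()` drops zero differences, mid-ranks the
absolute differences, and uses the exact signed-rank distribution for
n ≤ 25 untied differences (a 23-subject cohort stays exact) and the
tie-corrected, continuity-corrected normal approximation otherwise.
Both are implemented in the package and are cross-checked in the test
suite against `stats::friedman.test()` and `stats::wilcox.test()` as
independent references. No multiplicity correction is applied to the
pairwise comparisons by default, matching the raw-threshold reporting
style of the field; Bonferroni is available
(`pairwise_wilcoxon(correction = "bonferroni")`).

## The synthetic generator

`synthetic_spec()` fixes the study conditions once:

* 60 frames/s, four 30-minute phases;
* per-phase blink rates 14.77/18.17/22.13/23.60 per minute and
  duration means 0.57/0.63/0.68/0.75 s (sd 0.12 s) — the published
  per-phase medians of blink number and mean blink duration for this
  kind of session;
* incomplete-blink probabilities 0.104/0.061/0.048/0.047 (the
  published incomplete-to-total ratios);
* burst probabilities 0.06–0.11 chosen to land group counts near the
  published 25–71 groups per phase;
* lid-descent depths: complete ~ TruncNormal(0.95, 0.04) on
  [0.85, 1], incomplete ~ TruncNormal(0.55, 0.06) on [0.40, 0.65].
  The separation (> 3 sd) encodes that manual complete/incomplete
  labelling of real sessions presumes visibly distinct classes;
* landmark noise sd 0.5 px, open-eye EAR 0.3.

Mechanics worth knowing:

* Blink closures are raised-cosine dips whose window width is set so
  the aperture stays below the detection level for the sampled number
  of frames. Ground-truth boundaries are read back off the finished
  aperture trace, so bookkeeping and emitted streams agree frame by
  frame by construction.
* Non-burst gaps follow a shifted-exponential renewal with a 1.3 s
  floor, so sub-second intervals occur only in planted bursts and the
  group structure is identifiable. Burst blinks (anchors and
  followers) use short durations (≈0.25 s): consecutive sub-second
  eyelid motions must re-open above the EAR threshold between events,
  which 0.6–0.75 s motions cannot do — physiologically these are rapid
  partial re-blinks. Overlaps that survive sampling are resolved by
  dropping the later event (deterministic, rare).
* One consequence, stated for honesty: the *realized* per-phase mean
  blink duration sits ~10–15% below the duration prior (≈0.63 s in
  phase 4 rather than 0.75 s) because the brief burst blinks are
  averaged in. Similarly, mean blink interval follows arithmetically
  from the planted rates (≈2.5 s at 23.6 blinks/min) rather than
  matching published interval medians — in the published table the
  blink-count and interval medians are cross-subject medians of
  different quantities and are not jointly attainable by any single
  subject. The generator prioritises rates and durations.
* `kinematics_to_landmarks()` places eye landmarks so that
  EAR = 0.3 × aperture *exactly* before noise. The rest of the face is
  a static template: head pose, gaze and expression are not modelled.
* Renders are three intensity bands (sclera 230, skin 90, iris 40)
  under parabolic lids with anti-aliased edges, so sub-pixel lid
  positions survive magnification. They exercise thresholding and
  contour logic; they do not exercise eyelashes, shadows, specular
  highlights or compression artifacts, so passing renders says
  nothing about landmark-model quality on real video.
* `generate_cohort()` works at the event level (no frame traces) with
  a multiplicative subject effect on rates (log-sd 0.2) and an
  additive one on durations. Because the subject effect scales all
  phases alike, the within-subject phase ordering — all the Friedman
  test sees — is preserved.
* All randomness flows from the single seed; identical specs and
  seeds are bit-identical.

## Numerical choices and degenerate inputs

* EAR at exactly the threshold ends a run (strict `<`).
* Classification ties (`max_duc` exactly at 75% of `mm_duc`) are
  complete.
* Degenerate eye geometry (zero eye length) is an error in scalar
  code and an imputed-and-flagged frame in trace code.
* Empty foreground is a `no-contour` error; a component touching all
  four image borders is an `unreliable contour` warning.
* The Friedman denominator collapsing (all subjects constant) yields
  p = 1 with a warning, as does an all-zero-difference Wilcoxon pair.
* Keys bicubic uses `a = -0.5` with replicate borders and center
  alignment, so factor 1 is the identity.

## Problem sizes in the test suite

The suite validates the pipeline on 10-minute sessions (planted-truth
recovery, 20 seeds, noiseless and 0.5 px noise), 20-minute
two-phase sessions for calibration/classification, full 2-hour
cohorts of 23 subjects for trend power (200 replicates), 2000-replicate
null simulations for test size, and a 20-step noiseless render ramp
for the imaging chain. These sizes are chosen so the whole suite runs
in a few minutes while keeping every estimate's Monte-Carlo error
well inside the asserted margins.

## Limitations

* The landmark detector itself is out of scope: the pipeline consumes
  landmark streams (CSV) produced by any 68-point detector behind an
  adapter, and all tests run without a face model.
* Published cohort-level results for real subjects cannot be
  reproduced here — they require the original recordings; the package
  reproduces the *qualitative* trend pattern (rising blink and group
  counts, falling intervals) on synthetic cohorts and verifies every
  computational rule against planted truth.
* The imaging chain is validated for ordering, not absolute descent
  in millimetres; no corneal-coverage estimate is attempted.
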