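---
title: "Estimating loss aversion from keypress behavior and relating it to striatal fMRI contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating loss aversion from keypress behavior and relating it to striatal fMRI contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Loss aversion (LA) is the overweighting of negative valuations relative to
positive ones. In prospect theory it is the ratio of the value function's
slopes on the loss and gain sides; in the more general approach/avoidance
framing used here it is the ratio of avoidance to approach sensitivity.
`lapref` implements a complete desk-scale pipeline for a study design in
which LA is measured *outside* the scanner with a keypress task on affective
face pictures, and related to a *passively viewed* presentation of the same
stimuli inside the scanner — a model-based fMRI design that keeps motor
activity out of the imaging signal. The three questions the pipeline answers
for a cohort are:

1. Does the ventral striatum / nucleus accumbens (VS/NAc) respond more to
   negative faces (angry, fearful, sad) than to positive ones (happy)?
   The per-subject summary of that difference is the *neural differential
   sensitivity* (NDS).
2. Does NDS correlate with behavioral LA across subjects?
3. How do NDS and LA each relate to age across the adult range (20–55
   years)?

Because no subject-level data are released for such studies, the package
ships a first-class synthetic-cohort generator with known ground truth, so
that every stage — sequence design, keypress reduction, curve fitting, GLM,
contrast extraction, group inference — is testable end to end.

## Relative preference coordinates: K and H

The keypress task shows each picture for a default 6 s (plus a 2 s decision
block). Pressing one key pair (buttons 1/2) lengthens viewing, the other
(buttons 3/4) shortens it; the work a subject trades for viewing time is the
valuation. `tally_trials()` reduces an event log to per-trial approach and
avoid counts and the implied viewing time
(`clamp(6 + 0.1 * (n_approach - n_avoid), 0, 14)` seconds by default — the
original task's effort-to-seconds exchange rate is unpublished, so the
increment and bounds are explicit, configurable parameters rather than
constants).

`category_valuation()` summarizes each stimulus category by two coordinates:

* **K** — the mean over the category's pictures of the signed net keypress
  count (approach − avoid). Positive K marks the approach limb, negative K
  the avoidance limb. Mean viewtime deviation can substitute
  (`measure = "viewtime"`) and yields comparable results because viewtime
  is an affine function of net presses until clamped.
* **H** — the Shannon entropy (bits) of the distribution of total keypress
  counts across the category's pictures: the choice uncertainty of how
  effort was allocated within the category. With 8 pictures per category H
  is bounded by 3 bits, attained when effort is spread uniformly.

Whether K should be net or gross presses is a convention choice; this
package uses net counts (gross per-class means are exported alongside for
diagnostics). H is computed on per-picture *total* counts so that both
limbs use the same support.

Neutral faces and scrambled baselines never enter curve fitting. A
category whose |K| falls inside a dead band (default 0.05 presses) is
additionally labeled `neutral` rather than forced onto a limb.

## Value curves and the local loss-aversion statistic

Each limb's category points (H, K) are fitted with a value curve on |K|:
a power law `|K| = a H^b` by default, with linear-through-origin
(`|K| = a H`) and quadratic (`|K| = a H + b H^2`) alternatives. The power
law is the default because it passes through the origin and accommodates
both concave and convex limb shapes. Two numerical guards matter in
practice:

* A power law is under-determined with fewer than 3 points or when the
  limb's H values are nearly identical (spread below `min_h_spread = 0.1`
  bits); `fit_value_curve()` then falls back to the linear form and
  records the form used (`form` vs `form_requested`). With the
  seven-condition face set the approach limb is typically a single happy
  point, which the one-parameter through-origin line fits exactly — the
  reason a single-point limb is admitted for the linear form only.
* The avoidance limb is fitted on |K| and mirrored (sign −1), so fitted
  avoidance values are never positive; the power-law amplitude is bounded
  at zero.

The LA statistic is *local*: `local_slope()` takes the mean slope of the
fitted curve over the fraction (default 10%) of the H range nearest the
origin — operationalized as the limb endpoint of smallest |K|, since the
limbs meet near K = 0. The mean slope over a window of width w is
`(f(h0 + w) - f(h0)) / w`, i.e. the integral of the derivative divided by
the window width, which makes

```
lambda = | s_minus / s_plus |
```

a dimensionless ratio of avoidance to approach sensitivity. Whether "10%
of the curve" means 10% of the H range or of arc length is ambiguous; the
H-range reading is used. On a linear fit the window choice is irrelevant
(the slope is constant), which is also why the fraction → 1 limit equals
the global least-squares slope.

Cohort-level screening uses the 2-standard-deviation rule
(`flag_outliers()`): a subject's lambda is an outlier when it lies more
than 2 sample SDs (n − 1 denominator; unspecified in the source
literature, so the conventional estimator is used) from the cohort mean,
both computed over all values in a single pass. Non-finite lambdas (e.g.
a flat approach limb giving lambda = ∞) are always flagged. Note a hard
arithmetic consequence of this rule: because the squared z-scores sum to
n − 1, at most ⌊(n − 1)/4⌋ values can exceed 2 SD — at n = 17, never more
than 4 subjects. Reports of 5-of-17 exclusions under a nominally
identical rule must therefore have used a variant (e.g. iterative or
leave-one-out flagging); this package implements the single-pass rule
exactly as stated.

## The block design and its counterbalancing

The scanner paradigm is a block design: 20-s blocks of seven conditions
(five facial expressions, phase-scrambled faces, fixation), 25 blocks per
run, ordered so that **no condition follows or precedes another more than
once** — i.e. the 24 ordered transitions are pairwise distinct (24 of the
42 possible ordered pairs at 7 conditions). Per-condition block counts are
balanced to within one; the exact per-condition composition of a 25-block
run is not dictated, so the balance rule is the constraint enforced.
`generate_block_sequence()` finds such sequences by randomized
backtracking over the transition graph (default budget 10,000 node
expansions; exhausting it raises a distinct "design infeasible" error
rather than returning a violating sequence). A second run of 24 blocks is
counterbalanced across runs by prefixing it with a copy of the first
run's final block (`prefix =`), reproducing the 24 + 1 device.

Within a face block, `build_timeline()` lays out 8 identities × 5
repetitions at 200 ms display + 300 ms interstimulus interval — 40 faces
filling the 20 s — in a pseudorandom order with no identity twice in a
row. Scrambled and fixation blocks are single block-length events.
Timelines export to BIDS-style events TSV.

## The desk-scale GLM and NDS

`build_design_matrix()` convolves each modeled condition's stimulus
indicator with the canonical double-gamma HRF (response gamma shape 6,
undershoot shape 16, ratio 6 — peaking ~5 s post-onset), samples at
volume midpoints (TR 2.5 s), and appends an intercept and a linear drift
term; fixation is the implicit baseline. `fit_glm()` runs per-voxel OLS
with residual df = volumes − columns; the NDS contrast is

```
contrast = mean(beta_angry, beta_fearful, beta_sad) - beta_happy
```

with its standard error from the OLS covariance and t mapped to a
standard-normal z by two-sided tail matching (computed in log space so
noiseless fits give z = ±∞ rather than overflow). Neutral faces get a
regressor but sit on neither side of the contrast.

`extract_nds()` implements the per-subject ROI sampling rule: the NDS is
the mean contrast over VS/NAc voxels with z > 1.96 (p < 0.05). Whether a
per-subject NDS should be a mean beta difference, a mean contrast
estimate, or a peak-voxel value is not fixed by convention; the mean over
supra-threshold ROI voxels is used. If no voxel survives, the subject's
imaging is marked invalid and excluded downstream, the same bookkeeping
used for motion-artifact subjects. The default hemisphere is left (the
hemisphere conventionally reported for the NDS–LA relation), with right
and bilateral options. Group-level cluster correction (z = 2.3
whole-brain) belongs to full-scale imaging pipelines and is outside desk
scope; the per-subject z = 1.96 rule is the implemented selection step.

## Group inference

`assemble_cohort()` builds the per-subject table (age, lambda, NDS,
flags). Three associations are computed:

* **NDS ~ LA** (`correlate_nds_la()`): Pearson correlation over subjects
  who are neither lambda nor NDS outliers and have valid imaging. As an
  isolated test, alpha = 0.05.
* **NDS ~ age** and **LA ~ age** (`regress_on_age()`): simple linear
  regressions. Because two tests run against age, the default threshold
  is Bonferroni-corrected to alpha = 0.05/2 = 0.025. The LA regression
  excludes lambda outliers; the NDS regression uses all valid-imaging
  subjects (NDS outliers are excluded only from the correlation, where
  they can single-handedly manufacture or destroy r; for the age
  regression the full valid-imaging set is retained — both choices are
  overridable). One cannot regress an NDS that could not be measured, so
  invalid-imaging subjects are necessarily absent from both NDS
  analyses.

All p-values are two-sided. Every association carries an `excluded`
attribute listing each dropped subject and the reason, and
`n_used + n_excluded` always equals the cohort size. `la_pipeline()`
chains the stages, aborts with the failing stage's name on error, and
reproduces its CSV outputs byte for byte under a fixed seed.

## What the synthetic cohort emulates

`cohort_spec()` defaults encode the study conditions the pipeline
targets:

* 17 subjects, ages uniform on 20–55.
* Ground-truth lambda log-normal with median 2 (log-SD 0.3) —
  centering the cohort near the classic LA ≈ 2 scale — independent of age
  (`beta_age_la = 0`), with a 5/17-rate heavy-tail mixture component
  (log-SD 1.5) to exercise outlier flagging.
* Ground-truth NDS linear in age (`beta_age_nds = 0.02` contrast units
  per year) plus a coupling to centred log-lambda
  (`beta_la_nds = 0.7`) and residual SD 0.156. These three variance
  components were chosen once, by partitioning the NDS variance so that
  age explains ≈ 0.37 of it and log-lambda ≈ 0.41: with age variance
  (35²/12) ≈ 102, that allocation puts the expected NDS~age F near 9 and
  the expected NDS~LA correlation near 0.6 at n = 17 — the scale of the
  findings this design is meant to detect — while keeping lambda and age
  independent.
* A 2/17 rate of motion-artifact subjects whose imaging is invalid.
* Keypress counts Poisson around `approach_gain × |valence|` (avoidance
  side multiplied by the subject's lambda); `keypress_noise` selects
  deterministic (0), Poisson (1) or negative-binomial (> 1) counts. The
  count model is a modeling choice — keypress variability is not
  characterized in the source literature.
* Picture valences are the category valence ±1/0 plus Uniform(−0.2, 0.2)
  per-picture jitter *centred within category*. The jitter exists to make
  within-category entropy non-degenerate; centring it keeps the category
  mean valence exact, so ground-truth lambda is well defined at the
  category level and recoverable in the vanishing-noise limit.
* Voxel tables: 100 voxels (60% in the ROI, split between hemispheres;
  40% null), response amplitude 1 signal unit on a baseline of 100 with a
  linear drift, white noise SD 0.5. The noise level is set so that
  responsive VS/NAc voxels are reliably supra-threshold at z = 1.96 in
  single subjects, matching designs where most scanned subjects show
  usable ROI activation.

What the generator deliberately does **not** emulate: realistic fMRI
artifacts (motion, physiological noise, spatial autocorrelation,
nonlinear drift), anatomical segmentation, session-to-session behavioral
drift, or any dependence between keypress noise and imaging noise.
Passing tests therefore demonstrate that the *estimators* are correct and
calibrated under the stated statistical structure — not that real data
meet that structure.

## Numerical choices and degenerate inputs

* Backtracking sequence search is randomized; identical seeds give
  identical designs, timelines, sessions and cohorts (`withr`-scoped,
  never touching the global RNG state outside seeded calls).
* All-zero keypress categories get H = 0 with a warning; all-H-identical
  limbs are "unfittable" errors rather than silent degenerate fits.
* Zero approach slope gives lambda = ∞ (flagged), not an error.
* Zero residual variance in the GLM maps a nonzero contrast to z = ∞, so
  noiseless recovery retains its voxels.
* Constant age or constant lambda in an association raises a degenerate
  -input error instead of returning NaN.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: single runs of 25 blocks (500 s at TR 2.5 s, 200
volumes), 40–2,500 voxels per subject, cohorts of 17, twenty-cohort
parameter-recovery sweeps, and a 2,000-cohort null-calibration study on
the fast table-only generator path. These sizes keep the full suite in a
few minutes on one CPU while leaving every statistical check
well-powered.

## Known limitations

* Category-level fitting leaves the approach limb with a single point
  under the default seven-condition design; its slope is exact only
  under the through-origin linear form. Designs with several positive
  categories would let the power form act on both limbs.
* The z > 1.96 ROI-sampling rule induces a selection bias (upward for
  small true contrasts) that is part of the emulated method, not a bug;
  at the default noise level its effect on cohort-level associations is
  small but visible in subjects with weak true contrasts.
* The heavy-tail lambda mixture cannot reproduce 5-of-17 outlier flags
  under the single-pass 2-SD rule (see the arithmetic bound above).
* The pipeline models one run; multi-run fixed-effects combination is
  out of scope.
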