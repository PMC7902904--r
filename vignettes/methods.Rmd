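---
title: "Measuring working-memory usage from gaze in an object-copying task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring working-memory usage from gaze in an object-copying task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazewm)
library(data.table)
```

## The task and the measure

In the immersive object-copying task a participant reproduces a *model*
arrangement of 8 objects by fetching objects from a *resource* pool of 24
(8 targets + 16 distractors, drawn from a 60-object pool) and placing them
into a *workspace* grid. One object can be carried at a time, each display
has a 45 s budget, and gaze is sampled at 90 Hz as an area-of-interest
(AOI) label: `MODEL`, `RESOURCE`, `WORKSPACE` or `OTHER`. The angular
separation between model and workspace (0°, 45°, 90°, 135°, varied
run-wise; two runs per condition, i.e. 28 displays and 224 object
placements per condition per participant) manipulates the *locomotive
effort* of re-inspecting the model.

The analysis unit is the **sequence**: it opens at a gaze sample on the
model and closes at the next model view that follows a qualifying
interlude; the closing view simultaneously opens the next sequence, so a
display's sequences tile its timeline with shared boundary views. Every
controller action is attributed to the sequence containing its timestamp
(half-open spans `(start, end]`). The **number of features in memory** used
during a sequence counts the information acted upon before gaze returned to
the model: each non-corrective pickup of a model object credits one
*identity* feature, each non-corrective correct placement credits one
*location* feature. A pickup-only sequence scores 1, pickup-then-place
scores 2, and so on; sequences with no action score 0. Because each of the
8 objects carries exactly two features, a completed error-free display
conserves 16 credited features regardless of strategy — the package treats
this identity as an internal consistency check (`tally_displays()`).

## Design choices in segmentation and scoring

**Qualification rule.** The default rule closes a sequence at a model
re-view whenever at least one `RESOURCE` *or* `WORKSPACE` visit intervened;
a stricter resource-only rule is available
(`segment_sequences(rule = "resource")`). The default is deliberate: under
the look-before-placing strategy (encode identity → pick up → re-view the
model for the location → place) the placement interlude contains only a
workspace visit. A resource-only rule would merge that interlude into the
following sequence, turning the canonical one-feature behavior into
two-feature sequences; with workspace interludes qualifying, the strategy
scores as the 1-feature pattern the measure is designed to capture. `OTHER`
samples (travel, floor, walls) never qualify and never split a sequence.

**Corrections.** The task forces immediate correction of wrong placements.
Corrective actions — re-pickups of a misplaced object (`REMOVE` events) and
re-placements of an object with an unresolved wrong placement — never earn
features: the 16-feature conservation identity only holds if a feature is
credited exactly once, at its first successful use. A sequence containing a
distractor pickup is flagged with an *identity error*; a sequence where a
model object was set on the wrong cell is flagged with a *location error*.

**Exclusions.** The per-condition feature-probability table excludes, by
default (each has a switch): truncated sequences (no closing model view
before the display ended), 0-feature sequences (dominated by positional
adjustment and lapses rather than memory use; they are reported separately),
and error-flagged sequences. The last exclusion keeps the table
interpretable as a distribution over *successful* memory use: an erroneous
sequence's credited count reflects the failed action, not the intended one.
Error rates themselves are reported over all non-truncated sequences.

**Viewing time.** A sequence's viewing time is its initial model dwell:
summed model gaze from the opening view up to the first resource visit;
brief `OTHER` interludes neither end nor extend it. Dwells outside the
closed interval [50, 2000] ms are excluded, as are sequences outside 1-4
features — in simulated data this removes well under 1% of eligible
sequences. Display completion time is the summed sequence durations, which
telescopes exactly to last-boundary minus first-view because adjacent
sequences share their boundary view.

## The synthetic agent

`simulate_experiment()` generates frame logs with the statistical structure
the analysis assumes, so every stage is testable by parameter recovery with
no external data. The agent alternates model encoding, resource search and
workspace placement; its policy fixes, per condition, the distribution of
features loaded per model visit (`features_pmf`), the rate of unproductive
trips, per-sequence error-injection probabilities, and a log-normal time
model (all durations positive and right-skewed, matching the log transform
the analysis applies; dispersion σ = 0.3).

Default calibration, chosen once from the study conditions: the 0°
one-feature probability is 0.60 and the 135° four-feature probability is
0.10 — the two anchor values the study reports — with remaining mass
allocated so mean usage rises roughly linearly from ~1.5 to ~2.1 features
across conditions; identity and location errors are injected at 1.8% and
2.9% per sequence; travel legs touching the model cost
0.35 + 0.45·(angle/135°) s on average, searches 0.55 s, placements 0.40 s,
encoding dwell 250 + 150·k ms scaled by a mild condition gain. Dwell-time
distributions and travel means are not published quantities; they are
calibrated qualitatively so that completion times land in the tens of
seconds, grow with angle, and displays almost never hit the 45 s timeout
(empirically ~1 in 10⁴ displays at the highest conditions; timeouts are
truncated, flagged, and excluded like the study's own removed displays).

Three generator subtleties matter for exactness of recovery:

* **Composition conditioning.** A display consumes exactly 16 features, so
  per-visit loads are drawn i.i.d. and accepted only when they tile 16
  exactly. Conditioning on the tiling size-biases the pooled per-sequence
  load distribution (small loads make more sequences), so the internal
  proposal distribution is solved — by an exact renewal dynamic program and
  a fixed-point iteration (`composition_part_dist()`) — such that the
  *realized* distribution equals the configured `features_pmf`.
* **Closing glance.** After the final placement the agent glances back at
  the model, giving the last sequence its closing view; otherwise every
  display's final sequence would be truncated and excluded, biasing
  recovery.
* **Error realization.** Error marks are drawn per sequence so the
  configured rates are per-sequence marginals. A location error marked on a
  sequence with no planned placement makes the agent fetch and misplace the
  next object, and the display's remaining visit plan is redrawn for the
  remaining feature budget. Unproductive (0-feature) trips occur only when
  the hands are free, which keeps every sequence eligible for a distractor
  pickup.

The simulator emits AOI labels directly rather than 3-D gaze vectors — the
analysis consumes labels, and geometry enters only through travel times. An
optional noise layer injects brief AOI flickers (`flicker_rate`); it is off
by default, and segmentation-vs-ledger agreement degrades smoothly as it is
enabled. What passing recovery tests therefore show is that the pipeline
inverts the generative structure it assumes — clean AOI labels, immediate
corrections, one object in hand; they do not certify robustness to
real-world failure modes such as calibration drift, AOI misassignment at
area borders, or un-modeled strategies.

## Statistical battery

All mixed models are fitted by maximum likelihood through lme4 (Laplace
approximation for the Poisson models), the implementation the original
analyses used. `boxcox_select()` profiles the Box-Cox λ on [-2, 2] and
recommends the log transform when 0 falls in the 95% profile interval —
on simulated dwell and completion times it does. `make_predictors()` codes
the four conditions as equally spaced ranks 1-4 *before* the exponential
and logarithmic transforms (log 0° is undefined on raw degrees), builds
orthogonal linear/quadratic/cubic polynomials over the design, and
z-scales every column; rank-then-transform-then-z is a package decision and
is flagged in outputs.

`fit_poisson_glmm()` models per-sequence feature counts with by-participant
random intercepts and a random slope for the locomotion predictor;
0-feature sequences are included by default (a count model accommodates
them; a switch excludes them). `lr_ladder()` compares the exponential →
logarithmic → linear → quadratic → cubic ladder: nested steps get
likelihood-ratio χ² tests; the equal-parameter exponential/logarithmic pair
is not nested, is flagged, compared by AIC, and its χ² is referred to 1 df
by convention so "the last significant step" stays defined.

`fit_lmm()` (log-transformed dwell or completion time) starts from the
maximal by-participant structure — intercept plus slopes for the feature
terms (orthogonal linear + quadratic), locomotion and their interaction —
and `simplify_random_structure()` removes a slope only when a principal
component of the random-effects covariance carries < 10⁻⁶ of the variance
*and* a likelihood-ratio test for that slope is non-significant, recording
every decision in an audit trail; intercepts are never removed. Fixed
effects are reported with Wald t statistics labelled as such; Satterthwaite
degrees of freedom are out of scope, so LMM p-values are not printed by
default and inference emphasis rests on estimates, standard errors and
likelihood-ratio comparisons. `paired_feature_tests()` runs the 12 planned
within-participant comparisons (features 1-4 × neighboring condition
pairs) with Cohen's d for paired data (mean difference / SD of
differences, signed).

## Numerical conventions and degenerate inputs

Sequence boundaries are half-open on event time; a boundary view's dwell is
credited only to the sequence it opens. Durations are frame counts divided
by the frame rate, so visit durations tile a display exactly. Dwell filter
bounds are closed. Ties cannot occur between events and boundaries in
simulated data (events never fall inside model views); for external data
the half-open convention resolves them deterministically. Displays with no
model view yield zero sequences with a warning; empty frame logs read as
zero-row tables with a warning; constant-response GLMMs are permitted (the
intercept-only identity check relies on one); identical paired vectors get
the degenerate t = 0, p = 1 result rather than NaN. All randomness flows
from one master seed; each participant draws from an independent substream,
so enlarging a simulated sample never perturbs earlier participants, and
identical configurations produce byte-identical CSV exports.

## Problem sizes used by the validation suite

The acceptance analyses simulate the full study size (24 participants,
2,688 displays, ≈ 25,000 sequences, ≈ 6 million frames) once and reuse
it: feature-probability recovery is judged against a participant-level 95%
t interval (sequence counts within a display are dependent, so a pooled
binomial interval would be anti-conservative), while error-rate recovery
uses the binomial interval (error marks are independent per sequence).
Structural properties run at reduced sizes: oracle equivalence on 1,000
randomly chosen displays, ladder selection on 50 replicates of 4,800
simulated sequences each (with the linear effect sized so the
linear-versus-logarithmic discrimination power matches a study-scale
analysis — the two codings correlate at ≈ .98 across four conditions), and
monotonicity checks on a few hundred displays per condition.

## Known limitations

The feature count measures *use*, not capacity: a feature never acted upon
is invisible, and the 0-feature class conflates genuine forgetting with
re-orientation. The simulator does not model saccade kinematics, partial
encoding, learning across runs, or strategic heterogeneity between
participants beyond what the shared policy induces. The deposited data of
the original study are not bundled; the reproduction battery therefore
validates the computation paths on synthetic data of the same shape, and
the mapping adapter for the archive's column layout is left open until that
schema is available offline.
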