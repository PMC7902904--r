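# gazewm

Gaze-based measurement of working-memory usage during naturalistic object
copying.

## The problem

In an immersive copying task a participant reproduces a *model* arrangement
of 8 objects by fetching them from a *resource* pool (8 targets among 16
distractors) and placing them into a *workspace*, one object at a time,
while gaze is sampled at 90 Hz as an area-of-interest label
(`MODEL` / `RESOURCE` / `WORKSPACE` / `OTHER`). The angular separation
between model and workspace (0°, 45°, 90°, 135°) sets the locomotive cost
of re-inspecting the model, which trades off against holding more
information in working memory (WM). This package turns the raw
frame-by-frame gaze/controller logs into that trade-off's measurements, for
researchers studying memory use in natural behavior.

## The measure

Gaze returns to the model delimit **sequences**. Within a sequence, the
number of WM features used is

&nbsp;&nbsp;&nbsp;&nbsp;*k* = #(non-corrective pickups of model objects) +
#(non-corrective correct placements),

one *identity* feature per pickup and one *location* feature per correct
placement — so a pickup-only sequence scores *k* = 1 (the participant
re-checked the model before placing), pickup-then-place scores *k* = 2, and
a completed error-free display conserves Σ*k* = 16 (8 objects × 2
features). On top of the scorer the package provides per-condition
probability tables P(*k* | condition), model viewing times (initial dwell,
filtered to [50, 2000] ms and *k* ∈ 1–4), display completion times, and the
statistical battery: Box–Cox transform selection, Poisson GLMMs of *k* with
by-participant random slopes over exponential / logarithmic / linear /
quadratic / cubic locomotion codings compared in a likelihood-ratio ladder
(`lr_ladder()`), LMMs for (log) dwell and completion time with maximal
random-effects structures and PCA-guided simplification, and the 12
planned paired *t* tests between neighboring conditions.

A seeded agent-based simulator (`simulate_experiment()`) generates complete
frame logs — 24 participants × 8 runs × 14 displays, condition varied
run-wise, 45 s display timeout — together with a ground-truth ledger, so the
whole pipeline is validated by parameter recovery without any external
data.

## Worked example

```r
library(gazewm)
library(data.table)

sim <- simulate_experiment(sim_config(n_participants = 2), seed = 42)
res <- run_pipeline(sim$frames, sim$displays)

dcast(res$probabilities$group, condition_deg ~ k_bin, value.var = "pct")
#>    condition_deg        1        2         3         4    >4
#> 1:             0 62.92254 27.58401  8.790462 0.7029899     0
#> 2:            45 49.27984 33.56907 14.735427 2.4156703     0
#> 3:            90 40.52989 38.32686 15.644410 5.4988354     0
#> 4:           135 28.86762 45.67853 15.994699 9.4591425     0

res$errors
#>    identity_pct location_pct  any_pct n_seq
#> 1:     2.128644     3.007867 5.136511  2161

ledger_agreement(res$scored, sim$ledger)
#> $k_agreement     [1] 1
#> $count_agreement [1] 1
#> $n               [1] 2161
```

Reading the output: at 0° almost two thirds of sequences use a single
feature (look back at the model before every placement), while at 135° the
modal sequence carries two features and four-feature sequences rise to
~9–10% — the shift from external sampling toward WM as locomotion gets
expensive. Mean features per sequence rise from ≈ 1.5 to ≈ 2.1
(`res$probabilities$group$mean_k`). The injected per-sequence error rates
(1.8% identity, 2.9% location) are recovered within sampling error, and
the scorer agrees with the simulator's ground-truth ledger on every
sequence (`k_agreement = 1`).

`wm_simulate()` / `wm_analyze()` are file-level wrappers that write the
frame-log CSV dialect, the ledger, the display manifest, all result tables,
a per-stage row-count log and a plain-text report.

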