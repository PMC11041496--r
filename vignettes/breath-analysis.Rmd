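---
title: "Breath segmentation and validity classification for incentive-spirometer sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath segmentation and validity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirobreath)
```

## The measurement problem

A volumetric incentive spirometer coaches slow, deep inhalation: a volume
piston rises along a graduated column (500 mL markings on the Voldyne 5000,
250 mL on the Voldyne 2500) and a flow bobbin floats within a
"good"/"better"/"best" band. An optical add-on device reports, at each time
stamp, the *highest triggered sensor*: a volume level in 0–10 and a flow
level in 0–3. Optical sensors only see where the piston *is*, not whether a
breath put it there — tilting the device makes the piston fall to any
level. The analysis problem is therefore to (i) cut the discrete stream
into breaths and (ii) decide for each breath whether it is a genuine,
well-executed inhalation.

## Segmentation

Two rules, applied to logged rows (the firmware sampling rate is not part
of the contract, so everything is timestamp-driven):

* a breath **starts** at a zero-flow sample immediately followed by a
  positive-flow sample;
* a breath **ends** at the *first* of the first pair of consecutive
  zero-flow samples after the start.

Conventions that the rules alone do not fix, and how this package fixes
them:

* "two consecutive zero flow values" is read per-sample (two adjacent
  rows), not per unit time;
* breath end (and hence duration) is measured to the first of the two
  terminating zeros; the second zero is re-usable as the start of the next
  breath, so back-to-back breaths need only a two-sample gap;
* a trailing segment that never reaches a two-zero terminator is
  discarded, not classified (`attr(boundaries, "n_discarded")` counts it);
* a single interior zero-flow sample does *not* terminate a breath.

`find_breath_boundaries()` is checked against an independently written
brute-force enumeration on 1,000 random level walks in the test suite.

## The five validity criteria

`classify_breath()` evaluates all five criteria exhaustively (no
short-circuiting), so the violation set is complete:

| criterion | violation code | reading adopted |
|---|---|---|
| volume starts at 0 | `NONZERO_START` | the first (zero-flow) sample of the breath has volume level 0 |
| rises within 1.5 s | `LATE_RISE` | some sample with volume > 0 occurs at `t <= start + 1.5` (boundary inclusive) |
| > 0 throughout | `VOLUME_DROPOUT` | from the first positive-volume sample through the end sample, volume never returns to 0 (enforcing positivity from the literal first sample would contradict "starts at 0") |
| no decrease under positive flow | `DECREASE_UNDER_FLOW` | evaluated between consecutive samples; a decrease is attributed to the *later* sample's flow state, so a piston settling under zero flow is allowed |
| duration 2–15 s | `DURATION_OUT_OF_RANGE` | inclusive at both ends: 2 s and 15 s are valid |

The dropout criterion is taken to bind through the end sample (the first
terminating zero) — whether it should also bind at the second zero, which
lies outside the breath, is ambiguous in the rule statement; we chose the
end-sample convention and note it here rather than silently guessing.

A monotonicity property follows from these readings and is tested:
enlarging the rise window or widening the duration interval can never turn
a valid breath invalid.

### Per-breath metrics

`compute_metrics()` reports maximum flow level, maximum volume level, the
time of *first* attainment of the maximum volume, the ascent rate
(`max_volume / time_to_max`, in levels/s) and the descent rate
(`(max - final) / (end_t - t_first_max)`). Degenerate cases are pinned
down: a breath whose volume never rises has ascent rate 0, and a breath
that already holds its maximum at the start sample (possible only for
invalid nonzero-start breaths) has `time_to_max_volume = 0` and ascent
rate 0 rather than an infinite rate.

## Calibration

`level_to_volume()` maps level *k* to *k* × 500 mL (Voldyne 5000) or
*k* × 250 mL (Voldyne 2500). The 2500's sensors align to its markings only
approximately; per-level additive offsets in `device_profile()` can encode
a measured misalignment and default to 0.

Flow bands store the measured mean (SD) of achieved flow per label. Note
the ordering: "best" is the *slowest* band (26.36 L/min mean on the
Voldyne 5000, vs 57.75 L/min for "good") — the bobbin coaches slow
inhalation, so better technique means lower flow. The bands are stored
verbatim and the labels are deliberately not reordered.

### Dead volume

The in-line flowmeter used for bench testing registers a fixed apparatus
volume before the spirometer display moves. It is modeled as additive and
constant: `calibrate_dead_volume()` estimates it as the mean raw reading
at a known display level minus that level (the reference procedure holds
1000 mL and averages 10 breaths, giving 183.75 mL, the package default),
and `subtract_dead_volume()` removes it from each raw reading, floored at
zero. A Monte-Carlo test confirms the estimator recovers a known offset
within 3σ/√n in ≥ 99% of 1,000 ten-breath calibrations at σ = 15 mL.

### BTPS correction

Flowmeter volumes are corrected from ambient temperature, pressure,
saturated (ATPS) to body temperature, pressure, saturated (BTPS):

$$ f \;=\; \frac{T_{body}+273.15}{T_{amb}+273.15}\cdot
          \frac{P_B - P_{H_2O}(T_{amb})}{P_B - P_{H_2O}(T_{body})} $$

with the Antoine-type saturation pressure
$P_{H_2O}(T)=\exp(20.386 - 5132/(T+273.15))$ mmHg. A genuinely open design
choice: clinical practice often writes the denominator with the rounded
constant 47 mmHg, but the Antoine form gives 46.49 mmHg at 37 °C, and
mixing the two makes the "correction" at body conditions equal 1.0007
instead of 1. We use the same vapor-pressure function at both temperatures,
so the factor is *exactly* 1 when ambient equals body conditions and
strictly decreases toward 1 as ambient temperature rises — both properties
are asserted in the tests. The rounded constant remains available via
`btps_conditions(..., body_svp_mmHg = 47)`, and the vapor-pressure
function is exported so an alternative table can be swapped in. At
20 °C / 760 mmHg the default factor is 1.1005 (1.1013 with the 47 mmHg
constant).

```{r btps}
btps_factor(btps_conditions(37, 760))
btps_factor(btps_conditions(20, 760))
```

## The simulator

No deposited sensor datasets exist for this device, so the package carries
a first-class synthetic generator that replaces the hardware and its human
testers; all classifier testing runs against it.

* **Kinematics.** The piston trajectory is a trapezoid — rise, hold,
  settle — because only level *crossings* are observable; any monotone
  rise profile would produce the same discrete stream up to timing. Flow
  is constant at the band's level during the body of the breath with a
  one-sample decay at its end, and every breath unit is one leading
  zero-flow sample, a positive-flow body, and two terminating zero-flow
  samples.
* **Sampling.** 10 Hz by default (configurable; the firmware rate is not
  part of the contract), with optional Gaussian timing jitter
  (SD 0.003 s default) clipped to keep timestamps strictly increasing,
  and an optional flow-flicker probability confined to the hold phase and
  to the positive range so noise cannot change a breath's label.
* **Margins.** Valid-mode breaths keep safety margins strictly inside
  every rule boundary: first volume rise within 1.0 s (rule: 1.5 s) and
  duration drawn uniformly from [3, 10] s (rule: [2, 15] s). Margins make
  ground truth unambiguous, which is what lets the label-fidelity tests
  demand 100% agreement rather than a tolerance.
* **Invalid modes.** The two physical constructions used on the bench —
  starting position above zero (`NONZERO_START`) and tipping the device so
  the piston falls during positive flow (`TIP_DECREASE`) — plus direct
  violations (`TOO_SHORT` ≤ 1.5 s, `TOO_LONG` ≥ 16 s, `LATE_RISE` first
  rise at 2–3 s, `DROPOUT` a mid-breath return to level 0 during a
  one-sample flow pause), so that every one of the five rules is exercised.
  Each mode is constructed to violate exactly its targeted criterion and
  no other, and the truth metadata records the mode name.
* **Flow realism.** Each breath draws an achieved peak flow from the
  band's measured mean and SD; over 1,000 "best"-band breaths the mean is
  within 3 standard errors of the measured 26.36 L/min.
* **Reproducibility.** Each breath's samples come from a private RNG
  substream derived from `(seed, breath index)`, so a suite is
  reproducible and order-independent, and generation never perturbs the
  caller's RNG state.

What the simulator does *not* emulate: continuous volume overshoot above
the triggering sensor (observed on the bench but invisible at level
resolution), optical sensor physics, transport timing artifacts, and human
variability beyond the per-band flow statistics. Passing the simulator
suites therefore demonstrates that the classifier implements the five
rules exactly and robustly on streams *shaped like* device logs; it does
not re-establish the hardware accuracy figures, which came from physical
bench testing.

## Evaluation conventions

The positive class is the **valid** breath: sensitivity is the share of
truly valid breaths classified valid, specificity the share of truly
invalid breaths classified invalid. This orientation is forced by the
bench arithmetic: 65 valid and 100 invalid breaths with a single
misclassification give 100% sensitivity and 99% specificity only if the
misclassified breath was an invalid one passed as valid — even though the
accompanying prose describes "a single valid reading" as misclassified.
The package implements the arithmetic and surfaces the inconsistency here
rather than resolving it.

Level summaries (`summarize_by_level()`) mirror the bench range tables —
n, mean (SD), median (IQR), min, max — with percentiles computed by linear
interpolation (`stats::quantile` type 7), a single-measurement SD reported
as 0 with `sd_defined = FALSE`, and display rates rounded half-up to the
reported precision while full precision is retained in the objects.

```{r pipeline}
suite <- generate_protocol_suite(sim_config(), n_valid = 5, n_invalid = 5,
                                 seed = 42)
analysis <- classify_stream(suite$stream)
pred <- vapply(analysis, function(r) r$classification$valid, logical(1))
evaluate_classification(suite$truth$label, pred)
```

## Streaming

`stream_processor()` is the real-time form of the pipeline (the device
drives a video game with breath events): it buffers samples and emits each
breath the moment its two-zero terminator arrives. Its event sequence is
identical to `classify_stream()` on the batched input for every feed
chunking — the suite checks sample-at-a-time and ragged-chunk feeds, and a
10,000-breath stress stream.

## Problem sizes and numerical choices

The property suites use 1,000 random streams of length 0–200 for the
segmentation oracle, a 10,000-breath stream for batch/stream equivalence,
1,000 replicates for the calibration recovery bound, and 1,000 breaths for
the flow-band statistic — sizes at which every stochastic assertion has
comfortable margin while the whole suite stays interactive. Timestamps are
compared exactly after serialization (17 significant digits), rule
boundaries are inclusive as documented above, and all tolerance constants
live in `validity_params()` rather than in the classifier body.

## Limitations

Rule-based classification is exact but narrow: breaths that satisfy all
five rules with poor technique (e.g. a just-in-range 2 s gasp) are still
"valid". The five rules are volume- and timing-based only; flow quality
enters the metrics but not the decision. Learned scoring is out of scope
here. The simulator's trapezoid is a modeling convenience; it spans the
discrete behaviours the classifier can see, not the full space of human
breath shapes.
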