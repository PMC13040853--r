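---
title: "Methods: repetition detection, engagement outcomes and single-case inference in exergauge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repetition detection, engagement outcomes and single-case inference in exergauge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exergauge)
```

`exergauge` analyses engagement with camera-tracked home exercise
programs: it turns 19-joint skeletal streams into attempted and
high-quality repetition counts, converts those into adherence, fidelity
and star-rating outcomes, and supports the single-case
alternating-treatments designs (ATD) and agreement analyses such a
study uses. This vignette documents the models, the parameters that
matter, and the design decisions taken where the methodology left
choices open.

## Kinematic model and angle conventions

Streams are x (horizontal), y (vertical), z (depth) positions in
meters, nominally 30 frames/s, of 19 canonical joints (head, neck,
three spine markers, and left/right shoulder, elbow, wrist, hand, hip,
knee, foot). Input readers map file joint names onto this vocabulary
and reject unknown names, because camera SDKs differ in their joint
vocabularies.

Angles are defined so that thresholds like "at least 20 degrees of hip
flexion" are directly comparable:

* **hip flexion** = 180° minus the angle between the trunk vector
  (spine-base → spine-shoulder) and the thigh vector (hip → knee),
  folded to [0°, 180°]; standing straight reads 0°.
* **knee flexion** = 180° minus the interior angle at the knee.
* **hip ab/adduction** = the frontal-plane (x–y) angle between thigh
  and downward trunk axis; sagittal movement does not register.
* **lateral trunk lean** = the angle between the trunk vector and
  vertical after projection onto the frontal plane, so a purely
  forward (sagittal) tilt reads 0°.

Missing markers are linearly interpolated across gaps of at most 5
frames (~0.17 s); longer outages stay missing and the affected frames
cannot form repetition events. This keeps brief tracking flickers from
splitting repetitions while refusing to invent motion across long
outages.

## Repetition detection

Each exercise nominates a *driver metric* (squat: the smaller of the
two hip flexions; stepping exercises: anterior–posterior foot
separation; sit-to-stand: downward chest displacement; and so on).
Candidate repetitions are segmented by hysteresis: an event opens when
the driver crosses the attempt threshold upward and closes when it
falls below 50% of the threshold, and events separated by less than
0.25 s are merged. Hysteresis plus the merge gap prevents sensor
chatter around the threshold from double-counting, which a plain
threshold-crossing counter would do. An event is an **attempt** only if
*every* attempt rule for the exercise passes within the event window;
an attempt is **high quality** only if every quality rule passes too,
with each failed rule reported by name (this is what corrective
feedback would be built from).

Two exercises ship with full quality-rule sets. For the squat: peak hip
and knee flexion inside an acceptance band around 90°, lateral trunk
lean under 10°, feet within ±25% of shoulder separation, and under
0.05 m of foot travel during the repetition. The stated requirement
"90 degrees flexion in lowest position within a 20-degree range" is
ambiguous between ±20° ([70°, 110°]) and a total 20° band
([80°, 100°]); the default is ±20°, and the band half-width is a
parameter (`squat_depth_band`) so the stricter reading is one argument
away. For the tandem stance: front-leg hip flexion ≥ 15° and hip
adduction ≥ 5° (adduction serving as a proxy for the heel of the front
foot crossing the toes of the hindfoot — the true foot-overlap geometry
is not modelled), held for the prescribed time. The remaining eleven
exercises have attempt rules only; their quality criteria live in prior
validation work and can be supplied through the same rule framework.

Rule thresholds that the study protocol stated only qualitatively were
operationalized once and made configurable: chest "displaces
vertically" defaults to a 0.10 m excursion of the spine-shoulder
marker; stepping distances default to 0.15–0.20 m; the foot-off-ground
threshold is 0.05 m; speed warnings default to 2.0 m/s sustained for
0.2 s (central-difference velocities, so single-frame noise spikes do
not trigger warnings).

Timed exercises are scored by `time_hold()`: the hold is the longest
contiguous span over which every rule holds frame-wise, with at most
three attempts inside a 2-minute window, mirroring the in-game cap.

## Engagement outcomes

Adherence is attempted/prescribed and fidelity is
high-quality/prescribed (timed: best-time/prescribed-time); both may
exceed 1.0 when a child does extra repetitions. In the feedback
condition the game allows at most three extra attempts beyond the
prescription, so `summarize_session()` caps feedback-condition attempts
at prescribed + 3 per set; no-feedback sessions are self-counted and
uncapped. Session-level adherence/fidelity is the unweighted mean of
per-exercise proportions — the aggregation behind published
session-level proportions is not stated, so a pooled
total-attempts/total-prescribed mode is available via `aggregate =
"pooled"`. The star rule awards 1 star below 50%, 2 stars from 50% to
75%, 3 stars above 75%; read literally, "less than 50%" and "more than
75%" are strict, so both boundary fractions award 2 stars.

## Design generation and single-case inference

Restricted randomization schedules (runs of at most `max_run = 2`
identical conditions; balanced counts by default — whether the original
schedules were exactly balanced is not stated, so balance is a flag)
are enumerated exhaustively up to 24 sessions and drawn uniformly.

**PND.** The percentage of non-overlapping data needs a defined
comparison set in an ATD. The rule here: walk the sessions in order and
form one comparison per adjacent condition transition, each session
entering at most one comparison; a comparison is a demonstration of
effect when the favoured condition's value *strictly* exceeds the
other's (exact ties count as overlap — the conservative choice). This
deterministic rule reproduces the magnitude of published comparison
counts (e.g. five comparisons from a 5-feedback/8-no-feedback phase)
but is a documented choice, not a verified reconstruction of the
original procedure.

**Best-alone selection.** PND ≥ 90% on the adherence series decides the
superior condition; otherwise the higher mean adherence does. An exact
mean tie is surfaced as `undetermined` rather than silently broken,
since no tie-break rule was ever stated.

**SCRT.** The single-case randomization test permutes outcomes over
*exactly* the admissible schedule space — never unrestricted shuffles —
with the feedback-minus-no-feedback mean difference as statistic. The
null is exhaustive when the space fits in the resampling budget
(`n_mc = 10000` by default; a 16-session balanced max-run-2 space has
1296 members, so study-scale tests are exact), and Monte-Carlo
otherwise, with the observed schedule always included so p > 0.
One-tailed p-values count ties as extreme. The default direction is
"feedback greater", the a priori hypothesis.

**Fisher-Pitman and Wilcoxon-Pratt.** Unpaired session comparisons use
label permutation of the mean difference; paired comparisons use the
signed-rank statistic with Pratt's zero handling (zeros are ranked with
all absolute differences, then discarded, so they still displace the
ranks). Both enumerate exhaustively when feasible and are verified
against independent enumeration oracles in the test suite.

**Bayes factor.** For small designs the two-sample JZS Bayes factor is
computed by adaptive quadrature over the Zellner-Siow mixing variable
(inverse-gamma(1/2, r²/2) prior on g, i.e. a Cauchy prior with scale
`r_scale` on the standardized effect). The default scale √2⁄2 and
two-sided formulation are the field-standard defaults; the original
analysis named neither its prior nor sidedness, which is why published
Bayes-factor values are treated qualitatively rather than as numeric
targets.

**Visual analysis.** The level/trend/variability vocabulary is
quantified with configurable bands: level by tertiles of the outcome
scale; trend by the least-squares slope in scale-ranges per session
(< 0.01 zero-celerating, < 0.05 gradual, else steep); variability by
the coefficient of variation (< 10% stable, < 25% somewhat variable,
else highly variable). The original labels were assigned by eye; these
bands make the labels reproducible, and all thresholds are arguments.

## Agreement statistics

WMRE is the manual-count-weighted mean of per-video relative errors,
computed as the ratio of sums `100·Σ|system − manual| / Σ manual`, with
manual counts as ground truth and < 25% graded acceptable. The exact
published formula is not printed anywhere; the ratio-of-sums form is
consistent with the printed 100% boundary when a system records nothing
and is scale-invariant, and an unweighted per-video mean is available
via `aggregation = "mean"`. Videos with a zero manual count contribute
their system count to the numerator only. ICC(2,1) is estimated from
the two-way mean squares with exact F-based confidence bounds (not
bootstrap), graded excellent at ≥ 0.90 and good at 0.75–0.90;
Bland-Altman reports bias and `bias ± 1.96·SD` limits with the raw
(mean, difference) pairs exposed for plotting — figure rendering is out
of scope.

## The synthetic-data generator

The generator exists so every downstream stage is testable without
participant data; its defaults describe plausible study conditions, not
estimates of any real child's data (the distributions of real adherence
and miscount noise were never published).

Skeleton streams drive one or two joint angles with a raised-cosine
pulse per repetition (plus a plateau for held exercises) and solve limb
positions on a fixed-length chain (trunk 0.45 m, thigh and shank
0.40 m, child-scaled configurable) — the simplest model whose angle
traces are exactly controllable, which is what makes construction-based
oracles possible. Camera error is additive isotropic Gaussian noise on
*positions* (default studies use 10 mm), deliberately applied in
position space so it propagates through the angle computations the way
camera jitter would; dropouts are whole-frame missing markers. Session
series follow a Gaussian model around `baseline + delta·feedback +
trend·session`, with optional extra miscount noise on self-counted
no-feedback sessions; `feedback_delta = 0` with zero miscount noise is
exchangeable across conditions, which is what the type-I calibration
tests rely on. Rater tables add Gaussian noise and a systematic bias to
true counts, rounded and clipped at zero.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: biomechanically realistic
balance and compensation strategies, child-specific movement patterns,
correlated or limb-specific tracking failure (real dropouts cluster
when clothing or lighting is poor, and a parent stepping into frame is
a different failure mode entirely), game events, rest breaks and
multiplayer interference. Detection accuracy on these streams is an
upper bound on real-world accuracy.

## Numerical choices and problem sizes

All random draws flow from one stated seed per call, through an RNG
scope that restores the caller's state. Ties in permutation nulls are
counted as extreme (with a 10⁻¹² float guard); p-values from exhaustive
tests are bounded below by 1/|space|. Degenerate inputs error loudly
and specifically: zero prescriptions, zero pooled variance,
all-missing streams, empty schedule spaces, rating tables with missing
cells.

The test suite sizes simulations to what the checks need: type-I
calibration of the SCRT uses 2,000 null series at the study's
16-session scale; permutation oracles compare 200 random instances at
n ≤ 10 against full enumeration; detection robustness uses 50 simulated
videos at 10 mm noise and 2% dropouts; ICC coverage uses 500 replicates
of a 30 × 2 two-way design. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands.

## Interface

The package's functions are the interface, composed end to end by
`run_trial()` (scoring → series → visual/PND → best-alone → tests →
agreement) with delimited-text readers/writers for skeleton streams,
session logs and agreement tables, and YAML trial configurations.
Reports are emitted as a machine-readable results table plus a
human-readable summary, and rerunning the same configuration and inputs
reproduces the output byte for byte.

## Known limitations

Quality criteria are bundled for two exercises only; the others accept
rules but none are asserted. The PND comparison rule and several rule
thresholds are documented operationalizations of qualitative
statements, not recovered constants. Published participant-level
summary tables cannot be reproduced because the per-session and
per-video data underlying them were never released; the package's
guarantees are therefore stated as properties (calibration, oracle
equivalence, recovery, coverage) checked by simulation rather than as
numeric replications.
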