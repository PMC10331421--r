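---
title: "Simulating assistive-technology policies on a ward, and scoring their ethical compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating assistive-technology policies on a ward, and scoring their ethical compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wardsim is a discrete-time stochastic multi-agent simulation of a nursing
home ward, built to study a question that cannot be answered ethically on
real patients: how should a wearable assistive device that detects
disorientation decide when to stop prompting its wearer and call a human
caregiver instead? The package couples the simulator to an *ethical
compliance quantification* (ECQ) layer: named value models map each run's
complete record to a score in $[0, 1]$, so that assistive policies can be
compared quantitatively along dimensions such as safety and fairness — and
so that a badly operationalized value can be caught by comparing the scores
it produces against common sense.

## The simulated world

The world is a 2D floor plan: a grid of unit cells, each walkable or wall,
with named destination cells (rooms residents move between) and nurse
stations. Agent positions are continuous coordinates inside the grid
(origin top-left, x rightward, y downward, one cell = one `cell_size`
meter). Routing uses breadth-first search on the 4-connected walkable grid;
routes are sequences of cell centers, so every segment has unit length.
Diagonal movement, doors, and multi-floor geometry are deliberately out of
scope. The shipped demonstration ward (`demo_ward()`) is built
programmatically — a three-cell-wide corridor flanked by six rooms with
one-cell doorways and two corridor stations — because no real ward geometry
is distributed with the package; only the structure (rooms off a corridor
spine) is meant to be realistic.

## Agent behavior, one tick at a time

Each tick applies four phases in a fixed order: orientation transitions,
the smart-watch step, the nurse step, then movement. The order is a
reproducibility decision, not a behavioral claim; all randomness flows from
one generator seeded per run, so a serialized run protocol is a pure
function of (configuration, seed).

**Patients** cycle through a shuffled schedule of destinations. While
*oriented*, a patient advances along the shortest route by a step length
drawn from a normal distribution truncated below at zero (rejection
sampling; `sd_step = 0` degenerates to exact steps), clamped at the
destination. At every en-route tick an oriented patient becomes
*disoriented* with probability `dis_level` — the single knob that the
trajectory small-multiples vary. A disoriented, unguided patient performs a
correlated random walk: the heading is perturbed uniformly within ±90° and
a step is taken; a step into a wall resamples the heading (up to 8
attempts, then the patient stays put). Disorientation ends by a successful
cue, by nurse delivery, or — with small probability `reorient_prob` per
tick — spontaneously. Spontaneous recovery is a modeling addition with a
specific purpose: without it, runs under the no-help baseline would have an
absorbing disoriented state and the baseline's scores would be trivially 1.
It is configurable and may be set to 0.

**The smart watch** sees the wearer's true orientation only through a
noisy channel: an ongoing disorientation is detected with probability
`p_detect` per tick (geometric detection latency — the simplest reading of
"a certain detection probability" with an explicit time semantics). Once
detected, the watch issues an orientation cue every `cue_cooldown` ticks;
each cue restores orientation with probability `p_cue_success`. After
`n_help` failed cues the watch gives up and calls a nurse, once per
episode; `n_help = 0` calls immediately upon detection. Any reorientation
resets the episode state.

**Nurses** idle at their stations between tasks (standing in for all other
caregiving work). The nearest routine nurse claims the oldest pending
call, walks the shortest route to the patient at `speed` cells per tick,
and on arrival (within one cell) escorts the patient along the shortest
route to the patient's destination, the patient's position following the
nurse. On delivery the patient is released oriented. A guided patient's
orientation flag deliberately stays "disoriented" until release: that is
exactly what makes the naive safety operationalization below count
nurse-accompanied time as unsafe, which is the mistake the ECQ layer is
meant to expose. Calls whose patient has already recovered are dropped
(logged as cancelled); one call per episode, queued if all nurses are
busy. Under the *nurse-only* policy there is no watch, and a routine nurse
instead notices an unguided disoriented patient within
`discovery_radius`; under *no-help*, nurses never respond at all.

## The run protocol

A run executes a fixed `horizon` of ticks (fixed-time termination keeps
time-fraction scores comparable across runs) and records two redundant
views: a per-tick state table for every agent (position, orientation,
guidance, nurse task) and a time-stamped event list (DISORIENT, DETECT,
CUE_ISSUED, CUE_SUCCESS/CUE_FAIL, NURSE_CALLED, NURSE_ARRIVED,
GUIDE_START/GUIDE_END, DEST_REACHED, ...). Value models are defined over
time fractions (state), plausibility checks over event sequences; an
accounting invariant — disoriented time derived from events equals
disoriented time read off the state table — guards the redundancy and is
property-tested across seeds and policies. Protocols serialize to JSONL
(header record, then state records, then event records) with full
round-trip precision, so write–read is the identity and repeated runs are
byte-identical.

## Value models

Each value model carries an explicit polarity so plots can label axes
honestly: *violation* scores are best at 0, *compliance* scores at 1.

* `safety_original` (violation): fraction of a patient's time spent
  disoriented, regardless of guidance.
* `safety_refined` (violation): fraction of time disoriented *and
  unguided*. Time at a nurse's side counts as safe.
* `fairness` (violation): fraction of total nurse duty time
  (`n_nurses × horizon`) spent responding or guiding — caregiver time lost
  to route guidance, whose complement is time available for other
  caregiving. The pooled denominator is a choice; a per-nurse variant
  would expose load imbalance instead.
* `efficiency` (compliance): per completed leg, straight-line distance
  over distance travelled, averaged over legs and patients; and
  `fairness_quotient(a, b) = min/max`, the symmetric efficiency ratio
  between stakeholders, 1 at equality.

The two safety models are the package's worked example of
*value-operationalization feedback*. Under the original model, calling a
nurse immediately (`n_help = 0`) scores *worse* than waiting out five
failed cues — because a promptly-called nurse spends many escorted (still
"disoriented") ticks with the patient. That inversion contradicts common
sense, and seeing it in the per-policy box plots is what motivates the
refined model, under which immediate escalation is safest. Both models
ship, and the acceptance tests assert both the inversion and its
resolution. Per-run safety aggregates patient scores by their mean
(configurable to `max` for a worst-case reading); patient-level scores are
retained.

Beyond scores, `count_requirement()` counts how often a qualitative
requirement (a predicate over a run protocol, with a not-applicable
option) is satisfied or violated across runs.

## Study conditions and why they look the way they do

The shipped demo configuration is the package's reference condition: 3
patients, 2 nurses, 1000-tick runs, `dis_level` 0.01, `reorient_prob`
0.005, steps 1.0 ± 0.2 cells, `p_detect` 0.1, `p_cue_success` 0.3,
`cue_cooldown` 5, nurse speed 1.0, `discovery_radius` 2. No published
parameter set exists for this setting, so the defaults were chosen once,
by the following reasoning, and then frozen.

Write $D = 1/p_\text{detect}$ for the expected detection delay, $C$ for
the expected length of the cue phase, $F = (1-p_\text{cue})^{n_\text{help}}$
for the probability that every cue fails, and $R$, $G$ for nurse response
and escort times. Then per episode, to first order,

$$\text{refined}(n_\text{help}) \approx D + C + F R, \qquad
  \text{original}(n_\text{help}) \approx D + C + F (R + G),$$

with $C = 0$ and $F = 1$ at $n_\text{help} = 0$. The refined ordering
(immediate escalation safest) requires $C > (1-F)R$; the original-model
inversion requires $(1-F)(R+G) > C$. Both hold when
$(1-F)R < C < (1-F)(R+G)$ — the cue phase must outweigh the saved response
trips but not the response-plus-escort time. On the demo ward $R \approx G
\approx 12$ ticks at speed 1 (escorting a frail walker is not faster than
walking alone, so one speed serves both), and with `p_cue_success` 0.3 and
`cue_cooldown` 5 the cue phase at $n_\text{help} = 5$ is $C \approx 14$
ticks with $F \approx 0.17$: inside the window, with room on both sides.
Per-step monotonicity of the refined score in `n_help` additionally wants
`cue_cooldown` $> p_\text{cue} R \approx 3.6$. The discovery radius is the
one parameter set after piloting: at radius 5 the two corridor stations
blanket enough of the ward that nurses out-detect the watch and the
nurse-only baseline comes out safest, which is not the regime under study;
at radius 2 discovery requires a wanderer to pass close by a busy nurse,
and the intended regime — watch detects faster than humans notice —
obtains. `dis_level` 0.01 gives roughly ten episodes per patient per run,
enough signal without making disorientation the norm.

Problem sizes are likewise package choices: 1000-tick runs, 200 paired
runs per policy for the headline comparisons, and an 1812-run sweep (302
per policy across six policies) for scale parity. Seeds pair across
policies (`base_seed + i` for run *i* under every policy), which cancels
most Monte-Carlo noise from cross-policy orderings.

```{r sweep}
library(wardsim)
cfg <- read_sim_config(demo_config_path())
res <- policy_sweep(
  cfg,
  policies = list("smart_watch:0", "smart_watch:1", "smart_watch:3",
                  "smart_watch:5", "nurse_only", "no_help"),
  n_runs = 200,
  value_models = list(vm_safety_original(), vm_safety_refined(),
                      vm_fairness_guidance()),
  base_seed = 1)
glance(res)        # per policy x value model summaries
autoplot(res)      # grouped box plots, violation/compliance in the legend
```

## Numerical and degenerate-input decisions

* Routing ties break deterministically (neighbor order up, down, left,
  right); identical-cell endpoints give an empty route of length 0.
* Step lengths: truncation by rejection, not clamping, except that
  `sd_step = 0` short-circuits to the mean.
* Nurse arrival triggers within one cell of the patient; cue cooldown is
  measured from detection, so the first cue comes `cue_cooldown` ticks
  after detection and escalation at `n_help = 0` is immediate.
* Value-model outputs are clamped to $[0, 1]$; efficiency of a run with no
  completed leg falls back to the partial first leg, and a patient who
  never travelled scores 1 (no travel, no inefficiency). A leg of zero
  path length is a named degenerate-input error at the primitive level.
* Fairness without nurses, unknown patient ids, mixed-condition score
  pooling, unreachable route targets, and malformed protocol files all
  raise distinct classed conditions rather than returning silent zeros.

## What the generator does and does not emulate

The synthetic ward emulates the *structure* of the setting: spatial
route-following, stochastic disorientation with noisy detection, cue
escalation, human response latency, and the competition for caregiver
time. It does not emulate real ward geometry, observed human way-finding
(the random-walk wanderer is a stand-in, not a fitted model), patient
heterogeneity or preferences, emotional states, nurse shift patterns, or
time-varying disorientation risk. Passing tests therefore show that the
implementation is faithful to its own model and that the qualitative
policy trade-offs are robust within it — not that the absolute scores
transfer to any real ward. The shipped value models are worked examples
for the quantification method, not validated ethical instruments; the
package deliberately provides enumeration over a policy list rather than
policy optimization, because optimizing against a possibly-misspecified
value model is exactly the failure mode the refined-versus-original safety
example warns about.

## Known limitations

Single-floor geometry and 4-connected routing; one call per episode with
no re-issue; discovery only under the nurse-only policy (a watch-equipped
ward assumes the watch is the detection channel); per-tick Bernoulli
semantics for detection and transitions (no duration dependence); and a
pure-R engine, sized so that the full acceptance workload runs in minutes
on one CPU rather than for very large wards or populations.
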