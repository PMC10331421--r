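# wardsim

Stochastic multi-agent simulation of a nursing-home ward — disoriented
residents, nurses, and a smart-watch assistive device — together with an
**Ethical Compliance Quantification (ECQ)** layer that converts complete
run records into numerical scores on ethical value dimensions, so that
assistive-technology policies can be compared quantitatively before any
real patient is involved.

The package is for researchers in health-services simulation, assistive
technology design, and machine ethics who want a reproducible, seedable
testbed for the question: *after how many failed device interventions
should a wearable alert a human caregiver?*

## The model in brief

A ward is a grid floor plan (walkable cells, named rooms, nurse stations).
Each simulation tick, in fixed order:

1. an oriented resident *en route* becomes disoriented with probability
   `dis_level`; a disoriented unguided one recovers spontaneously with
   probability `reorient_prob`;
2. the smart watch detects an ongoing disorientation with per-tick
   probability `p_detect`, then issues orientation cues (success
   probability `p_cue_success`, one per `cue_cooldown` ticks) and, after
   `Nhelp` failed cues, calls a nurse — `Nhelp` is the policy under study,
   alongside the *Nurse Only* (no device, nurses must discover wanderers)
   and *No Help* baselines;
3. the nearest idle nurse answers the oldest call, walks to the patient,
   and escorts them to their destination;
4. oriented residents follow shortest routes with steps drawn from a
   truncated normal N(`mean_step`, `sd_step`²); disoriented residents
   perform a correlated random walk.

Every run yields a *protocol*: a per-tick state table plus an event log,
serialized as JSONL and byte-reproducible from (config, seed). Value
models map protocols to scores in [0, 1]:

| value model       | polarity   | definition                                             |
|-------------------|------------|--------------------------------------------------------|
| `safety_original` | violation  | time disoriented / horizon                             |
| `safety_refined`  | violation  | time disoriented *and unguided* / horizon              |
| `fairness`        | violation  | nurse time spent responding or guiding / total duty time |
| `efficiency`      | compliance | straight-line distance / distance travelled, per leg   |

The two safety models are a worked example of value-operationalization
feedback: the *original* model scores immediate escalation (`Nhelp = 0`)
as **less** safe than waiting out five failed cues, because escorted time
still counts as disoriented — an inversion that contradicts common sense
and disappears under the *refined* model. Reproducing both the inversion
and its resolution is part of the package's acceptance suite.

## Worked example

Sweep four policies over the shipped demo ward, 50 paired-seed runs each:

```r
library(wardsim)

cfg <- read_sim_config(demo_config_path())
res <- policy_sweep(
  cfg,
  policies     = list("smart_watch:0", "smart_watch:5", "nurse_only", "no_help"),
  n_runs       = 50,
  value_models = list(vm_safety_original(), vm_safety_refined(),
                      vm_fairness_guidance()),
  base_seed    = 1)
glance(res)
#> # A tibble: 12 × 10
#>    policy     value    polarity   mean median    q25    q75    min    max n_runs
#>    <chr>      <chr>    <chr>     <dbl>  <dbl>  <dbl>  <dbl>  <dbl>  <dbl>  <int>
#>  1 Nhelp=0    fairness VIOLATI… 0.227  0.225  0.196  0.261  0.120  0.320      50
#>  2 Nhelp=0    safety_… VIOLATI… 0.216  0.214  0.186  0.235  0.129  0.295      50
#>  3 Nhelp=0    safety_… VIOLATI… 0.127  0.125  0.107  0.142  0.0793 0.189      50
#>  4 Nhelp=5    fairness VIOLATI… 0.0300 0.0308 0.0152 0.0408 0      0.0725     50
#>  5 Nhelp=5    safety_… VIOLATI… 0.187  0.190  0.164  0.213  0.107  0.244      50
#>  6 Nhelp=5    safety_… VIOLATI… 0.174  0.180  0.154  0.199  0.107  0.224      50
#>  7 Nurse Only fairness VIOLATI… 0.103  0.106  0.0864 0.116  0.0435 0.170      50
#>  8 Nurse Only safety_… VIOLATI… 0.347  0.352  0.298  0.399  0.171  0.524      50
#>  9 Nurse Only safety_… VIOLATI… 0.284  0.289  0.226  0.344  0.0937 0.479      50
#> 10 No Help    fairness VIOLATI… 0      0      0      0      0      0          50
#> 11 No Help    safety_… VIOLATI… 0.626  0.620  0.576  0.713  0.338  0.855      50
#> 12 No Help    safety_… VIOLATI… 0.626  0.620  0.576  0.713  0.338  0.855      50
```

Reading the means (rows 2–3 vs 5–6): under `safety_original` the
immediate-escalation policy looks *worse* (0.216 > 0.187) — the
implausible inversion — while under `safety_refined` it is clearly safer
(0.127 < 0.174). Both smart-watch policies beat *Nurse Only* (0.284),
which beats *No Help* (0.626). The price shows in `fairness`: immediate
escalation consumes 22.7% of caregiver duty time against 3.0% when the
watch retries five times, and 0 when nobody helps. `autoplot(res)` draws
the per-policy box plots; `plot_trajectories()` draws orientation-colored
movement maps (blue oriented, red disoriented).

Protocols are first-class:

```r
prot <- run_simulation(cfg, seed = 7)
safety_refined(prot, "P1")
expected_step_count(run_batch(cfg, 10, base_seed = 1))
```

A command-line wrapper ships at `inst/cli/wardsim.R`
(`simulate`, `ecq`, `sweep`, `plot-traj`, `plot-scores`, `demo`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","wardsim.R",package="wardsim"))')" \
  sweep --config inst/extdata/demo_config.yaml \
  --policies smart_watch:0,smart_watch:5,nurse_only,no_help \
  --runs 50 --seed 1 --out /tmp/demo
```

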