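# Demo study conditions: a six-room ward with three residents and two
# nurses over a 1000-tick run. All parameters are simulation design
# parameters; see the package vignette for rationale.
world:
  floorplan: demo_ward.map
patients:
  n: 3
  dis_level: 0.01        # P(disorientation) per en-route tick
  mean_step: 1.0         # cells per tick
  sd_step: 0.2
  reorient_prob: 0.005   # spontaneous recovery per tick while unguided
nurses:
  n: 2
  speed: 1.0             # cells per tick (response and escort pace)
  discovery_radius: 2    # cells; nurse-only passive discovery
iat:
  p_detect: 0.1          # per-tick detection probability
  p_cue_success: 0.3     # per-cue reorientation probability
  cue_cooldown: 5        # ticks between cues
policy: "smart_watch:0"
run:
  horizon: 1000
  seed: 1
  n_runs: 10
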