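# Default study configuration (all values also built into default_config()).
viewing:
  distance_cm: 175       # eye-to-screen distance
  iod_cm: 6.2            # interocular distance used for the projections
display:
  width_deg: 13          # total horizontal span of the stimulus pair
stimulus:
  width_cm: 16           # disc width; length is width x ratio in [1, 1.5]
  depth_cm: 10           # |disc-centre depth| relative to the screen
texture:
  grid_cm: 1             # Voronoi generator grid spacing
  jitter_cm: 0.225       # uniform per-axis generator jitter half-range
dots:
  grid_cm: 1
  jitter_cm: 1.5
design:
  trials_per_condition: 30
  standard_deg: 45
  delta_deg: 12.5
observer:
  criterion_deg: 6.25    # same/different criterion: half the slant step
  gate_k: 2              # selective-fusion gate, in discrepancy SDs
  lapse: 0
population:
  sigma_median_deg: 5    # lognormal cue-noise median
  sigma_gsd: 1.3         # geometric SD
  cue_correlation: 1     # shared precision factor between cues
groups:
  ASD: {n: 16, regime: selective_fusion}
  TD: {n: 14, regime: mandatory_fusion}
analysis:
  alpha: 0.05
seed: 1
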