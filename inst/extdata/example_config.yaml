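# Example dirswarm configuration.
# `params` holds the model coupling constants; omitted fields keep their
# defaults (the fixed values used for the silent-disco fit, with the two
# calibrated parameters c and D at their rounded optima of 0.25).
params:
  A: 0.1        # attraction strength (1/s)
  a: 1          # attraction range exponent
  R: 1.5        # repulsion strength (1/s)
  r: 2          # repulsion decay exponent
  P: 0.5        # phase-and-gaze attraction strength (1/s)
  p: 1          # its spatial decay exponent
  D: 0.25       # gaze attraction strength "g" (rad/s)
  d: 1          # rotational spatial decay exponent
  U: 0.8        # auditory entrainment strength (rad/s)
  V: 0.4        # visual entrainment strength (rad/s)
  v: 1          # visual spatial decay exponent
  c: 0.25       # constriction (width of the visual field)
scenario:
  n_agents: 12
  bpm: 120
  condition: phase_180   # phase_90 | phase_180 | sped_up | uniform
  phase_shift_deg: 180   # informational; implied by the condition
  arena_radius: 3
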