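# Demonstration configuration: a small synthetic bilayer with a
# transmembrane water channel and a nona-arginine-sized peptide chain,
# plus a staged pull over a 5 kcal/mol Gaussian barrier.
seed: 1
asmd:
  span_start: 0.0
  span_end: 40.0
  stage_width: 5.0
  n_replicas: 25
  velocity: 1.0
  temperature: 310.15
  grid_spacing: 0.25
langevin:
  potential:
  - height: 5.0
    center: 20.0
    width: 3.0
  friction: 0.05
  spring_constant: 10.0
  timestep: 0.001
bilayer:
  lipid_counts:
    DPPC: 50
  box_xy: 60.0
  headgroup_planes: [19.25, -19.25]
  tail_beads_per_chain: 4
  chain_tilt_noise: 0.15
  water_slab_margin: 8.0
  channel: 6.0
  peptide:
    n_residues: 9
    depth: 0.0
  n_frames: 10
  frame_jitter: 0.3
metrics:
  slab_width: 1.0
  cutoff: 4.0
  trailing_fraction: 0.8
  margin: 5.0
  pore_threshold: 1.0
  persistence: 0.5
peptides: [Arg9, MAP, TP2]
plots: false
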