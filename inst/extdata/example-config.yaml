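input:
  coords: system.gro
  trajectory: traj.trr
  topology: topology.yaml
stages:
- onset
- migration
- rdf
- clusters
- order
window_ps:
- 1500000.0
- 2000000.0
stride_ps: 200.0
leaflet_cutoff: 1.2
cluster_cutoff: 1.2
persistence_ns: 1.0
rdf:
  r_max: 3.0
  bin_width: 0.02
seed: 1.0
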