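# Example configuration: dissociation-rate measurement at eps = 5 kBT.
# All quantities in reduced units; the units block is mandatory.
units:
  energy: eps0
  length: sigma_R
  time: tau
experiment:
  protocol: dissociation
  n_receptors: 100
  surface_density: 0.01
  box_height: 20
  epsilon: 5
  n_geom: 2
  n_replicates: 4
  seed: 120
  n_steps: 20000
  sample_interval: 100
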