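# Example run configuration: an average-height adult, default device layout.
# Lengths in cm, angles in degrees.
anthropometry:
  H: 175
geometry:
  rm: 2.0
simulation:
  theta1_range: [-15, 15]
  theta2_range: [-15, 15]
  n_frames: 25
  noise_sigma: 0.05
  seed: 1
  movement: both
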