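# Synthetic medial microstructure presets.
#
# Calibration targets (ECM volume fraction, median per-slice aspect ratio,
# medial thickness) follow the published group means for baseline and 100 nM
# noradrenaline-constricted rat aortic media.  Cell dimensions and helix angle
# are calibration values chosen to reproduce those targets, not measurements.
version: 1
baseline:
  grid_shape: [64, 64, 64]
  voxel_spacing: [0.5, 0.5, 0.5]        # um per voxel (r, z, theta)
  target_phi_ecm: 0.60
  cell_semi_axes: [12.0, 2.5, 2.5]      # um: long (z-theta plane), theta-transverse, radial
  helix_angle: 60.0                     # deg between long axis and circumferential direction
  angle_jitter: 5.0                     # deg sd of per-cell helix angle
  radial_flattening: 1.0
  placement_jitter: 3.0                 # um sd around the seeding lattice
  thickness_um: 27.7
  median_ar_reference: 0.5232
constricted:
  grid_shape: [64, 64, 64]
  voxel_spacing: [0.5, 0.5, 0.5]
  target_phi_ecm: 0.68
  cell_semi_axes: [9.6, 3.227, 3.227]
  helix_angle: 60.0
  angle_jitter: 5.0
  radial_flattening: 0.72
  placement_jitter: 3.0
  thickness_um: 33.2
  median_ar_reference: 0.4163
# Default contraction mapping baseline -> constricted: cells shorten along the
# long axis, widen transversely and flatten radially; the wall thickens by the
# published thickness ratio 33.2/27.7.
contraction:
  long_axis_scale: 0.80
  transverse_scale: 1.291
  radial_flattening: 0.72
  thickness_scale: 1.1986
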