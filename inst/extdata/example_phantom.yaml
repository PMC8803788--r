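# Minimal torso phantom specification (schema_version 1).
# Voxel coordinates are 0-based; the axial direction is the last axis.
schema_version: 1
grid_shape: [32, 32, 16]
voxel_size: [4.0, 4.0, 4.0]
seed: 1
body:
  center: [15.5, 15.5, 7.5]
  semi_axes: [14.0, 12.0, 20.0]
  suv: 1.0
organs:
- label: liver
  center: [19.0, 17.0, 7.0]
  semi_axes: [7.0, 6.0, 5.0]
  suv: 2.5
lesions:
- center: [19.0, 17.0, 7.0]
  radius: 2.5
  suv: 8.0
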