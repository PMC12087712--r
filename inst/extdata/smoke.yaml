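# Small, fast end-to-end configuration (coarse mesh, short phantom).
# Run:  Rscript inst/cli/osteofe.R sweep --config inst/extdata/smoke.yaml --out smoke-out
seed: 1
phantom:
  length: 60
  outer_radius: 8
  inner_radius: 5
  flare_radius: 11
  flare_length: 14
  trabecular_smoothness: 3
  spacing: 1.5
assembly:
  plate_length: 40
  plate_width: 8
  plate_thickness: 4
  plate_z0: 4
  hole_z: [9, 15, 33, 39]
  filled_holes: [1, 2, 3, 4]
  fracture_z: 24
  pad_height: 6
  h: 2.5
law:
  type: density
stages:
  C1: 1
  C2: 10
  C3: 100
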