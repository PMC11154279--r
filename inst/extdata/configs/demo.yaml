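# Demo run: 20 x 40 x 20 mm^3 PMMA validation phantom on the standard
# divergent microbeam geometry.  Small history count for a quick smoke run.
geometry:
  sd_mm: 212
  slit_um: 30
  ctc_um: 400
  field_mm: [10, 10]
  sigma_mm: 0.58
  tilt_deg: 8
spectrum:
  kvp: 225
  filtration_mm_al: 1
phantom:
  recipe: slab
  dims_mm: [20, 40, 20]
  material: pmma
plan:
  prescription_peak_gy: 20
  roi: beam
  gap_mm: 4
execution:
  seed: 20240130
  histories: 20000
  voxel_mm: 1
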