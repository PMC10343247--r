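# Default run configuration: Kevlar/PCU constituents and the 32 x 26 x 11 mm
# braided meniscus design.  Moduli are given in GPa at this boundary and
# converted to MPa internally.
materials:
  fiber:
    name: Kevlar
    E11_GPa: 128.7
    E22_GPa: 12.87
    v12: 0.3
    G12_GPa: 12.87
    G23_GPa: 12.87
  matrix:
    name: PCU
    E_GPa: 0.057
    v: 0.43
bridging:
  Vf: 0.70
  alpha: 0.30
  beta: 0.30
geometry:
  length_mm: 32
  width_mm: 26
  height_mm: 11
  inner_length_mm: 26
  inner_bulge_mm: 3
  min_thickness_mm: 3
  fiber_width_mm: 2
  fiber_height_mm: 1
  gap_mm: 2
  fan_angle_deg: 15
  interlock_area_mm2: 0.5
mesh:
  resolution_mm: 1
loads_N: [400, 600, 800, 1200, 1400]
output_dir: results
log_level: info
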