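# 20x / 0.5 NA water-dipping configuration.
# The 9 mm pupil (2 * 0.5 * 9 mm) is relayed at 2.4x onto the 16 mm ETL
# aperture, so the NA is cropped to 0.5 * (16/2.4)/9 = 0.37.
# Magnification: a nominal effective value of 16.66x has been reported for
# this configuration, but the lens-chain arithmetic (f_obj = 180/20 = 9 mm
# with the 125, 300, 200, 100, 200 mm chain) gives 18.52x, which is also
# the value consistent with the 720 um horizontal field of view
# (2048 * 6.5 um / 18.52 = 719 um). The chain value is used; the
# discrepancy is recorded here rather than resolved.
objective:
  na: 0.5
  f_obj_mm: 9.0
  immersion_index: 1.33
  nominal_mag: 20
light_sheet:
  aperture_ratio: 0.18
relays:
  focal_lengths_mm: [125, 300, 200, 100, 200]
etl:
  aperture_diameter_mm: 16
  max_power_dioptre: 5
  flyback_time_s: 0.008
camera:
  n_cols: 2048
  n_rows: 1024
  pixel_pitch_um: 6.5
  line_time_s: 9.74e-06
  bidirectional_shutter: false
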