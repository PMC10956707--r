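# 60x / 1.1 NA water-dipping configuration.
# The pupil is perfectly matched to the 16 mm ETL aperture by the 2.4x
# relay (6.6 mm x 2.4 = 15.84 mm), so the full objective NA is retained.
# Lens chain after the objective (f = 180/60 = 3 mm): 125, 300, 200, 100,
# 200 mm, giving a total magnification of 55.56x.
objective:
  na: 1.1
  f_obj_mm: 3.0
  immersion_index: 1.33
  nominal_mag: 60
  bfp_diameter_mm: 6.6
light_sheet:
  aperture_ratio: 0.18
relays:
  focal_lengths_mm: [125, 300, 200, 100, 200]
etl:
  aperture_diameter_mm: 16
  max_power_dioptre: 5
  flyback_time_s: 0.008      # reproduces a 60% duty cycle at 50 Hz
camera:
  n_cols: 2048
  n_rows: 1024
  pixel_pitch_um: 6.5
  line_time_s: 9.74e-06
  bidirectional_shutter: false
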