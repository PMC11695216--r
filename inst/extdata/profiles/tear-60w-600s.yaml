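name: TEAR-60W-600s
shape_label: TEAR
intervals:
- power_w: 60.0
  duration_s: 360.0
  distance_mm: 0.0
- power_w: 60.0
  duration_s: 210.0
  distance_mm: 30.0
- power_w: 60.0
  duration_s: 30.0
  distance_mm: 15.0
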