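name: HOUR-60W-600s
shape_label: HOUR
intervals:
- power_w: 60.0
  duration_s: 260.0
  distance_mm: 0.0
- power_w: 60.0
  duration_s: 80.0
  distance_mm: 40.0
- power_w: 60.0
  duration_s: 260.0
  distance_mm: 0.0
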