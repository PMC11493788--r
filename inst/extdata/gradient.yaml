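# UHPLC gradient: eluent A = 2 mM ammonium formate in water,
# eluent B = 80:20 methanol/acetonitrile (v/v); compositions are A:B at
# segment end.
flow_ml_min: 0.5
segments:
  - {duration_min: 0.5, pct_b_end: 25, mode: isocratic}
  - {duration_min: 9.5, pct_b_end: 95, mode: linear}
  - {duration_min: 2.0, pct_b_end: 95, mode: isocratic}
  - {duration_min: 1.0, pct_b_end: 25, mode: linear}
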