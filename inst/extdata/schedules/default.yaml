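name: default
baseline_times:
- -5.0
- -1.0
segments:
- start_min: 0.0
  end_min: 10.0
  interval_min: 0.5
- start_min: 10.0
  end_min: 30.0
  interval_min: 1.0
- start_min: 30.0
  end_min: 90.0
  interval_min: 3.0
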