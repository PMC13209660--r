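# Default behavioural sleep-stage coding scheme (package default weights;
# mutually exclusive criteria between stages carry the higher weights).
epoch_length_s: 15
codability_threshold_pct: 65
criteria:
  - name: eye_movements
    applicability: both
    weight: 35
  - name: respiration_pattern
    applicability: both
    weight: 35
  - name: body_movements
    applicability: both
    weight: 15
  - name: startles
    applicability: both
    weight: 10
  - name: sucking
    applicability: both
    weight: 5
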