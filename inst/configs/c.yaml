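# ablation variant: C
toggles:
  A: false
  B: false
  C: true
  D: false
num_classes: 11
input_size: 640
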