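# ablation variant: A+D
toggles:
  A: true
  B: false
  C: false
  D: true
num_classes: 11
input_size: 640
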