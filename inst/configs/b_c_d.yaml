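# ablation variant: B+C+D
toggles:
  A: false
  B: true
  C: true
  D: true
num_classes: 11
input_size: 640
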