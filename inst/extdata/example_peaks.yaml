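# three-component synthetic mixture used in the README walkthrough
peaks:
  - frequency: 40
    amplitude: 1.0
    decay: 0.01
  - frequency: 97.5
    amplitude: 0.6
    decay: 0.02
  - frequency: 180
    amplitude: 0.25
    decay: 0.01
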