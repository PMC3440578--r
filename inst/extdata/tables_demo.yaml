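# Demonstration config: derive the reported quantities (amplitude-average
# lifetime, total time-zero anisotropy, wobbling-in-cone angle) from the
# bundled reference parameter sets of the three yeast Dre2 constructs.
seed: 1
stages:
  - name: tables
    rows:
      - construct: ntd
      - construct: fl-apo
      - construct: fl-holo
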