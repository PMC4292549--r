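units: s^-1
acyclic: yes
states:
- name: S1
  class: O_S
- name: S2
  class: C
- name: S3
  class: O
- name: S4
  class: O_S
- name: S5
  class: O_S
edges:
- from: S1
  to: S3
  rate_fwd: 141.6
  rate_rev: 9.79
- from: S1
  to: S5
  rate_fwd: 177.3
  rate_rev: 148.1
- from: S3
  to: S4
  rate_fwd: 253.3
  rate_rev: 0.24
- from: S2
  to: S4
  rate_fwd: 332.6
  rate_rev: 0.4
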