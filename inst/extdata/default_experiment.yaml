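datasets:
- id: D1
  dose_gy: 20.0
  phase: asynchronous
  channels:
    fast:
      mode: full
      mu: 1
    slow:
      mode: full
      mu: 2
    aej:
      mode: full
      mu: 3
- id: D2
  dose_gy: 20.0
  phase: G1
  channels:
    fast:
      mode: binding_only
      mu: 4
    slow:
      mode: full
      mu: 2
    aej:
      mode: full
      mu: 3
- id: D3
  dose_gy: 20.0
  phase: G2
  channels:
    fast:
      mode: binding_only
      mu: 4
    slow:
      mode: full
      mu: 2
    aej:
      mode: full
      mu: 3
- id: D4
  dose_gy: 80.0
  phase: asynchronous
  channels:
    fast:
      mode: full
      mu: 1
    slow:
      mode: binding_only
      mu: 4
    aej:
      mode: full
      mu: 3
- id: D5
  dose_gy: 80.0
  phase: asynchronous
  channels:
    fast:
      mode: absent
      mu: ~
    slow:
      mode: full
      mu: 2
    aej:
      mode: full
      mu: 3
- id: D6
  dose_gy: 54.0
  phase: asynchronous
  channels:
    fast:
      mode: absent
      mu: ~
    slow:
      mode: full
      mu: 2
    aej:
      mode: full
      mu: 3
- id: D7
  dose_gy: 52.0
  phase: asynchronous
  channels:
    fast:
      mode: absent
      mu: ~
    slow:
      mode: full
      mu: 2
    aej:
      mode: absent
      mu: ~
- id: D8
  dose_gy: 32.0
  phase: asynchronous
  channels:
    fast:
      mode: full
      mu: 1
    slow:
      mode: full
      mu: 2
    aej:
      mode: absent
      mu: ~
prior:
  alpha:
  - -6.9077553
  - -6.9077553
  - -6.9077553
  - -6.9077553
  beta:
  - 2.9957323
  - 2.9957323
  - 2.9957323
  - 2.9957323
  sigma2: 0.25
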