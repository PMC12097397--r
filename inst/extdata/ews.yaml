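name: EWS
rules:
- parameter: heart_rate
  type: numeric
  bands:
  - points: 1
    lo: 41.0
    hi: 50.0
    lo_closed: yes
    hi_closed: yes
  - points: 1
    lo: 101.0
    hi: 110.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 111.0
    hi: 129.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: -.inf
    hi: 40.0
    lo_closed: yes
    hi_closed: no
  - points: 3
    lo: 130.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
- parameter: sbp
  type: numeric
  bands:
  - points: 1
    lo: 81.0
    hi: 100.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 71.0
    hi: 80.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 200.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 70.0
    lo_closed: yes
    hi_closed: no
- parameter: resp_rate
  type: numeric
  bands:
  - points: 1
    lo: 15.0
    hi: 20.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 21.0
    hi: 29.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: -.inf
    hi: 8.0
    lo_closed: yes
    hi_closed: no
  - points: 3
    lo: 30.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
- parameter: temperature
  type: numeric
  bands:
  - points: 1
    lo: 35.1
    hi: 36.5
    lo_closed: yes
    hi_closed: yes
  - points: 1
    lo: 37.5
    hi: .inf
    lo_closed: no
    hi_closed: yes
  - points: 2
    lo: -.inf
    hi: 35.0
    lo_closed: yes
    hi_closed: no
- parameter: avpu
  type: avpu
  bands:
  - points: 1
    levels: V
  - points: 2
    levels: P
  - points: 3
    levels: U
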