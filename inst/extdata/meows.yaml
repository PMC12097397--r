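name: MEOWS
rules:
- parameter: resp_rate
  type: numeric
  bands:
  - points: 2
    lo: 21.0
    hi: 25.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 12.0
    lo_closed: yes
    hi_closed: no
  - points: 3
    lo: 25.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
- parameter: spo2
  type: numeric
  bands:
  - points: 2
    lo: 92.0
    hi: 95.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 92.0
    lo_closed: yes
    hi_closed: no
- parameter: o2_supplement
  type: logical
  bands:
  - points: 2
    flag: yes
- parameter: temperature
  type: numeric
  bands:
  - points: 2
    lo: 37.3
    hi: 37.7
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: 37.7
    hi: .inf
    lo_closed: no
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 36.0
    lo_closed: yes
    hi_closed: no
- parameter: sbp
  type: numeric
  bands:
  - points: 1
    lo: 140.0
    hi: 150.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 150.0
    hi: 160.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: 160.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 90.0
    lo_closed: yes
    hi_closed: no
- parameter: dbp
  type: numeric
  bands:
  - points: 1
    lo: 90.0
    hi: 100.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 100.0
    hi: 110.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: 110.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
- parameter: heart_rate
  type: numeric
  bands:
  - points: 1
    lo: 110.0
    hi: 120.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 120.0
    hi: 130.0
    lo_closed: yes
    hi_closed: yes
  - points: 2
    lo: 50.0
    hi: 60.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: 130.0
    hi: .inf
    lo_closed: no
    hi_closed: yes
  - points: 3
    lo: -.inf
    hi: 50.0
    lo_closed: yes
    hi_closed: no
- parameter: avpu
  type: avpu
  bands:
  - points: 3
    levels:
    - V
    - P
    - U
- parameter: vas_pain
  type: numeric
  bands:
  - points: 2
    lo: 4.0
    hi: 7.0
    lo_closed: yes
    hi_closed: yes
  - points: 3
    lo: 7.0
    hi: .inf
    lo_closed: yes
    hi_closed: yes
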