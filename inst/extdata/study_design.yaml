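items:
  labels:
  - a
  - b
  - c
  - d
  - e
  attribute: abstraction
  intended_order:
  - a
  - b
  - c
  - d
  - e
'n': 987
seed: 1.0
covariates:
- name: age
  kind: numeric
  mean: 15.35
  sd: 2.96
  lognormal: no
  round: yes
  min: 13.0
- name: game_time
  kind: numeric
  mean: 23.010000000000002
  sd: 10.26
  lognormal: yes
  round: no
- name: gender
  kind: nominal
  levels:
  - female
  - male
  probs:
  - 0.52
  - 0.48
- name: art_grade
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  probs:
  - 0.344394973216768
  - 0.40918214639616
  - 0.19446280224768
  - 0.04620898271232
  - 0.00549017616384
  - 0.000260919263232
- name: S1
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  probs:
  - 0.013760756289063
  - 0.10566653734375
  - 0.304273350234375
  - 0.38941066234375
  - 0.186888693789063
- name: S2
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  probs:
  - 0.011156640625
  - 0.0926859375
  - 0.28875234375
  - 0.3998109375
  - 0.207594140625
- name: S3
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  probs:
  - 0.030382668789062
  - 0.16956076234375
  - 0.354859200234375
  - 0.33006863734375
  - 0.115128731289063
- name: S4
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  probs:
  - 0.011156640625
  - 0.0926859375
  - 0.28875234375
  - 0.3998109375
  - 0.207594140625
- name: S5
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  - 5
  probs:
  - 0.035806100625
  - 0.1860270975
  - 0.36243210375
  - 0.3138300975
  - 0.101904600625
- name: PM
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  probs:
  - 0.108303962962963
  - 0.356721444444444
  - 0.391645222222222
  - 0.14332937037037
- name: SO
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  probs:
  - 0.018962962962963
  - 0.156444444444444
  - 0.430222222222222
  - 0.39437037037037
- name: LM
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  probs:
  - 0.08137037037037
  - 0.319222222222222
  - 0.417444444444444
  - 0.181962962962963
- name: IM
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  probs:
  - 0.274625
  - 0.443625
  - 0.238875
  - 0.042875
- name: IP
  kind: ordinal
  levels:
  - 1
  - 2
  - 3
  - 4
  probs:
  - 0.074088
  - 0.306936
  - 0.423864
  - 0.195112
group: ~
leaves:
- when:
  - covariate: game_time
    op: <=
    value: 20.0
  - covariate: IP
    op: <=
    value: 2.0
  worth:
  - 0.415
  - 0.241
  - 0.143
  - 0.12
  - 0.081
  group_worth: ~
- when:
  - covariate: game_time
    op: <=
    value: 20.0
  - covariate: IP
    op: '>'
    value: 2.0
  worth:
  - 0.318
  - 0.237
  - 0.184
  - 0.144
  - 0.117
  group_worth: ~
- when:
  - covariate: game_time
    op: '>'
    value: 20.0
  - covariate: IP
    op: <=
    value: 1.0
  worth:
  - 0.28
  - 0.233
  - 0.23
  - 0.158
  - 0.099
  group_worth: ~
- when:
  - covariate: game_time
    op: '>'
    value: 20.0
  - covariate: IP
    op: '>'
    value: 1.0
  worth:
  - 0.403
  - 0.223
  - 0.184
  - 0.116
  - 0.074
  group_worth: ~
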