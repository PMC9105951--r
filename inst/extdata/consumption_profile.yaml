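months:
- 6
- 7
- 8
- 9
- 10
- 11
- 12
- 13
- 14
- 15
- 16
- 17
- 18
- 19
- 20
- 21
- 22
- 23
share_overall:
- 0.46
- 0.63
- 0.554
- 0.478
- 0.402
- 0.326
- 0.25
- 0.23
- 0.21
- 0.19
- 0.17
- 0.15
- 0.13
- 0.122
- 0.114
- 0.106
- 0.098
- 0.09
share_tertile:
  t1:
  - 0.39
  - 0.534
  - 0.4632
  - 0.3924
  - 0.3216
  - 0.2508
  - 0.18
  - 0.1691
  - 0.1582
  - 0.1473
  - 0.1364
  - 0.1255
  - 0.1145
  - 0.1036
  - 0.0927
  - 0.0818
  - 0.0709
  - 0.06
  t2:
  - 0.49
  - 0.671
  - 0.5888
  - 0.5066
  - 0.4244
  - 0.3422
  - 0.26
  - 0.2445
  - 0.2291
  - 0.2136
  - 0.1982
  - 0.1827
  - 0.1673
  - 0.1518
  - 0.1364
  - 0.1209
  - 0.1055
  - 0.09
  t3:
  - 0.52
  - 0.712
  - 0.6256
  - 0.5392
  - 0.4528
  - 0.3664
  - 0.28
  - 0.2636
  - 0.2473
  - 0.2309
  - 0.2145
  - 0.1982
  - 0.1818
  - 0.1655
  - 0.1491
  - 0.1327
  - 0.1164
  - 0.1
duration_pmf:
  '0': 0.26
  '1': 0.085
  '2': 0.085
  '3': 0.07
  '4': 0.07
  '5': 0.07
  '6': 0.041666666666667
  '7': 0.041666666666667
  '8': 0.041666666666667
  '9': 0.041666666666667
  '10': 0.041666666666667
  '11': 0.041666666666667
  '12': 0.015714285714286
  '13': 0.015714285714286
  '14': 0.015714285714286
  '15': 0.015714285714286
  '16': 0.015714285714286
  '17': 0.015714285714286
  '18': 0.015714285714286
servings_per_day: 1.0
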