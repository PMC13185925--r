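n_pairs_mz: 12
n_pairs_dz: 13
ace_exposure:
- 0.33333333333333331
- 0.33333333333333331
- 0.33333333333333331
ace_outcome:
- 0.17000000000000001
- 0.07000000000000001
- 0.76000000000000001
ace_factors:
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
ace_mediators:
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
- - 0.29999999999999999
  - 0.10000000000000001
  - 0.59999999999999998
instrumental_path: 0.09
pleiotropy_outcome: 0.06
pleiotropy_factors:
- 0.04
- 0.03
pleiotropy_mediators:
- 0.0
- 0.0
- 0.0
- 0.0
- 0.0
- 0.0
a_paths:
- 0.28999999999999998
- 0.28999999999999998
b_paths:
- 0.17000000000000001
- 0.14000000000000001
c_prime: 0.05
factor_loadings:
  med_01:
  - 0.65000000000000002
  - 0.0
  med_02:
  - 0.65000000000000002
  - 0.0
  med_03:
  - 0.65000000000000002
  - 0.0
  med_04:
  - 0.0
  - 0.59999999999999998
  med_05:
  - 0.0
  - 0.59999999999999998
  med_06:
  - 0.0
  - 0.59999999999999998
factor_correlation: 0.45000000000000001
confounder_cor:
- 0.17000000000000001
- 0.17000000000000001
- 0.0
dz_pgs_cor: 0.5
measurement: ordinal
items_exposure: 8
items_outcome: 6
items_mediator: 5
thresholds_exposure:
- 0.12566134685507413
- 0.67448975019608171
- 1.17498679206608991
- 1.75068607125216946
thresholds_outcome:
- 0.12566134685507413
- 0.67448975019608171
- 1.17498679206608991
- 1.75068607125216946
thresholds_mediator:
- -0.84162123357291418
- -0.25334710313579978
- 0.25334710313579978
- 0.84162123357291441
item_reliability: 0.80000000000000004
missing_rate: 0.02
seed: 20240101
mediator_names:
- med_01
- med_02
- med_03
- med_04
- med_05
- med_06
factor_names:
- f1
- f2
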