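# Randomized-search distributions for the nine classical families.
# Each entry is either a discrete value set ("values") or a range
# ("min"/"max", optionally log-uniform or integer-valued).
SVC:
  cost: {min: 0.01, max: 1000, log: true}
  gamma: {min: 0.0001, max: 1, log: true}
  kernel: {values: [radial, linear]}
RF:
  ntree: {min: 100, max: 1000, integer: true}
  mtry: {min: 2, max: 30, integer: true}
KNN:
  k: {min: 3, max: 15, integer: true}
DT:
  maxdepth: {min: 2, max: 30, integer: true}
  minsplit: {min: 2, max: 40, integer: true}
  cp: {min: 0.0001, max: 0.05, log: true}
GBDT:
  nrounds: {min: 50, max: 500, integer: true}
  max_depth: {min: 2, max: 8, integer: true}
  eta: {min: 0.01, max: 1, log: true}
ABDT:
  n_estimators: {min: 50, max: 500, integer: true}
  maxdepth: {values: [1, 2, 3]}
  learning_rate: {min: 0.01, max: 1, log: true}
GNB: {}
SGD:
  lambda: {min: 0.000001, max: 0.01, log: true}
  eta0: {min: 0.001, max: 0.1, log: true}
  epochs: {values: [10, 20, 50]}
LR:
  C: {min: 0.01, max: 100, log: true}
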