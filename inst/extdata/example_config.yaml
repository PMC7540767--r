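# Example rmphage run configuration: baseline correlated growth-defence
# trade-off assembled with the fast iterative engine. Unset fields take
# the package defaults (see default_config()).
engine: iterative
n_rounds: 5000
seed: 1
params:
  eta: 1.0e-8
  beta: 100
  delta: 0.1
  alpha: 0.1
  C: 1.0e+8
  T: 10000
  ext_threshold: 1
sampler:
  family: correlated_product
  steepness: 0.03
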