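# Example platform configuration: promising treatment, correlated endpoints,
# 125 participants per arm, concurrent control sharing.
cohort_size: 250
trt_rates: [0.45, 0.45]
rho: 0.3
sharing_mode: concurrent
n_sims: 1000
seed: 42
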