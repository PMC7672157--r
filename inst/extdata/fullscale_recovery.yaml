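# Full-scale heritability-recovery study (fully synthetic scenario).
# The shipped validation suites run reduced versions of this design;
# this configuration reproduces the complete grid. Expect hours of
# compute and >20 GB of memory at the largest n/p combination.
scenario: recovery_grid
"n": 10000
p: 500000
h2: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
f_c: 0.1
replicates: 30
n_std: 1000
methods: [gcv_projection, gcv_two_set, kfold_cv, reml_oracle]
seed: 1
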